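# Dipeptide database: enumeration, physicochemical properties
# (MW, net charge, pI, hydrophobicity) and threshold screening.

#' Enumerate the 400 dipeptide sequences
#'
#' All ordered pairs of the 20 standard amino acids, lexicographically
#' sorted.
#'
#' @return character vector of 400 two-letter codes, "AA" first
#' @export
enumerate_dipeptides <- function() {
  aa <- amino_acid_codes()
  sort(as.vector(outer(aa, aa, paste0)))
}

#' Dipeptide molecular weight
#'
#' Sum of the free amino-acid average masses minus one water (one peptide
#' bond).
#'
#' @param sequence two-letter code (vectorised)
#' @return molecular weight (Da)
#' @export
molecular_weight <- function(sequence) {
  vapply(sequence, function(s) {
    res <- .check_sequence(s)
    sum(.aa_mass[res]) - .water_mass
  }, numeric(1), USE.NAMES = FALSE)
}

# ionizable groups of a dipeptide: both termini plus ionizable side chains
.ionizable_groups <- function(sequence, table = default_pka_table()) {
  res <- .check_sequence(sequence)
  groups <- c("Nterm", "Cterm", res[res %in% table$group])
  idx <- match(groups, table$group)
  data.frame(group = groups, pka = table$pka[idx], sign = table$sign[idx],
             stringsAsFactors = FALSE)
}

#' Henderson-Hasselbalch net charge of a dipeptide
#'
#' Positive (basic) groups contribute 1/(1 + 10^(pH - pKa)); negative
#' (acidic) groups contribute -1/(1 + 10^(pKa - pH)).  Only the two termini
#' and ionizable side chains are considered.
#'
#' @param sequence two-letter code
#' @param pH pH value in [0, 14]
#' @param table pKa table (see \code{\link{default_pka_table}})
#' @return net charge (elementary charges)
#' @export
net_charge <- function(sequence, pH = 7, table = default_pka_table()) {
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]", call. = FALSE)
  g <- .ionizable_groups(sequence, table)
  pos <- g$pka[g$sign > 0]
  neg <- g$pka[g$sign < 0]
  sum(1 / (1 + 10^(pH - pos))) - sum(1 / (1 + 10^(neg - pH)))
}

#' Isoelectric point by bisection
#'
#' The net-charge function is strictly decreasing in pH, so its unique root
#' in (0, 14) is found by bisection to the requested tolerance.
#'
#' @param sequence two-letter code
#' @param table pKa table
#' @param tol bisection tolerance (pH units)
#' @return pI (pH units)
#' @export
isoelectric_point <- function(sequence, table = default_pka_table(),
                              tol = 1e-3) {
  lo <- 0; hi <- 14
  f_lo <- net_charge(sequence, lo, table)
  if (f_lo < 0) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, table) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Dipeptide hydrophobicity
#'
#' Sum of the per-residue hydropathy values.
#'
#' @param sequence two-letter code (vectorised)
#' @param scale named hydropathy vector (default Kyte-Doolittle)
#' @return hydrophobicity (scale units)
#' @export
hydrophobicity <- function(sequence, scale = kyte_doolittle()) {
  vapply(sequence, function(s) {
    res <- .check_sequence(s)
    if (anyNA(scale[res])) stop("hydropathy scale missing residue", call. = FALSE)
    sum(scale[res])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build the dipeptide property database
#'
#' Enumerates the 400 dipeptides and computes molecular weight, isoelectric
#' point, net charge at pH 7 and hydrophobicity; imported docking energies
#' and umami probabilities may be merged in by sequence.
#'
#' @param scores optional data.frame with column \code{sequence} and any of
#'   \code{e_t1r1_kcal}, \code{e_t1r3_kcal}, \code{umami_prob}
#' @param pka_table pKa table
#' @param scale hydropathy scale
#' @return data.frame with one row per dipeptide and columns
#'   \code{sequence}, \code{mw_da}, \code{pi}, \code{net_charge_ph7},
#'   \code{hydrophobicity}, \code{acidic}, \code{hydrophilic}, plus any
#'   merged score columns
#' @export
dipeptide_database <- function(scores = NULL, pka_table = default_pka_table(),
                               scale = kyte_doolittle()) {
  seqs <- enumerate_dipeptides()
  db <- data.frame(
    sequence = seqs,
    mw_da = molecular_weight(seqs),
    pi = vapply(seqs, isoelectric_point, numeric(1), table = pka_table,
                USE.NAMES = FALSE),
    net_charge_ph7 = vapply(seqs, net_charge, numeric(1), pH = 7,
                            table = pka_table, USE.NAMES = FALSE),
    hydrophobicity = hydrophobicity(seqs, scale),
    stringsAsFactors = FALSE)
  db$acidic <- db$pi < 7.0
  db$hydrophilic <- db$hydrophobicity < 0
  if (!is.null(scores)) {
    stopifnot("sequence" %in% names(scores))
    keep <- intersect(c("umami_prob", "e_t1r1_kcal", "e_t1r3_kcal"),
                      names(scores))
    idx <- match(db$sequence, scores$sequence)
    for (col in keep) db[[col]] <- scores[[col]][idx]
  }
  db
}

#' Screen dipeptide records by docking energy and umami probability
#'
#' Applies the binding-energy threshold (pass when energy <= threshold, i.e.
#' at least as favourable as -6.5 kcal/mol by default) per pocket and the
#' umami-probability threshold (pass when probability >= threshold).  Records
#' lacking a score are excluded from that filter and counted separately.
#'
#' @param records data.frame as from \code{\link{dipeptide_database}}
#' @param energy_threshold kcal/mol, default -6.5
#' @param umami_threshold probability fraction, default 0.85
#' @return list with \code{pass_t1r1}, \code{pass_t1r3}, \code{pass_joint},
#'   \code{pass_umami}, \code{acidic_hydrophilic} (character vectors of
#'   sequences) and \code{summary} (counts and fractions)
#' @export
screen_dipeptides <- function(records, energy_threshold = -6.5,
                              umami_threshold = 0.85) {
  n <- nrow(records)
  pick <- function(col, test) {
    if (is.null(records[[col]]) || n == 0L) return(character(0))
    v <- records[[col]]
    records$sequence[!is.na(v) & test(v)]
  }
  # scores are compared at 0.1 kcal/mol input precision: "<= threshold"
  p1 <- pick("e_t1r1_kcal", function(v) round(v, 1) <= energy_threshold)
  p3 <- pick("e_t1r3_kcal", function(v) round(v, 1) <= energy_threshold)
  pu <- pick("umami_prob", function(v) v >= umami_threshold)
  joint <- intersect(p1, p3)
  ah <- if (n) records$sequence[records$acidic & records$hydrophilic]
        else character(0)
  missing_scores <- if (n) vapply(
    c("e_t1r1_kcal", "e_t1r3_kcal", "umami_prob"),
    function(col) if (is.null(records[[col]])) n else sum(is.na(records[[col]])),
    numeric(1)) else c(e_t1r1_kcal = 0, e_t1r3_kcal = 0, umami_prob = 0)
  n_scored <- function(col) {
    if (is.null(records[[col]]) || n == 0L) return(0L)
    sum(!is.na(records[[col]]))
  }
  ns <- c(n1 = n_scored("e_t1r1_kcal"), n3 = n_scored("e_t1r3_kcal"),
          nu = n_scored("umami_prob"))
  counts <- c(n = n, pass_t1r1 = length(p1), pass_t1r3 = length(p3),
              pass_joint = length(joint), pass_umami = length(pu),
              acidic_hydrophilic = length(ah))
  # fractions over the records carrying the relevant score(s)
  denom <- c(n, ns[["n1"]], ns[["n3"]], min(ns[["n1"]], ns[["n3"]]),
             ns[["nu"]], n)
  summary <- data.frame(
    metric = names(counts), count = as.integer(counts),
    n_scored = as.integer(denom),
    fraction = ifelse(denom > 0, unname(counts) / denom, NA_real_),
    stringsAsFactors = FALSE)
  list(pass_t1r1 = p1, pass_t1r3 = p3, pass_joint = joint, pass_umami = pu,
       acidic_hydrophilic = ah, summary = summary,
       missing_scores = missing_scores)
}
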
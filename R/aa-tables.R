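# Reference tables: amino-acid codes, masses, ionizable-group pKa values,
# hydropathy, residue atom templates, element vdW radii and LJ parameters.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetically ordered one-letter codes of the 20 standard amino acids.
#' @return Character vector of length 20.
#' @export
amino_acid_codes <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# average masses of the free amino acids (Da)
.aa_mass <- c(
  A = 89.09,  C = 121.16, D = 133.10, E = 147.13, F = 165.19,
  G = 75.07,  H = 155.15, I = 131.17, K = 146.19, L = 131.17,
  M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
  S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19)

.water_mass <- 18.02

.aa_three <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Default pKa table for dipeptide ionizable groups
#'
#' Model pKa values for the alpha-amino and alpha-carboxyl termini and the
#' seven ionizable side chains (D, E, H, C, Y, K, R).  \code{sign} is the
#' charge the group carries when it holds its proton-coupled charge state:
#' +1 for basic groups (positively charged when protonated), -1 for acidic
#' groups (negatively charged when deprotonated).  This widely used model set
#' reproduces the printed isoelectric point of Glu-Lys (6.41) and the
#' database-wide minimum net charge at pH 7 (-2.02).
#'
#' @return A data.frame with columns \code{group}, \code{pka}, \code{sign}.
#' @export
default_pka_table <- function() {
  data.frame(
    group = c("Nterm", "Cterm", "D", "E", "H", "C", "Y", "K", "R"),
    pka   = c(8.6,     3.6,     3.9, 4.1, 6.5, 8.5, 10.1, 10.8, 12.5),
    sign  = c(1L,     -1L,     -1L, -1L,  1L, -1L, -1L,   1L,   1L),
    stringsAsFactors = FALSE)
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; positive = hydrophobic, negative =
#' hydrophilic.  Dipeptide hydrophobicity is the sum over the two residues.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Element van der Waals radii
#'
#' Standard element radii used for channel profiling, SASA and density
#' grids (Angstrom).
#' @return Named numeric vector.
#' @export
element_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, X = 1.70)
}

# Lennard-Jones well depth (kcal/mol) and Rmin/2 (Angstrom) per element,
# Amber-style generic atom classes.
.lj_table <- data.frame(
  element   = c("H",    "C",    "N",    "O",    "S"),
  epsilon   = c(0.0157, 0.0860, 0.1700, 0.2100, 0.2500),
  rmin_half = c(1.387,  1.908,  1.824,  1.661,  2.000),
  stringsAsFactors = FALSE)

#' Bundled Lennard-Jones parameter table
#'
#' Element-class 12-6 parameters (well depth kcal/mol, Rmin/2 Angstrom) used
#' by \code{\link{vdw_interaction}} with Lorentz-Berthelot combination.
#' @return data.frame with columns element, epsilon, rmin_half.
#' @export
lj_parameters <- function() .lj_table

# side-chain heavy atoms (path order) and attached-hydrogen counts, per residue
.side_atoms <- list(
  A = c(CB = 3),
  R = c(CB = 2, CG = 2, CD = 2, NE = 1, CZ = 0, NH1 = 2, NH2 = 1),
  N = c(CB = 2, CG = 0, OD1 = 0, ND2 = 2),
  D = c(CB = 2, CG = 0, OD1 = 0, OD2 = 1),
  C = c(CB = 2, SG = 1),
  E = c(CB = 2, CG = 2, CD = 0, OE1 = 0, OE2 = 1),
  Q = c(CB = 2, CG = 2, CD = 0, OE1 = 0, NE2 = 2),
  G = c(),
  H = c(CB = 2, CG = 0, ND1 = 1, CD2 = 1, CE1 = 1, NE2 = 0),
  I = c(CB = 1, CG1 = 2, CG2 = 3, CD1 = 3),
  L = c(CB = 2, CG = 1, CD1 = 3, CD2 = 3),
  K = c(CB = 2, CG = 2, CD = 2, CE = 2, NZ = 2),
  M = c(CB = 2, CG = 2, SD = 0, CE = 3),
  F = c(CB = 2, CG = 0, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 1),
  P = c(CB = 2, CG = 2, CD = 2),
  S = c(CB = 2, OG = 1),
  T = c(CB = 1, OG1 = 1, CG2 = 3),
  W = c(CB = 2, CG = 0, CD1 = 1, CD2 = 0, NE1 = 1, CE2 = 0, CE3 = 1,
        CZ2 = 1, CZ3 = 1, CH2 = 1),
  Y = c(CB = 2, CG = 0, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 0, OH = 1),
  V = c(CB = 1, CG1 = 3, CG2 = 3))

# coarse Amber-style partial charges keyed by atom role; residues are
# neutralised by spreading the residual charge over side-chain carbons
.default_charge <- function(name, element) {
  if (name == "N") return(-0.42)
  if (name == "CA") return(0.03)
  if (name == "C") return(0.60)
  if (name %in% c("O", "OXT")) return(-0.57)
  if (element == "O") return(-0.55)
  if (element == "N") return(-0.60)
  if (element == "S") return(-0.30)
  if (element == "H") return(0.10)
  -0.05
}

# element inferred from a PDB atom name (digits stripped, first letter)
.element_from_name <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  first <- toupper(substr(nm, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "H", "P", "F"), first, "X")
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) != 2L)
    stop("sequence must be a single two-letter code", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, amino_acid_codes())
  if (length(bad))
    stop("unknown residue code: ", paste(bad, collapse = ", "), call. = FALSE)
  res
}
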
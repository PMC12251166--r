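# Interaction analytics: geometric hydrogen-bond detection and occupancy,
# contact-residue fingerprints, Shrake-Rupley SASA, pocket hydrophobicity
# and pocket water counting.

.aa_one <- setNames(names(.aa_three), unname(.aa_three))

# indices of hydrogens within bond distance of each donor heavy atom
.attached_hydrogens <- function(xyz, elements, donor_idx, hmax = 1.3) {
  h_idx <- which(elements == "H")
  lapply(donor_idx, function(d) {
    if (!length(h_idx)) return(integer(0))
    dd <- sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - xyz[d, ])^2))
    h_idx[dd <= hmax]
  })
}

#' Detect hydrogen bonds in one conformation
#'
#' A donor-acceptor pair forms a hydrogen bond when the donor-acceptor
#' distance is below 3.5 Angstrom and the angle at the hydrogen vertex
#' between the donor and the acceptor exceeds 135 degrees.  Donors default
#' to N/O/S atoms carrying a hydrogen within bonding distance; acceptors to
#' all N/O/S atoms.  Donors without an attached hydrogen are skipped with a
#' warning.
#'
#' @param x a \code{structure_model}, or an n x 3 matrix with \code{topology}
#' @param donors,acceptors atom indices; NULL for automatic classification
#' @param dist_cut donor-acceptor distance criterion (Angstrom)
#' @param angle_cut donor-hydrogen-acceptor angle criterion (degrees)
#' @param topology required when \code{x} is a bare coordinate matrix
#' @return data.frame with donor, hydrogen, acceptor (atom keys and
#'   indices), distance (Angstrom) and angle (degrees); zero rows when none
#' @export
detect_hbonds <- function(x, donors = NULL, acceptors = NULL,
                          dist_cut = 3.5, angle_cut = 135,
                          topology = NULL) {
  if (inherits(x, "structure_model")) {
    topology <- x
    xyz <- coords(x)
  } else {
    stopifnot(inherits(topology, "structure_model"))
    xyz <- as.matrix(x)
  }
  a <- topology$atoms
  polar <- which(a$element %in% c("N", "O", "S"))
  if (is.null(acceptors)) acceptors <- polar
  hyd_by_donor <- NULL
  if (is.null(donors)) {
    hyd_by_donor <- .attached_hydrogens(xyz, a$element, polar)
    donors <- polar[lengths(hyd_by_donor) > 0]
    hyd_by_donor <- hyd_by_donor[lengths(hyd_by_donor) > 0]
  } else {
    hyd_by_donor <- .attached_hydrogens(xyz, a$element, donors)
    dry <- lengths(hyd_by_donor) == 0
    if (any(dry)) {
      warning("donor(s) without attached hydrogen skipped: ",
              paste(a$name[donors[dry]], collapse = ", "), call. = FALSE)
      donors <- donors[!dry]
      hyd_by_donor <- hyd_by_donor[!dry]
    }
  }
  key <- function(i) paste0(a$chain[i], "_", a$resno[i], "_", a$name[i])
  out <- list()
  for (di in seq_along(donors)) {
    d <- donors[di]
    for (acc in setdiff(acceptors, d)) {
      r_da <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
      if (r_da >= dist_cut) next
      for (h in hyd_by_donor[[di]]) {
        if (h == acc) next
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[acc, ] - xyz[h, ]
        cang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cang))) * 180 / pi
        if (ang > angle_cut) {
          out[[length(out) + 1L]] <- data.frame(
            donor = key(d), hydrogen = key(h), acceptor = key(acc),
            donor_idx = d, hydrogen_idx = h, acceptor_idx = acc,
            distance = r_da, angle = ang, stringsAsFactors = FALSE)
          break  # one bond per donor-acceptor pair
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = character(0), hydrogen = character(0),
                      acceptor = character(0), donor_idx = integer(0),
                      hydrogen_idx = integer(0), acceptor_idx = integer(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames in which each donor-acceptor pair satisfies the
#' geometric criteria; pairs at or above \code{min_occupancy} are retained
#' (the conventional stability filter keeps bonds present in more than 45
#' percent of frames).
#'
#' @param traj a \code{trajectory}
#' @param donors,acceptors atom indices (NULL = automatic)
#' @param min_occupancy retention threshold, default 0.45
#' @param dist_cut,angle_cut geometric criteria
#' @return data.frame with donor, acceptor, n_frames_bound, occupancy,
#'   filtered to \code{occupancy >= min_occupancy}; attribute
#'   \code{"full_table"} holds every pair observed at least once
#' @export
hbond_occupancy <- function(traj, donors = NULL, acceptors = NULL,
                            min_occupancy = 0.45, dist_cut = 3.5,
                            angle_cut = 135) {
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames", call. = FALSE)
  tally <- new.env(parent = emptyenv())
  for (k in seq_len(nf)) {
    hb <- suppressWarnings(
      detect_hbonds(frame_coords(traj, k), donors, acceptors, dist_cut,
                    angle_cut, topology = traj$topology))
    if (nrow(hb) == 0) next
    for (pair in unique(paste(hb$donor, hb$acceptor, sep = "|"))) {
      tally[[pair]] <- (if (is.null(tally[[pair]])) 0L else tally[[pair]]) + 1L
    }
  }
  pairs <- ls(tally)
  if (!length(pairs)) {
    empty <- data.frame(donor = character(0), acceptor = character(0),
                        n_frames_bound = integer(0), occupancy = numeric(0),
                        stringsAsFactors = FALSE)
    attr(empty, "full_table") <- empty
    return(empty)
  }
  counts <- vapply(pairs, function(p) tally[[p]], integer(1))
  parts <- strsplit(pairs, "|", fixed = TRUE)
  full <- data.frame(
    donor = vapply(parts, `[`, character(1), 1),
    acceptor = vapply(parts, `[`, character(1), 2),
    n_frames_bound = unname(counts),
    occupancy = unname(counts) / nf, stringsAsFactors = FALSE)
  full <- full[order(-full$occupancy, full$donor), , drop = FALSE]
  rownames(full) <- NULL
  kept <- full[full$occupancy >= min_occupancy, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "full_table") <- full
  kept
}

#' Receptor residues contacting a ligand
#'
#' Receptor residues with any heavy atom within \code{cutoff} of any ligand
#' heavy atom.  Each contact residue is classed \code{"hydrogen-bond"} when
#' a hydrogen bond fires between it and the ligand, \code{"hydrophobic"}
#' when all its contacts are apolar-apolar (C/S on both sides), and
#' \code{"polar"} otherwise.
#'
#' @param structure a \code{structure_model} holding the complex
#' @param receptor_sel,ligand_sel atom index vectors
#' @param cutoff heavy-atom contact distance (Angstrom), default 4.0
#' @return data.frame with residue, resname, class, min_distance
#' @export
contact_residues <- function(structure, receptor_sel, ligand_sel,
                             cutoff = 4.0) {
  if (!length(receptor_sel) || !length(ligand_sel))
    stop("receptor and ligand selections must be nonempty", call. = FALSE)
  a <- structure$atoms
  xyz <- coords(structure)
  rh <- receptor_sel[a$element[receptor_sel] != "H"]
  lh <- ligand_sel[a$element[ligand_sel] != "H"]
  if (!length(rh) || !length(lh))
    return(data.frame(residue = character(0), resname = character(0),
                      class = character(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE))
  dmat <- sqrt(outer(rowSums(xyz[rh, , drop = FALSE]^2),
                     rowSums(xyz[lh, , drop = FALSE]^2), "+") -
               2 * xyz[rh, , drop = FALSE] %*% t(xyz[lh, , drop = FALSE]))
  hits <- which(dmat <= cutoff, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(residue = character(0), resname = character(0),
                      class = character(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE))
  hb <- detect_hbonds(structure)
  hb_res <- character(0)
  if (nrow(hb)) {
    don_lig <- hb$donor_idx %in% ligand_sel | hb$acceptor_idx %in% ligand_sel
    rec_side <- ifelse(hb$donor_idx %in% ligand_sel, hb$acceptor_idx,
                       hb$donor_idx)
    hb_res <- unique(paste0(a$chain[rec_side[don_lig]], "_",
                            a$resno[rec_side[don_lig]]))
  }
  res_key <- paste0(a$chain[rh[hits[, 1]]], "_", a$resno[rh[hits[, 1]]])
  apolar <- a$element[rh[hits[, 1]]] %in% c("C", "S") &
            a$element[lh[hits[, 2]]] %in% c("C", "S")
  out <- lapply(unique(res_key), function(rk) {
    sub <- res_key == rk
    cls <- if (rk %in% hb_res) "hydrogen-bond"
           else if (all(apolar[sub])) "hydrophobic" else "polar"
    i1 <- rh[hits[sub, 1][1]]
    data.frame(residue = rk, resname = a$resname[i1], class = cls,
               min_distance = min(dmat[hits[sub, , drop = FALSE]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# deterministic near-uniform sphere points (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA by sphere-point sampling: for each atom, test points on the
#' sphere of radius vdw + probe count as accessible when outside every
#' neighbouring atom's expanded sphere.
#'
#' @param structure a \code{structure_model} (vdW radii required)
#' @param probe probe radius (Angstrom), default 1.4 (water)
#' @param n_points sample points per atom, default 960
#' @param sel atom indices to include (default all); excluded atoms do not
#'   occlude
#' @return list with \code{atom_area} (Angstrom^2 per included atom, named
#'   by index) and \code{total}
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, sel = NULL) {
  a <- structure$atoms
  if (is.null(sel)) sel <- seq_len(nrow(a))
  if (anyNA(a$vdw[sel]))
    stop("missing vdW radius for atom ", a$name[sel[is.na(a$vdw[sel])][1]],
         call. = FALSE)
  xyz <- coords(structure)[sel, , drop = FALSE]
  rad <- a$vdw[sel] + probe
  pts <- .sphere_points(n_points)
  n <- length(sel)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    d2 <- outer(rowSums(p^2), rowSums(xyz^2), "+") - 2 * p %*% t(xyz)
    d2[, i] <- Inf
    buried <- rowSums(sweep(d2, 2, rad^2, "<")) > 0
    areas[i] <- 4 * pi * rad[i]^2 * mean(!buried)
  }
  names(areas) <- sel
  list(atom_area = areas, total = sum(areas))
}

#' Pocket hydrophobicity score
#'
#' SASA-weighted mean hydropathy over pocket residues: each residue
#' contributes its hydropathy weighted by its solvent-exposed area within
#' the pocket, normalised by the total pocket SASA.  Positive values mark
#' hydrophobic pockets, negative hydrophilic ones; only sign and ordering
#' are meaningful, not absolute magnitudes.
#'
#' @param structure a \code{structure_model}
#' @param pocket_sel atom indices of the pocket lining
#' @param scale hydropathy scale (default Kyte-Doolittle)
#' @param probe,n_points SASA parameters
#' @return list with \code{score}, \code{residue_table} (residue, exposure,
#'   hydropathy)
#' @export
pocket_hydrophobicity <- function(structure, pocket_sel,
                                  scale = kyte_doolittle(), probe = 1.4,
                                  n_points = 240) {
  if (!length(pocket_sel)) stop("pocket selection is empty", call. = FALSE)
  a <- structure$atoms
  sa <- sasa(structure, probe = probe, n_points = n_points)
  res_key <- paste0(a$chain[pocket_sel], "_", a$resno[pocket_sel])
  per_res <- tapply(sa$atom_area[as.character(pocket_sel)], res_key, sum)
  rn <- vapply(names(per_res), function(rk) {
    i <- pocket_sel[res_key == rk][1]
    a$resname[i]
  }, character(1))
  hyd <- scale[.aa_one[rn]]
  hyd[is.na(hyd)] <- 0
  w <- as.numeric(per_res)
  score <- if (sum(w) > 0) sum(w * hyd) / sum(w) else mean(hyd)
  list(score = score,
       residue_table = data.frame(residue = names(per_res), resname = rn,
                                  exposure = w, hydropathy = unname(hyd),
                                  stringsAsFactors = FALSE))
}

#' Count pocket water molecules per frame
#'
#' Number of water oxygens (residue name HOH/WAT/SOL) within \code{cutoff}
#' of any pocket heavy atom, per frame, plus the mean over the final quarter
#' of frames (the converged tail).
#'
#' @param traj a \code{trajectory} whose topology includes waters
#' @param pocket_sel atom indices of pocket residues
#' @param cutoff Angstrom, default 5.0
#' @param tail_fraction fraction of final frames for the tail mean
#' @return list with \code{counts} (per frame) and \code{tail_mean}
#' @export
count_pocket_waters <- function(traj, pocket_sel, cutoff = 5.0,
                                tail_fraction = 0.25) {
  a <- traj$topology$atoms
  wat <- which(a$resname %in% c("HOH", "WAT", "SOL") & a$element == "O")
  pk <- pocket_sel[a$element[pocket_sel] != "H"]
  nf <- n_frames(traj)
  if (!length(wat)) {
    warning("no water molecules in topology", call. = FALSE)
    return(list(counts = rep(0L, nf), tail_mean = 0))
  }
  counts <- vapply(seq_len(nf), function(k) {
    xyz <- frame_coords(traj, k)
    dmat <- sqrt(outer(rowSums(xyz[wat, , drop = FALSE]^2),
                       rowSums(xyz[pk, , drop = FALSE]^2), "+") -
                 2 * xyz[wat, , drop = FALSE] %*% t(xyz[pk, , drop = FALSE]))
    sum(apply(dmat, 1, min) <= cutoff)
  }, numeric(1))
  tail_n <- max(1L, ceiling(tail_fraction * nf))
  list(counts = as.integer(counts),
       tail_mean = mean(counts[(nf - tail_n + 1L):nf]))
}
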
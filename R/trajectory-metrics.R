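# Trajectory analytics: RMSD series, per-residue RMSF, flexibility
# correlation, threshold clustering with lowest-energy representatives,
# and snapshot accounting.

#' Per-frame RMSD after Kabsch superposition
#'
#' Each frame is superposed onto the reference over the selection, then
#' RMSD = sqrt(mean squared atom offset) is evaluated over the same
#' selection.
#'
#' @param traj a \code{trajectory}
#' @param reference n x 3 matrix or \code{structure_model} (default: the
#'   trajectory topology)
#' @param sel atom indices (default: all)
#' @return numeric vector, Angstrom per frame
#' @export
rmsd_series <- function(traj, reference = NULL, sel = NULL) {
  if (is.null(reference)) reference <- traj$topology
  ref <- if (inherits(reference, "structure_model")) coords(reference)
         else as.matrix(reference)
  if (is.null(sel)) sel <- seq_len(dim(traj$frames)[2])
  if (length(sel) == 0) stop("selection is empty", call. = FALSE)
  if (max(sel) > nrow(ref)) stop("selection exceeds topology", call. = FALSE)
  vapply(seq_len(n_frames(traj)), function(k) {
    kabsch_superpose(frame_coords(traj, k, sel), ref[sel, , drop = FALSE])$rmsd
  }, numeric(1))
}

#' Per-residue RMSF profile
#'
#' Frames are superposed onto their mean structure (mean recomputed and the
#' superposition iterated twice), then RMSF_i = sqrt(mean |r_i - <r_i>|^2)
#' per selected atom; atoms are reported under their residue key.  The
#' conventional selection is the C-alpha trace.
#'
#' @param traj a \code{trajectory}
#' @param sel atom indices; default: the CA atoms of the topology
#' @return data.frame with columns \code{residue} (chain_resno),
#'   \code{resname} and \code{rmsf} (Angstrom); class
#'   \code{flexibility_profile}
#' @export
rmsf_profile <- function(traj, sel = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames", call. = FALSE)
  if (is.null(sel)) {
    sel <- atom_select(traj$topology, name = "CA")
    if (length(sel) == 0) sel <- seq_len(dim(traj$frames)[2])
  }
  nf <- n_frames(traj)
  stack <- lapply(seq_len(nf), function(k) frame_coords(traj, k, sel))
  mean_xyz <- Reduce(`+`, stack) / nf
  for (it in 1:2) {
    stack <- lapply(stack, function(m) kabsch_superpose(m, mean_xyz)$fitted)
    mean_xyz <- Reduce(`+`, stack) / nf
  }
  dev2 <- Reduce(`+`, lapply(stack, function(m) rowSums((m - mean_xyz)^2))) / nf
  a <- traj$topology$atoms[sel, , drop = FALSE]
  out <- data.frame(residue = paste0(a$chain, "_", a$resno),
                    resname = a$resname, rmsf = sqrt(dev2),
                    stringsAsFactors = FALSE)
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' Flexibility correlation between two RMSF profiles
#'
#' Pearson correlation R and ordinary least-squares slope k of profile b
#' regressed on profile a, over the shared residue keys.
#'
#' @param profile_a,profile_b \code{flexibility_profile} objects (or data
#'   frames with \code{residue} and \code{rmsf})
#' @return list with \code{r}, \code{k}, \code{n_shared} and the merged
#'   table
#' @export
flexibility_correlation <- function(profile_a, profile_b) {
  shared <- intersect(profile_a$residue, profile_b$residue)
  if (length(shared) < 3)
    stop("fewer than 3 shared residues", call. = FALSE)
  a <- profile_a$rmsf[match(shared, profile_a$residue)]
  b <- profile_b$rmsf[match(shared, profile_b$residue)]
  fit <- lm(b ~ a)
  list(r = cor(a, b), k = unname(coef(fit)[2]), n_shared = length(shared),
       table = data.frame(residue = shared, rmsf_a = a, rmsf_b = b,
                          stringsAsFactors = FALSE))
}

#' Threshold clustering of trajectory frames
#'
#' Greedy leader clustering under the pairwise criterion: two conformations
#' belong to the same cluster when their C-alpha RMSD after superposition is
#' at or below the threshold.  Frames are visited in file order; a frame
#' joins the first existing cluster whose seed frame is within the
#' threshold, otherwise it founds a new cluster.  The representative of each
#' cluster is its lowest-potential-energy frame (ties broken by lowest frame
#' index; uniform energies assumed when the trajectory carries none).
#'
#' @param traj a \code{trajectory}
#' @param threshold_nm clustering threshold in nm (default 0.5, the
#'   conventional value for receptor-scale ensembles)
#' @param sel atom indices used for the RMSD (default: C-alpha atoms)
#' @return object of class \code{cluster_result}: list with
#'   \code{labels} (per frame), \code{seeds}, \code{representatives},
#'   \code{threshold_nm} and \code{n_clusters}
#' @export
cluster_threshold <- function(traj, threshold_nm = 0.5, sel = NULL) {
  if (threshold_nm <= 0) stop("threshold must be positive", call. = FALSE)
  if (is.null(sel)) {
    sel <- atom_select(traj$topology, name = "CA")
    if (length(sel) == 0) sel <- seq_len(dim(traj$frames)[2])
  }
  thr_a <- threshold_nm * 10  # nm -> Angstrom
  nf <- n_frames(traj)
  labels <- integer(nf)
  seeds <- integer(0)
  seed_xyz <- list()
  for (k in seq_len(nf)) {
    xyz <- frame_coords(traj, k, sel)
    placed <- FALSE
    for (c in seq_along(seeds)) {
      if (kabsch_superpose(xyz, seed_xyz[[c]])$rmsd <= thr_a) {
        labels[k] <- c; placed <- TRUE; break
      }
    }
    if (!placed) {
      seeds <- c(seeds, k)
      seed_xyz[[length(seeds)]] <- xyz
      labels[k] <- length(seeds)
    }
  }
  energy <- traj$energy
  if (is.null(energy)) energy <- rep(0, nf)
  reps <- vapply(seq_along(seeds), function(c) {
    members <- which(labels == c)
    members[which.min(energy[members])]
  }, integer(1))
  structure(list(labels = labels, seeds = seeds, representatives = reps,
                 threshold_nm = threshold_nm, n_clusters = length(seeds)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$n_clusters, "clusters over", length(x$labels),
      "frames (threshold", x$threshold_nm, "nm)\n")
  invisible(x)
}

#' Export cluster representatives as a multi-model PDB
#'
#' @param traj the clustered \code{trajectory}
#' @param clusters a \code{cluster_result}
#' @param path output PDB path
#' @return \code{path}, invisibly
#' @export
write_representatives <- function(traj, clusters, path) {
  reps <- clusters$representatives
  frames <- traj$frames[reps, , , drop = FALSE]
  write_pdb(trajectory(traj$topology, frames), path)
}

#' Snapshot count of a sampled MD run
#'
#' Number of conformations collected when saving every
#' \code{save_interval_steps} integration steps of \code{timestep_fs} over
#' \code{duration_ns}: floor(duration / (interval x timestep)).  200 ns
#' saved every 5000 steps of 2 fs yields 20,000 snapshots.
#'
#' @param duration_ns simulated time (ns)
#' @param save_interval_steps steps between saved snapshots
#' @param timestep_fs integration timestep (fs)
#' @return integer snapshot count
#' @export
snapshot_count <- function(duration_ns, save_interval_steps, timestep_fs) {
  if (duration_ns <= 0 || save_interval_steps <= 0 || timestep_fs <= 0)
    stop("all arguments must be positive", call. = FALSE)
  as.integer(floor(duration_ns * 1e6 / (save_interval_steps * timestep_fs)))
}
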
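# Independent oracles used across the suite: quaternion-grid rigid-body
# RMSD minimisation, Henderson-Hasselbalch grid scan for pI, spherical-cap
# SASA closed form, and small geometry builders.

# rotation matrix from a unit quaternion (w, x, y, z)
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

# brute-force minimum RMSD over rotations: seeded uniform quaternion cloud,
# then shrinking perturbation rounds around the incumbent
oracle_min_rmsd <- function(mobile, reference, n_per_round = 1500) {
  A <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  B <- sweep(as.matrix(reference), 2, colMeans(reference))
  rmsd_of <- function(q) {
    R <- quat_to_mat(q / sqrt(sum(q^2)))
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  set.seed(99)
  best_q <- c(1, 0, 0, 0)
  best <- rmsd_of(best_q)
  for (i in seq_len(n_per_round)) {
    q <- rnorm(4)
    v <- rmsd_of(q)
    if (v < best) { best <- v; best_q <- q / sqrt(sum(q^2)) }
  }
  for (scale in c(0.2, 0.05, 0.01, 0.002)) {
    for (i in seq_len(n_per_round)) {
      dq <- c(1, rnorm(3) * scale)
      q <- quat_mult(best_q, dq / sqrt(sum(dq^2)))
      v <- rmsd_of(q)
      if (v < best) { best <- v; best_q <- q }
    }
  }
  best
}

# pI by dense grid scan for the sign change of the net charge
oracle_pi_grid <- function(sequence, table = default_pka_table(),
                           step = 1e-4) {
  res <- strsplit(sequence, "")[[1]]
  groups <- c("Nterm", "Cterm", res[res %in% table$group])
  idx <- match(groups, table$group)
  pka <- table$pka[idx]; sgn <- table$sign[idx]
  ph <- seq(0, 14, by = step)
  q <- rowSums(vapply(seq_along(pka), function(g) {
    if (sgn[g] > 0) 1 / (1 + 10^(ph - pka[g]))
    else -1 / (1 + 10^(pka[g] - ph))
  }, numeric(length(ph))))
  i <- which(q < 0)[1]
  (ph[i - 1] + ph[i]) / 2
}

# accessible area of two overlapping spheres (radii inflated by the probe)
oracle_two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  cap <- function(Ra, Rb) {
    x <- (d^2 + Ra^2 - Rb^2) / (2 * d)
    2 * pi * Ra * (Ra - x)
  }
  4 * pi * R1^2 - cap(R1, R2) + 4 * pi * R2^2 - cap(R2, R1)
}

# bare structure from a coordinate matrix (one pseudo-residue per atom)
cloud_structure <- function(xyz, element = "C", resname = "GLY") {
  n <- nrow(xyz)
  structure_model(data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), element = element,
    resname = resname, resno = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# trajectory from a list of coordinate matrices
frames_trajectory <- function(topology, frame_list, energy = NULL) {
  nf <- length(frame_list)
  na <- nrow(frame_list[[1]])
  fr <- array(NA_real_, c(nf, na, 3))
  for (k in seq_len(nf)) fr[k, , ] <- frame_list[[k]]
  trajectory(topology, fr, energy = energy)
}

# donor(N)-hydrogen-acceptor(O) triad with prescribed donor-acceptor
# distance and donor-hydrogen-acceptor angle (degrees); D-H = 1.0 A
hbond_triad <- function(d_da, angle_deg) {
  ang <- angle_deg * pi / 180
  # law of cosines for H-A given D-H = 1 and angle at H
  ca <- cos(ang)
  r_ha <- ca + sqrt(pmax(ca^2 + d_da^2 - 1, 0))
  acc <- c(1 - r_ha * ca, r_ha * sin(ang), 0)
  structure_model(data.frame(
    serial = 1:3, name = c("N", "HN", "O"), element = c("N", "H", "O"),
    resname = "GLY", resno = c(1L, 1L, 2L), chain = "A",
    x = c(0, 1, acc[1]), y = c(0, 0, acc[2]), z = 0,
    stringsAsFactors = FALSE))
}
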
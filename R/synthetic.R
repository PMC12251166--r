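# Synthetic inputs with planted ground truth: dipeptide structures,
# Gaussian-fluctuation trajectories, pore-lining channel structures,
# hydrogen-bond trajectories and docking/umami score tables.

# run expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic side-chain path: a gentle helix descending from CA so that
# consecutive template atoms sit ~1.5 A apart and branches do not collide
.side_chain_coords <- function(ca, n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  j <- seq_len(n)
  t(vapply(j, function(k)
    ca + c(1.05 * cos(1.9 * k), -1.25 * k, 1.05 * sin(1.9 * k)),
    numeric(3)))
}

#' Build an idealised all-atom dipeptide structure
#'
#' Constructs a 3-D model of a dipeptide from internal-coordinate templates
#' with standard bond lengths and angles: extended backbone, free N-terminal
#' amine and C-terminal carboxyl (with OXT), side chains on a deterministic
#' helical path, and hydrogens attached to their parent heavy atoms.  A tiny
#' seeded jitter (0.02 Angstrom) decorrelates different seeds without
#' affecting topology.  Coarse Amber-style partial charges are assigned and
#' each molecule is neutralised.
#'
#' @param sequence two one-letter residue codes, e.g. "DG"
#' @param seed integer seed
#' @return a \code{structure_model} with element, vdW radius and charge set
#' @export
make_dipeptide_structure <- function(sequence, seed = 1L) {
  res <- .check_sequence(sequence)
  rows <- list()
  add <- function(name, element, resname, resno, xyz, nh = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname, resno = resno,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    if (nh > 0) {
      for (h in seq_len(nh)) {
        hx <- xyz + 1.09 * c(cos(2.1 * h + xyz[1]), 0.35,
                             sin(2.1 * h + xyz[1])) / sqrt(1 + 0.35^2)
        rows[[length(rows) + 1L]] <<- data.frame(
          name = paste0("H", name, if (nh > 1) h else ""), element = "H",
          resname = resname, resno = resno,
          x = hx[1], y = hx[2], z = hx[3], stringsAsFactors = FALSE)
      }
    }
  }
  for (i in 1:2) {
    aa <- res[i]
    r3 <- .aa_three[[aa]]
    o <- c(3.45 * (i - 1), 1.77 * (i - 1), 0)
    N <- o; CA <- o + c(1.46, 0, 0); C <- o + c(2.22, 1.32, 0)
    O <- C + c(-0.52, 1.11, 0)
    add("N", "N", r3, i, N, nh = if (i == 1) 2 else 1)
    add("CA", "C", r3, i, CA, nh = if (aa == "G") 2 else 1)
    side <- .side_atoms[[aa]]
    if (length(side)) {
      sc <- .side_chain_coords(CA, length(side))
      for (k in seq_along(side))
        add(names(side)[k], .element_from_name(names(side)[k]), r3, i,
            sc[k, ], nh = side[[k]])
    }
    add("C", "C", r3, i, C)
    add("O", "O", r3, i, O)
    if (i == 2) {
      OXT <- C + c(1.18, -0.35, 0)
      add("OXT", "O", r3, i, OXT, nh = 1)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- "A"
  jitter <- .with_seed(seed,
    matrix(runif(3 * nrow(atoms), -0.02, 0.02), ncol = 3))
  atoms$x <- atoms$x + jitter[, 1]
  atoms$y <- atoms$y + jitter[, 2]
  atoms$z <- atoms$z + jitter[, 3]
  atoms$charge <- mapply(.default_charge, atoms$name, atoms$element)
  # neutralise each molecule
  atoms$charge <- atoms$charge - sum(atoms$charge) / nrow(atoms)
  structure_model(atoms)
}

#' Generate a Gaussian-fluctuation trajectory around a reference
#'
#' Each frame is the reference plus independent isotropic Gaussian
#' displacements with per-atom, per-axis standard deviation \code{sigma};
#' with \code{rigid_noise}, every frame additionally receives a random
#' global rotation and translation (removable by superposition).  Synthetic
#' per-frame potential energies are drawn from a seeded Gaussian so that
#' lowest-energy representative selection is deterministic.
#'
#' @param reference a \code{structure_model}
#' @param sigma per-atom displacement sd (Angstrom); length 1 or n_atoms
#' @param n_frames number of frames (>= 1)
#' @param rigid_noise add a random rigid transform per frame
#' @param seed integer seed
#' @param dt frame spacing (ps)
#' @return list with \code{trajectory} and planted \code{sigma}
#' @export
make_trajectory <- function(reference, sigma, n_frames, rigid_noise = FALSE,
                            seed = 1L, dt = 10) {
  na <- nrow(reference$atoms)
  sigma <- rep_len(sigma, na)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  ref <- coords(reference)
  out <- .with_seed(seed, {
    frames <- array(NA_real_, c(n_frames, na, 3))
    for (k in seq_len(n_frames)) {
      disp <- matrix(rnorm(3 * na, sd = rep(sigma, 3)), ncol = 3)
      xyz <- ref + disp
      if (rigid_noise) {
        ang <- runif(3, 0, 2 * pi)
        Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                                   0, 0, 1), 3, 3)
        Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                                   sin(a), 0, cos(a)), 3, 3)
        R <- Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3])
        xyz <- sweep(xyz %*% t(R), 2, runif(3, -5, 5), "+")
      }
      frames[k, , ] <- xyz
    }
    energy <- rnorm(n_frames, mean = -1000, sd = 25)
    list(frames = frames, energy = energy)
  })
  traj <- trajectory(reference, out$frames,
                     times = dt * (seq_len(n_frames) - 1),
                     energy = out$energy)
  list(trajectory = traj, sigma = sigma)
}

#' Generate a pore-lining channel structure with a planted radius profile
#'
#' Places rings of carbon pseudo-atoms (vdW 1.70 Angstrom) around the z
#' axis at 0.25 Angstrom stations so that the maximal inscribed sphere
#' centred on the axis at each station has the prescribed radius; the
#' profile between supplied control points is linearly interpolated.  Each
#' ring is its own residue so contact residues are identifiable.
#'
#' @param radius_profile data.frame or matrix with columns axial position
#'   (Angstrom, strictly increasing) and radius (> 0)
#' @param lining_density atoms per ring
#' @param seed integer seed (ring phase offsets)
#' @return list with \code{structure}, planted \code{stations},
#'   \code{radius} (per station) and \code{min_radius}/\code{min_station}
#' @export
make_channel_structure <- function(radius_profile, lining_density = 16,
                                   seed = 1L) {
  rp <- as.matrix(radius_profile)
  if (nrow(rp) < 2) stop("radius profile needs at least 2 stations",
                         call. = FALSE)
  z0 <- rp[, 1]; r0 <- rp[, 2]
  if (any(diff(z0) <= 0)) stop("axial positions must be strictly increasing",
                               call. = FALSE)
  if (any(r0 <= 0)) stop("radii must be positive", call. = FALSE)
  stations <- seq(z0[1], z0[length(z0)], by = 0.25)
  radius <- stats::approx(z0, r0, xout = stations)$y
  a <- element_vdw_radii()[["C"]]
  phases <- .with_seed(seed, runif(length(stations), 0, 2 * pi))
  rows <- lapply(seq_along(stations), function(k) {
    th <- phases[k] + 2 * pi * seq_len(lining_density) / lining_density
    R <- radius[k] + a
    data.frame(name = paste0("C", seq_len(lining_density)), element = "C",
               resname = "CHN", resno = k, chain = "A",
               x = R * cos(th), y = R * sin(th), z = stations[k],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  kmin <- which.min(radius)
  list(structure = structure_model(atoms), stations = stations,
       radius = radius, min_radius = radius[kmin],
       min_station = stations[kmin])
}

#' Generate a donor-H-acceptor trajectory with planted H-bond occupancy
#'
#' Builds a three-atom system (amide N donor with its hydrogen, carbonyl O
#' acceptor in a second residue) whose geometry satisfies the hydrogen-bond
#' criteria (donor-acceptor distance < 3.5 Angstrom, donor-hydrogen-acceptor
#' angle > 135 degrees) in exactly \code{round(occupancy * n_frames)}
#' frames: bonded frames place the acceptor at 2.88 Angstrom on a
#' near-linear geometry, broken frames at 6 Angstrom.
#'
#' @param occupancy planted occupancy fraction in [0, 1]
#' @param n_frames number of frames (> 0)
#' @param seed integer seed (which frames are bonded, coordinate jitter)
#' @return list with \code{trajectory}, planted \code{bond_frames} (indices)
#'   and \code{occupancy}
#' @export
make_hbond_trajectory <- function(occupancy, n_frames, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be positive", call. = FALSE)
  if (occupancy < 0 || occupancy > 1)
    stop("occupancy must lie in [0, 1]", call. = FALSE)
  topo <- structure_model(data.frame(
    serial = 1:3,
    name = c("N", "HN", "O"),
    element = c("N", "H", "O"),
    resname = c("GLY", "GLY", "GLY"),
    resno = c(1L, 1L, 2L),
    chain = "A",
    x = c(0, 1.0, 2.835), y = c(0, 0, 0.492), z = 0,
    stringsAsFactors = FALSE))
  k <- round(occupancy * n_frames)
  out <- .with_seed(seed, {
    bonded <- sort(sample.int(n_frames, k))
    frames <- array(NA_real_, c(n_frames, 3, 3))
    for (f in seq_len(n_frames)) {
      xyz <- coords(topo)
      if (!(f %in% bonded)) xyz[3, ] <- c(6.0, 0.3, 0)  # broken: D-A = 6 A
      frames[f, , ] <- xyz + matrix(runif(9, -0.01, 0.01), 3, 3)
    }
    list(bonded = bonded, frames = frames)
  })
  traj <- trajectory(topo, out$frames, times = 10 * (seq_len(n_frames) - 1))
  list(trajectory = traj, bond_frames = out$bonded,
       occupancy = k / n_frames)
}

#' Generate a docking/umami score table with planted pass fractions
#'
#' Builds a synthetic score table in which exactly
#' \code{round(fraction_pass_energy * n)} records have T1R1 docking
#' energies at or below -6.5 kcal/mol (likewise for T1R3), exactly
#' \code{round(fraction_pass_umami * n)} have umami probability >= 0.85,
#' and the T1R1/T1R3 pass sets overlap in exactly
#' \code{round(overlap * n)} records when \code{overlap} is given.
#'
#' @param n number of records (<= 400 draws real dipeptide sequences)
#' @param fraction_pass_energy fraction passing the T1R1 energy threshold
#' @param fraction_pass_umami fraction passing the umami threshold
#' @param fraction_pass_energy_t1r3 fraction passing for T1R3 (defaults to
#'   \code{fraction_pass_energy})
#' @param overlap planted joint T1R1-and-T1R3 pass fraction, or NULL for
#'   maximal overlap
#' @param seed integer seed
#' @return list with \code{table} (data.frame: sequence, e_t1r1_kcal,
#'   e_t1r3_kcal, umami_prob) and planted pass index lists
#' @export
make_score_table <- function(n, fraction_pass_energy, fraction_pass_umami,
                             fraction_pass_energy_t1r3 = fraction_pass_energy,
                             overlap = NULL, seed = 1L) {
  fr <- c(fraction_pass_energy, fraction_pass_energy_t1r3,
          fraction_pass_umami)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  k1 <- round(fraction_pass_energy * n)
  k3 <- round(fraction_pass_energy_t1r3 * n)
  ku <- round(fraction_pass_umami * n)
  j <- if (is.null(overlap)) min(k1, k3) else round(overlap * n)
  if (j > min(k1, k3) || k1 + k3 - j > n)
    stop("overlap incompatible with pass fractions", call. = FALSE)
  set1 <- seq_len(k1)
  set3 <- if (k3 > 0) c(utils::head(set1, j),
                        setdiff(seq_len(n), set1)[seq_len(k3 - j)])
          else integer(0)
  setu <- seq_len(ku)
  .with_seed(seed, {
    seqs <- if (n <= 400) sample(enumerate_dipeptides(), n)
            else paste0("P", seq_len(n))
    e1 <- round(runif(n, -6.0, -3.0), 1)
    e3 <- round(runif(n, -6.0, -3.0), 1)
    e1[set1] <- round(runif(k1, -9.0, -6.6), 1)
    e3[set3] <- round(runif(length(set3), -9.0, -6.6), 1)
    up <- round(runif(n, 0.20, 0.84), 3)
    up[setu] <- round(runif(ku, 0.86, 0.99), 3)
    tab <- data.frame(sequence = seqs, e_t1r1_kcal = e1, e_t1r3_kcal = e3,
                      umami_prob = up, stringsAsFactors = FALSE)
    list(table = tab, pass_t1r1 = set1, pass_t1r3 = sort(set3),
         pass_joint = sort(intersect(set1, set3)), pass_umami = setu)
  })
}

#' Write planted ground truth to a JSON sidecar
#'
#' @param planted list of planted parameters (numeric/integer vectors)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_planted_json <- function(planted, path) {
  planted <- planted[!vapply(planted, is.object, logical(1))]
  jsonlite::write_json(planted, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
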
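# Reduced density gradient (NCI) analysis on a promolecular electron
# density: Slater-rule atomic shell densities (H-Kr), RDG per
# RDG = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3)), sign(lambda2) rho
# classification, and Gaussian cube import/export.

.BOHR <- 0.529177210903  # Angstrom per bohr

.element_symbols <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
  "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA",
  "SC", "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
  "GA", "GE", "AS", "SE", "BR", "KR")

.atomic_number <- function(element) {
  z <- match(toupper(element), .element_symbols)
  if (anyNA(z))
    stop("unsupported element (H-Kr required): ",
         paste(unique(element[is.na(z)]), collapse = ", "), call. = FALSE)
  z
}

# Slater-rule shell table for one atom: occupancy, principal n and
# effective exponent zeta (a.u.) per shell group
.slater_shells <- function(Z) {
  occ <- c(s1 = 0, sp2 = 0, sp3 = 0, d3 = 0, sp4 = 0)
  fill <- function(g, cap, left) {
    take <- min(cap - occ[[g]], left)
    occ[[g]] <<- occ[[g]] + take
    left - take
  }
  left <- Z
  left <- fill("s1", 2, left)
  left <- fill("sp2", 8, left)
  left <- fill("sp3", 8, left)
  if (left > 0) {            # 4s before 3d, then 3d, then 4p
    take <- min(2, left); occ[["sp4"]] <- take; left <- left - take
    left <- fill("d3", 10, left)
    left <- fill("sp4", 8, left)
  }
  if (Z == 24) { occ[["d3"]] <- 5; occ[["sp4"]] <- 1 }
  if (Z == 29) { occ[["d3"]] <- 10; occ[["sp4"]] <- 1 }
  n <- c(1, 2, 3, 3, 4)
  nstar <- c(1, 2, 3, 3, 3.7)
  inner1 <- occ[["s1"]]; inner2 <- occ[["sp2"]]; inner3 <- occ[["sp3"]]
  sigma <- c(
    0.30 * max(occ[["s1"]] - 1, 0),
    0.35 * max(occ[["sp2"]] - 1, 0) + 0.85 * inner1,
    0.35 * max(occ[["sp3"]] - 1, 0) + 0.85 * inner2 + 1.00 * inner1,
    0.35 * max(occ[["d3"]] - 1, 0) + 1.00 * (inner1 + inner2 + inner3),
    0.35 * max(occ[["sp4"]] - 1, 0) + 0.85 * (inner3 + occ[["d3"]]) +
      1.00 * (inner1 + inner2))
  keep <- occ > 0
  data.frame(n = n[keep], occ = unname(occ[keep]),
             zeta = pmax((Z - sigma[keep]) / nstar[keep], 0.1))
}

# spherically averaged atomic density (a.u.) at radius r (bohr)
.atomic_density <- function(Z, r) {
  sh <- .slater_shells(Z)
  rho <- numeric(length(r))
  for (k in seq_len(nrow(sh))) {
    n <- sh$n[k]; z <- sh$zeta[k]
    norm <- (2 * z)^(2 * n + 1) / (4 * pi * factorial(2 * n))
    rho <- rho + sh$occ[k] * norm * r^(2 * n - 2) * exp(-2 * z * r)
  }
  rho
}

#' Construct an empty scalar-field grid
#'
#' @param origin grid origin (Angstrom, length 3)
#' @param spacing voxel spacing (Angstrom; scalar or length 3)
#' @param dims voxel counts (nx, ny, nz)
#' @return object of class \code{scalar_field_grid}
#' @export
scalar_field_grid <- function(origin, spacing, dims) {
  spacing <- rep_len(spacing, 3)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims), rho = NULL, grad_norm = NULL,
                 lambda2 = NULL, rdg = NULL, atoms = NULL),
            class = "scalar_field_grid")
}

# voxel centre coordinates along each axis (Angstrom)
.grid_axes <- function(grid) {
  lapply(1:3, function(k)
    grid$origin[k] + grid$spacing[k] * (seq_len(grid$dims[k]) - 1))
}

#' Promolecular electron density on a grid
#'
#' rho(r) = sum over atoms of the spherically averaged free-atom density,
#' built from Slater-rule single-zeta shell densities (supported elements
#' H through Kr).  Each atomic density integrates exactly to the element's
#' electron count.  Densities are in atomic units (e / bohr^3); grid
#' geometry stays in Angstrom.
#'
#' @param structure a \code{structure_model}
#' @param origin,spacing,dims grid specification (Angstrom), or a prebuilt
#'   \code{scalar_field_grid} via \code{grid}
#' @param grid optional \code{scalar_field_grid} to fill
#' @return the grid with \code{rho} filled
#' @export
promolecular_density <- function(structure, origin = NULL, spacing = 0.1,
                                 dims = NULL, grid = NULL) {
  xyz <- coords(structure)
  if (is.null(grid)) {
    if (is.null(origin)) origin <- apply(xyz, 2, min) - 3
    if (is.null(dims)) {
      span <- apply(xyz, 2, max) + 3 - origin
      dims <- pmax(2L, as.integer(ceiling(span / spacing)) + 1L)
    }
    grid <- scalar_field_grid(origin, spacing, dims)
  }
  Z <- .atomic_number(structure$atoms$element)
  ax <- .grid_axes(grid)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  rho <- array(0, c(nx, ny, nz))
  gx <- rep(ax[[1]], times = ny * nz)
  gy <- rep(rep(ax[[2]], each = nx), times = nz)
  gz <- rep(ax[[3]], each = nx * ny)
  for (i in seq_len(nrow(xyz))) {
    r <- sqrt((gx - xyz[i, 1])^2 + (gy - xyz[i, 2])^2 +
              (gz - xyz[i, 3])^2) / .BOHR
    rho <- rho + array(.atomic_density(Z[i], r), c(nx, ny, nz))
  }
  grid$rho <- rho
  grid$atoms <- data.frame(Z = Z, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  grid
}

# finite differences along one array axis: fourth-order central stencil in
# the deep interior, second-order central one voxel from the edge,
# one-sided at the boundary
.diff_axis <- function(f, axis, h) {
  d <- dim(f)
  n <- d[axis]
  idx <- function(i) {
    args <- list(f)
    args[1 + seq_len(3)] <- lapply(d, seq_len)
    args[[1 + axis]] <- i
    args$drop <- FALSE
    do.call(`[`, args)
  }
  g <- array(NA_real_, d)
  put <- function(i, val) {
    if (axis == 1) g[i, , ] <<- val
    else if (axis == 2) g[, i, ] <<- val
    else g[, , i] <<- val
  }
  put(1, (idx(2) - idx(1)) / h)
  put(n, (idx(n) - idx(n - 1)) / h)
  if (n >= 3) {
    put(2, (idx(3) - idx(1)) / (2 * h))
    put(n - 1, (idx(n) - idx(n - 2)) / (2 * h))
  }
  if (n >= 5) {
    i <- 3:(n - 2)
    put(i, (idx(i - 2) - 8 * idx(i - 1) + 8 * idx(i + 1) - idx(i + 2)) /
          (12 * h))
  }
  g
}

# middle eigenvalue of symmetric 3x3 Hessians, vectorised
.middle_eigenvalue <- function(h11, h22, h33, h12, h13, h23) {
  q <- (h11 + h22 + h33) / 3
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 +
    2 * (h12^2 + h13^2 + h23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- (h11 - q); b22 <- (h22 - q); b33 <- (h33 - q)
  detB <- b11 * (b22 * b33 - h23^2) - h12 * (h12 * b33 - h23 * h13) +
    h13 * (h12 * h23 - b22 * h13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  3 * q - e1 - e3
}

#' Reduced density gradient of a density grid
#'
#' Fills \code{grad_norm}, \code{lambda2} (middle eigenvalue of the density
#' Hessian) and \code{rdg} = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3)) by
#' central finite differences (one-sided at the grid boundary).  Voxels
#' with rho below \code{rho_floor} are masked (NA).  All three axis
#' spacings must agree within 1 percent.
#'
#' @param grid a \code{scalar_field_grid} with \code{rho} filled
#' @param rho_floor density floor (a.u.), default 1e-8
#' @return the grid with derivative fields filled
#' @export
rdg <- function(grid, rho_floor = 1e-8) {
  if (is.null(grid$rho)) stop("rho is not filled", call. = FALSE)
  sp <- grid$spacing
  if (max(sp) / min(sp) > 1.01)
    stop("grid spacing non-uniform beyond 1 percent", call. = FALSE)
  h <- sp / .BOHR  # derivatives in atomic units
  f <- grid$rho
  gx <- .diff_axis(f, 1, h[1])
  gy <- .diff_axis(f, 2, h[2])
  gz <- .diff_axis(f, 3, h[3])
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  h11 <- .diff_axis(gx, 1, h[1]); h22 <- .diff_axis(gy, 2, h[2])
  h33 <- .diff_axis(gz, 3, h[3])
  h12 <- .diff_axis(gx, 2, h[2]); h13 <- .diff_axis(gx, 3, h[3])
  h23 <- .diff_axis(gy, 3, h[3])
  l2 <- array(.middle_eigenvalue(h11, h22, h33, h12, h13, h23), dim(f))
  cfac <- 2 * (3 * pi^2)^(1 / 3)
  val <- gn / (cfac * f^(4 / 3))
  mask <- f < rho_floor
  val[mask] <- NA_real_
  gn[mask] <- NA_real_
  l2[mask] <- NA_real_
  grid$grad_norm <- gn
  grid$lambda2 <- l2
  grid$rdg <- val
  grid
}

#' Classify non-covalent interaction voxels
#'
#' Among voxels with RDG below the isovalue and density below the cutoff,
#' sign(lambda2) x rho separates attraction from repulsion: values below
#' \code{-sign_threshold} mark hydrogen bonds, values above
#' \code{+sign_threshold} steric repulsion, the band between them van der
#' Waals contacts.  Boundary voxels (one-sided derivative stencil) are
#' excluded.
#'
#' @param grid a grid with rho, rdg and lambda2 filled
#' @param rdg_isovalue default 0.5
#' @param rho_cutoff a.u., default 0.05
#' @param sign_threshold a.u., default 0.01
#' @return list with \code{label} (character array: "hbond", "vdw",
#'   "steric" or NA), \code{counts} and \code{signed_rho}
#' @export
classify_nci <- function(grid, rdg_isovalue = 0.5, rho_cutoff = 0.05,
                         sign_threshold = 0.01) {
  if (is.null(grid$rdg) || is.null(grid$lambda2))
    stop("run rdg() first", call. = FALSE)
  d <- grid$dims
  interior <- array(FALSE, d)
  if (all(d >= 3))
    interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  s <- sign(grid$lambda2) * grid$rho
  sel <- interior & !is.na(grid$rdg) & grid$rdg < rdg_isovalue &
    grid$rho < rho_cutoff
  label <- array(NA_character_, d)
  label[sel & s < -sign_threshold] <- "hbond"
  label[sel & abs(s) <= sign_threshold] <- "vdw"
  label[sel & s > sign_threshold] <- "steric"
  counts <- c(hbond = sum(label == "hbond", na.rm = TRUE),
              vdw = sum(label == "vdw", na.rm = TRUE),
              steric = sum(label == "steric", na.rm = TRUE))
  list(label = label, counts = counts, signed_rho = s)
}

#' Export a grid field as a Gaussian cube file
#'
#' Lengths are written in bohr per the cube convention; data ordering is z
#' fastest.
#'
#' @param grid a \code{scalar_field_grid}
#' @param field one of "rho", "rdg", "grad_norm", "lambda2",
#'   or "signed_rho"
#' @param path output path
#' @return \code{path}, invisibly
#' @export
export_cube <- function(grid, field = "rho", path) {
  f <- switch(field,
    rho = grid$rho, rdg = grid$rdg, grad_norm = grid$grad_norm,
    lambda2 = grid$lambda2,
    signed_rho = sign(grid$lambda2) * grid$rho,
    stop("unknown field: ", field, call. = FALSE))
  if (is.null(f)) stop("field '", field, "' is not filled", call. = FALSE)
  f[is.na(f)] <- 0
  atoms <- grid$atoms
  if (is.null(atoms)) atoms <- data.frame(Z = integer(0), x = numeric(0),
                                          y = numeric(0), z = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("umamidp cube export", paste("field:", field)), con)
  o <- grid$origin / .BOHR
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(atoms),
                     o[1], o[2], o[3]), con)
  sp <- grid$spacing / .BOHR
  vecs <- diag(sp)
  for (k in 1:3)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[k],
                       vecs[k, 1], vecs[k, 2], vecs[k, 3]), con)
  if (nrow(atoms))
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$Z,
                       as.numeric(atoms$Z), atoms$x / .BOHR,
                       atoms$y / .BOHR, atoms$z / .BOHR), con)
  # z fastest: loop x, then y, stream z
  vals <- aperm(f, c(3, 2, 1))  # now [z, y, x]; as.vector runs z fastest
  flat <- as.vector(vals)      # ordered x slowest, z fastest
  writeLines(paste0(" ", formatC(flat, format = "E", digits = 6)), con)
  invisible(path)
}

#' Read a Gaussian cube file written by \code{\link{export_cube}}
#'
#' @param path cube file path
#' @return a \code{scalar_field_grid} with \code{rho} holding the stored
#'   field
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  natoms <- as.integer(hdr[1])
  origin <- as.numeric(hdr[2:4]) * .BOHR
  dims <- integer(3); spacing <- numeric(3)
  for (k in 1:3) {
    v <- as.numeric(strsplit(trimws(lines[3 + k]), "\\s+")[[1]])
    dims[k] <- as.integer(v[1])
    spacing[k] <- v[1 + k] * .BOHR
  }
  atom_lines <- lines[seq_len(natoms) + 6]
  atoms <- if (natoms) {
    m <- do.call(rbind, lapply(atom_lines, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    data.frame(Z = as.integer(m[, 1]), x = m[, 3] * .BOHR,
               y = m[, 4] * .BOHR, z = m[, 5] * .BOHR)
  } else NULL
  data_lines <- lines[-(seq_len(6 + natoms))]
  flat <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  g <- scalar_field_grid(origin, spacing, dims)
  vals <- array(flat, dim = c(dims[3], dims[2], dims[1]))
  g$rho <- aperm(vals, c(3, 2, 1))
  g$atoms <- atoms
  g
}
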
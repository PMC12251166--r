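# HOLE-style channel profiling: maximal inscribed sphere radius along an
# axis at 0.25 Angstrom stations, nearest contact residues, and channel
# acid-base summaries.

# clearance radius of a sphere centred at p: min over atoms of
# (distance - vdw); the pore radius when p lies inside the channel
.clearance <- function(p, xyz, vdw) {
  min(sqrt(colSums((t(xyz) - p)^2)) - vdw)
}

#' Profile a channel along an axis
#'
#' At stations spaced 0.25 Angstrom along the axis from \code{axis_start}
#' to \code{axis_end}, the centre of the maximal inscribed sphere is
#' optimised within the plane perpendicular to the axis (16 seeded
#' multi-starts around the previous station's centre, Nelder-Mead
#' refinement) to maximise r = min over atoms of (centre-atom distance -
#' atom vdW radius).  Radii are capped at \code{bulk_radius} where the pore
#' opens to solvent; stations with no atoms within 15 Angstrom are flagged
#' open.  The two nearest distinct contact residues are recorded per
#' station.
#'
#' @param structure a \code{structure_model} with vdW radii
#' @param axis_start,axis_end length-3 points (Angstrom)
#' @param spacing station spacing (Angstrom), default 0.25
#' @param bulk_radius cap marking bulk solvent (Angstrom), default 10
#' @param seed integer seed for the multi-start pattern
#' @return object of class \code{channel_profile}: data.frame with columns
#'   station (axial position), radius, cx, cy, cz, contact1, contact2,
#'   open; attributes \code{min_radius}, \code{min_station},
#'   \code{mean_radius}, \code{contact_residues}
#' @export
profile_channel <- function(structure, axis_start, axis_end, spacing = 0.25,
                            bulk_radius = 10, seed = 1L) {
  axis_start <- as.numeric(axis_start); axis_end <- as.numeric(axis_end)
  u <- axis_end - axis_start
  L <- sqrt(sum(u^2))
  if (L < 1e-9) stop("axis endpoints must be distinct", call. = FALSE)
  u <- u / L
  # in-plane orthonormal basis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  xyz <- coords(structure)
  vdw <- structure$atoms$vdw
  stations <- seq(0, L, by = spacing)
  n <- length(stations)
  res <- data.frame(station = stations, radius = NA_real_, cx = NA_real_,
                    cy = NA_real_, cz = NA_real_, contact1 = NA_character_,
                    contact2 = NA_character_, open = FALSE,
                    stringsAsFactors = FALSE)
  prev_off <- c(0, 0)  # in-plane offset of previous centre
  angles <- .with_seed(seed, runif(16, 0, 2 * pi))
  a <- structure$atoms
  for (k in seq_len(n)) {
    p0 <- axis_start + stations[k] * u
    near <- which(sqrt(colSums((t(xyz) - p0)^2)) <= 15 + max(vdw))
    if (!length(near)) {
      res$radius[k] <- bulk_radius
      res$open[k] <- TRUE
      res[k, c("cx", "cy", "cz")] <- as.list(p0)
      prev_off <- c(0, 0)
      next
    }
    nxyz <- xyz[near, , drop = FALSE]; nvdw <- vdw[near]
    obj <- function(off) {
      p <- p0 + off[1] * e1 + off[2] * e2
      -.clearance(p, nxyz, nvdw)
    }
    starts <- rbind(prev_off,
                    t(vapply(angles, function(th)
                      prev_off + 2 * c(cos(th), sin(th)), numeric(2))))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- optim(starts[s, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-8))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    r <- -best$value
    ctr <- p0 + best$par[1] * e1 + best$par[2] * e2
    if (r >= bulk_radius) {
      r <- bulk_radius
      res$open[k] <- TRUE
    }
    res$radius[k] <- r
    res[k, c("cx", "cy", "cz")] <- as.list(ctr)
    prev_off <- best$par
    # two nearest distinct contact residues by centre-to-surface distance
    surf <- sqrt(colSums((t(nxyz) - ctr)^2)) - nvdw
    ord <- order(surf)
    rk <- paste0(a$chain[near], "_", a$resno[near], "_", a$resname[near])
    seen <- unique(rk[ord])
    res$contact1[k] <- seen[1]
    res$contact2[k] <- if (length(seen) > 1) seen[2] else seen[1]
  }
  closed <- !res$open
  attr(res, "min_radius") <- min(res$radius[closed], Inf)
  attr(res, "min_station") <-
    if (any(closed)) res$station[closed][which.min(res$radius[closed])]
    else NA_real_
  attr(res, "mean_radius") <- mean(res$radius[closed])
  attr(res, "contact_residues") <-
    sort(unique(c(res$contact1[closed], res$contact2[closed])))
  class(res) <- c("channel_profile", "data.frame")
  res
}

#' Brute-force channel radius at given stations (reference oracle)
#'
#' Plane-grid search for the maximal inscribed sphere, used as an
#' independent check of \code{\link{profile_channel}}.
#'
#' @param structure a \code{structure_model}
#' @param axis_start,axis_end axis endpoints
#' @param stations axial positions (Angstrom from axis_start)
#' @param grid_step in-plane grid step (Angstrom)
#' @param grid_half half-width of the search square (Angstrom)
#' @return numeric vector of radii
#' @export
profile_channel_bruteforce <- function(structure, axis_start, axis_end,
                                       stations, grid_step = 0.05,
                                       grid_half = 2) {
  axis_start <- as.numeric(axis_start); axis_end <- as.numeric(axis_end)
  u <- axis_end - axis_start
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  xyz <- coords(structure)
  vdw <- structure$atoms$vdw
  g <- seq(-grid_half, grid_half, by = grid_step)
  offs <- as.matrix(expand.grid(g, g))
  vapply(stations, function(s) {
    p0 <- axis_start + s * u
    max(apply(offs, 1, function(off)
      .clearance(p0 + off[1] * e1 + off[2] * e2, xyz, vdw)))
  }, numeric(1))
}

#' Acid-base summary of channel contact residues
#'
#' Mean model pKa over the unique titratable contact residues of a channel
#' profile; channels with mean pKa above 7 are classed basic, otherwise
#' acidic.  Per-residue pKa values may be imported (e.g. from an external
#' electrostatics calculation) in place of the model table.
#'
#' @param profile a \code{channel_profile}
#' @param pka_source either a pKa table as from
#'   \code{\link{default_pka_table}} (matched by residue type) or a named
#'   numeric vector of per-residue pKas keyed like the profile's contact
#'   residues (chain_resno_RESNAME)
#' @return list with \code{mean_pka}, \code{class} ("basic"/"acidic"/
#'   "undefined"), \code{assignments} (data.frame residue, pka)
#' @export
channel_acidity <- function(profile, pka_source = default_pka_table()) {
  contacts <- attr(profile, "contact_residues")
  if (is.numeric(pka_source)) {
    hit <- intersect(contacts, names(pka_source))
    assign <- data.frame(residue = hit, pka = unname(pka_source[hit]),
                         stringsAsFactors = FALSE)
  } else {
    resname <- sub(".*_", "", contacts)
    one <- .aa_one[resname]
    idx <- match(one, pka_source$group)
    keep <- !is.na(idx)
    assign <- data.frame(residue = contacts[keep],
                         pka = pka_source$pka[idx[keep]],
                         stringsAsFactors = FALSE)
  }
  if (!nrow(assign))
    return(list(mean_pka = NA_real_, class = "undefined",
                assignments = assign))
  m <- mean(assign$pka)
  list(mean_pka = m, class = if (m > 7) "basic" else "acidic",
       assignments = assign)
}

#' Write a channel profile as CSV and sphere-centre PDB
#'
#' @param profile a \code{channel_profile}
#' @param csv_path output CSV path (NULL to skip)
#' @param pdb_path output PDB path of pseudo-atom sphere centres (NULL to
#'   skip)
#' @return invisibly, the paths written
#' @export
write_channel_profile <- function(profile, csv_path = NULL, pdb_path = NULL) {
  if (!is.null(csv_path))
    write.csv(as.data.frame(profile), csv_path, row.names = FALSE)
  if (!is.null(pdb_path)) {
    n <- nrow(profile)
    centres <- structure_model(data.frame(
      serial = seq_len(n), name = "SPH", element = "X", resname = "SPH",
      resno = seq_len(n), chain = "Z",
      x = profile$cx, y = profile$cy, z = profile$cz,
      stringsAsFactors = FALSE))
    write_pdb(centres, pdb_path)
  }
  invisible(c(csv = csv_path, pdb = pdb_path))
}
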
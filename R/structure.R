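# Structure and trajectory containers, PDB reading/writing, Kabsch
# superposition and principal-axis bounding boxes.

#' Construct a structure model
#'
#' A structure model holds an ordered atom table.  Coordinates are in
#' Angstrom; vdW radii are assigned from \code{\link{element_vdw_radii}} when
#' missing.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z} and optionally \code{vdw}, \code{charge}.
#' @return An object of class \code{structure_model}.
#' @export
structure_model <- function(atoms) {
  req <- c("serial", "name", "element", "resname", "resno", "chain",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (is.null(atoms$vdw)) {
    radii <- element_vdw_radii()
    atoms$vdw <- unname(radii[match(atoms$element, names(radii))])
    atoms$vdw[is.na(atoms$vdw)] <- radii[["X"]]
  }
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, name) atom key: ",
         key[anyDuplicated(key)][1], call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues\n")
  invisible(x)
}

#' Extract an n x 3 coordinate matrix
#'
#' @param x a \code{structure_model}
#' @param sel optional integer atom indices
#' @return numeric matrix with columns x, y, z (Angstrom)
#' @export
coords <- function(x, sel = NULL) {
  a <- x$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Replace coordinates of a structure model
#' @param x a \code{structure_model}
#' @param xyz n x 3 matrix
#' @return the modified model
#' @export
set_coords <- function(x, xyz) {
  stopifnot(nrow(xyz) == nrow(x$atoms), ncol(xyz) == 3)
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' Select atoms by attribute
#'
#' @param x a \code{structure_model}
#' @param name,element,resname,chain optional values to match
#' @param resno optional residue numbers to match
#' @param heavy if TRUE, restrict to non-hydrogen atoms
#' @return integer vector of atom indices
#' @export
atom_select <- function(x, name = NULL, element = NULL, resname = NULL,
                        resno = NULL, chain = NULL, heavy = FALSE) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (heavy) keep <- keep & a$element != "H"
  which(keep)
}

#' Construct a trajectory
#'
#' @param topology a \code{structure_model}
#' @param frames array of dim (n_frames, n_atoms, 3), Angstrom
#' @param times optional frame times (ps), strictly increasing
#' @param energy optional per-frame potential energies (kcal/mol)
#' @return object of class \code{trajectory}
#' @export
trajectory <- function(topology, frames, times = NULL, energy = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(dim(frames)) != 3L || dim(frames)[2] != nrow(topology$atoms) ||
      dim(frames)[3] != 3L)
    stop("frames must be an (n_frames, n_atoms, 3) array matching topology",
         call. = FALSE)
  nf <- dim(frames)[1]
  if (!is.null(times)) {
    stopifnot(length(times) == nf)
    if (nf > 1 && any(diff(times) <= 0))
      stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(energy)) stopifnot(length(energy) == nf)
  structure(list(topology = topology, frames = frames, times = times,
                 energy = energy), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$frames)[1], "frames x", dim(x$frames)[2],
      "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a \code{trajectory}
#' @return integer frame count
#' @export
n_frames <- function(x) dim(x$frames)[1]

#' Coordinates of one trajectory frame
#' @param x a \code{trajectory}
#' @param i frame index
#' @param sel optional atom indices
#' @return n x 3 matrix
#' @export
frame_coords <- function(x, i, sel = NULL) {
  m <- x$frames[i, , , drop = TRUE]
  dim(m) <- dim(x$frames)[2:3]
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

# ---- PDB input/output -------------------------------------------------------

.parse_pdb_atoms <- function(lines, lineno) {
  n <- length(lines)
  get <- function(from, to) substr(lines, from, to)
  xs <- suppressWarnings(as.numeric(get(31, 38)))
  ys <- suppressWarnings(as.numeric(get(39, 46)))
  zs <- suppressWarnings(as.numeric(get(47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop("malformed PDB coordinate field at line ", lineno[bad[1]],
         call. = FALSE)
  serial <- suppressWarnings(as.integer(get(7, 11)))
  serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
  name <- trimws(get(13, 16))
  resname <- trimws(get(18, 20))
  chain <- trimws(get(22, 22))
  chain[chain == ""] <- "A"
  resno <- suppressWarnings(as.integer(get(23, 26)))
  if (anyNA(resno))
    stop("malformed PDB residue number at line ",
         lineno[which(is.na(resno))[1]], call. = FALSE)
  element <- trimws(get(77, 78))
  fallback <- element == "" | is.na(element)
  element[fallback] <- .element_from_name(name[fallback])
  data.frame(serial = serial, name = name, element = toupper(element),
             resname = resname, resno = resno, chain = chain,
             x = xs, y = ys, z = zs, stringsAsFactors = FALSE)
}

#' Read a PDB file
#'
#' Single-model files yield a \code{structure_model}; multi-MODEL files yield
#' a \code{trajectory} whose topology is the first model.  Elements are taken
#' from columns 77-78 with an atom-name fallback; vdW radii are assigned from
#' the element table.
#'
#' @param path path to a PDB file
#' @return a \code{structure_model} or \code{trajectory}
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  if (!any(is_model)) {
    atoms <- .parse_pdb_atoms(lines[is_atom], which(is_atom))
    return(structure_model(atoms))
  }
  model_id <- cumsum(is_model)
  keep <- is_atom & model_id > 0
  atoms_all <- .parse_pdb_atoms(lines[keep], which(keep))
  grp <- model_id[keep]
  counts <- table(grp)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom counts across MODEL records (model ",
         names(counts)[which(counts != counts[1])[1]], ")", call. = FALSE)
  nf <- length(counts)
  na <- counts[[1]]
  topo <- structure_model(atoms_all[grp == sort(unique(grp))[1], , drop = FALSE])
  frames <- array(NA_real_, c(nf, na, 3))
  for (k in seq_len(nf)) {
    m <- atoms_all[grp == sort(unique(grp))[k], c("x", "y", "z")]
    frames[k, , ] <- as.matrix(m)
  }
  trajectory(topo, frames)
}

.format_pdb_line <- function(a) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          a$serial %% 100000L,
          ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
          a$resname, a$chain, a$resno %% 10000L, a$x, a$y, a$z, a$element)
}

#' Write a structure or trajectory to PDB
#'
#' Trajectories are written as multi-MODEL files.
#'
#' @param x a \code{structure_model} or \code{trajectory}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "structure_model")) {
    writeLines(.format_pdb_line(x$atoms), con)
    writeLines("END", con)
  } else if (inherits(x, "trajectory")) {
    for (k in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      m <- set_coords(x$topology, frame_coords(x, k))
      writeLines(.format_pdb_line(m$atoms), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("x must be a structure_model or trajectory", call. = FALSE)
  invisible(path)
}

# ---- superposition ----------------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' of \code{mobile} onto \code{reference} over the given selection, and
#' returns the post-fit RMSD over that selection:
#' RMSD = sqrt(mean of squared atom offsets).
#'
#' @param mobile,reference n x 3 coordinate matrices
#' @param sel optional row indices used for fitting (default: all)
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3,
#'   applied after rotation), \code{rmsd} (Angstrom) and \code{fitted}
#'   (all mobile rows transformed)
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3) stop("selection must contain at least 3 atoms",
                            call. = FALSE)
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selections differ in length", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sa <- svd(A0)
  if (sa$d[2] < 1e-8)
    stop("degenerate (collinear) selection", call. = FALSE)
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  trans <- cb - as.vector(R %*% ca)
  fit_sel <- sweep(A %*% t(R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fit_sel - B)^2)))
  fitted <- sweep(mobile %*% t(R), 2, trans, "+")
  list(rotation = R, translation = trans, rmsd = rmsd, fitted = fitted)
}

#' RMSD between two already-aligned coordinate sets
#' @param a,b n x 3 matrices
#' @return Angstrom
#' @export
rmsd_raw <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# ---- geometry ---------------------------------------------------------------

#' Principal-axis bounding box of an atom set
#'
#' Extents are measured along the principal axes of the coordinate
#' covariance (sorted descending) and padded by per-atom vdW radii, making
#' the measure rotation invariant; the volume is the product of the extents.
#'
#' @param xyz n x 3 coordinate matrix
#' @param vdw per-atom radii (Angstrom); default 0
#' @return list with \code{extents} (length/width/height, descending),
#'   \code{volume} (Angstrom^3) and \code{axes} (3 x 3, columns = axes)
#' @export
bounding_box <- function(xyz, vdw = 0) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 4) stop("need at least 4 atoms for a 3-D box", call. = FALSE)
  vdw <- rep_len(vdw, nrow(xyz))
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (ev$values[3] <= 1e-12)
    stop("atoms are coplanar; 3-D box undefined", call. = FALSE)
  proj <- X %*% ev$vectors
  ext <- vapply(1:3, function(k)
    max(proj[, k] + vdw) - min(proj[, k] - vdw), numeric(1))
  ord <- order(ext, decreasing = TRUE)
  list(extents = ext[ord], volume = prod(ext), axes = ev$vectors[, ord])
}
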
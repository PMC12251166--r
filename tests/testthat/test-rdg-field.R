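# Promolecular density, reduced density gradient, NCI classification,
# cube export.

single_atom <- function(element, x = 0) {
  structure_model(data.frame(
    serial = 1L, name = element, element = element, resname = "ATM",
    resno = 1L, chain = "A", x = x, y = 0, z = 0, stringsAsFactors = FALSE))
}

grid_for <- function(structure, spacing, half) {
  n <- as.integer(round(2 * half / spacing)) + 1L
  promolecular_density(structure, origin = c(-half, -half, -half),
                       spacing = spacing, dims = c(n, n, n))
}

test_that("promolecular density is positive, monotone and superposable", {
  g <- grid_for(single_atom("H"), 0.1, 2)
  expect_true(all(g$rho > 0))
  mid <- (dim(g$rho)[1] + 1) / 2
  along_x <- g$rho[mid:dim(g$rho)[1], mid, mid]
  expect_true(all(diff(along_x) < 0))
  # two identical atoms: midpoint density doubles the single-atom value
  pair <- structure_model(data.frame(
    serial = 1:2, name = "H", element = "H", resname = "ATM", resno = 1:2,
    chain = "A", x = c(-1, 1), y = 0, z = 0, stringsAsFactors = FALSE))
  gp <- promolecular_density(pair, origin = c(0, 0, 0), spacing = 0.1,
                             dims = c(1, 1, 1))
  g1 <- promolecular_density(single_atom("H"), origin = c(1, 0, 0),
                             spacing = 0.1, dims = c(1, 1, 1))
  expect_equal(gp$rho[1, 1, 1], 2 * g1$rho[1, 1, 1], tolerance = 1e-12)
  expect_error(promolecular_density(single_atom("X")), "unsupported")
})

test_that("the carbon density integrates to its electron count", {
  g <- grid_for(single_atom("C"), 0.05, 4)
  vol_bohr <- prod(g$spacing / 0.529177210903)
  expect_equal(sum(g$rho) * vol_bohr, 6, tolerance = 0.05)
})

test_that("RDG matches the exponential-density closed form", {
  # hydrogen's Slater density is a pure exponential with decay length
  # a = 0.5 bohr, so RDG(r) = rho^(-1/3) / (2 (3 pi^2)^(1/3) a)
  a <- 0.5
  err_at <- function(spacing) {
    g <- rdg(grid_for(single_atom("H"), spacing, 2))
    mid <- (dim(g$rho)[1] + 1) / 2
    i <- mid + as.integer(round(1 / spacing))   # 1 A from the nucleus
    analytic <- g$rho[i, mid, mid]^(-1 / 3) /
      (2 * (3 * pi^2)^(1 / 3) * a)
    abs(g$rdg[i, mid, mid] - analytic) / analytic
  }
  e1 <- err_at(0.1)
  expect_lt(e1, 0.02)
  # grid refinement shrinks the finite-difference error
  e2 <- err_at(0.05)
  expect_lt(e2, e1 / 2)
})

test_that("RDG vanishes at the two-atom symmetry midpoint", {
  pair <- structure_model(data.frame(
    serial = 1:2, name = "C", element = "C", resname = "ATM", resno = 1:2,
    chain = "A", x = c(-1.7, 1.7), y = 0, z = 0, stringsAsFactors = FALSE))
  n <- 41L
  g <- rdg(promolecular_density(pair, origin = c(-2, -2, -2), spacing = 0.1,
                                dims = c(n, n, n)))
  mid <- (n + 1) / 2
  expect_lt(g$rdg[mid, mid, mid], 1e-8)
  expect_true(all(g$rdg >= 0, na.rm = TRUE))
  expect_true(all(g$rho >= 0))
})

test_that("non-uniform spacing and unfilled fields are rejected", {
  g <- scalar_field_grid(c(0, 0, 0), c(0.1, 0.1, 0.2), c(5, 5, 5))
  g$rho <- array(1, c(5, 5, 5))
  expect_error(rdg(g), "non-uniform")
  expect_error(rdg(scalar_field_grid(c(0, 0, 0), 0.1, c(5, 5, 5))),
               "not filled")
})

test_that("the middle-eigenvalue kernel matches dense eigendecomposition", {
  set.seed(81)
  for (i in 1:20) {
    m <- matrix(rnorm(9), 3, 3)
    s <- (m + t(m)) / 2
    got <- umamidp:::.middle_eigenvalue(s[1, 1], s[2, 2], s[3, 3],
                                        s[1, 2], s[1, 3], s[2, 3])
    expect_equal(got, sort(eigen(s, symmetric = TRUE)$values)[2],
                 tolerance = 1e-8)
  }
})

test_that("NCI classification separates contact types on fixtures", {
  # two carbons at vdW contact: a van der Waals disc, no steric voxels at
  # the interatomic midplane region
  pair <- structure_model(data.frame(
    serial = 1:2, name = "C", element = "C", resname = "ATM", resno = 1:2,
    chain = "A", x = c(-1.7, 1.7), y = 0, z = 0, stringsAsFactors = FALSE))
  g <- rdg(promolecular_density(pair, origin = c(-3, -1.5, -1.5),
                                spacing = 0.1, dims = c(61, 31, 31)))
  cls <- classify_nci(g)
  expect_gt(cls$counts[["vdw"]], 0)
  expect_identical(cls$counts[["hbond"]], 0L)
  # an O-H...O fixture at 1.9 A H...O shows a hydrogen-bond region
  dimer <- structure_model(data.frame(
    serial = 1:3, name = c("O", "H", "O"), element = c("O", "H", "O"),
    resname = "HOH", resno = c(1L, 1L, 2L), chain = "A",
    x = c(0, 0.96, 2.86), y = 0, z = 0, stringsAsFactors = FALSE))
  gd <- rdg(promolecular_density(dimer, origin = c(-1.5, -1.5, -1.5),
                                 spacing = 0.1, dims = c(58, 31, 31)))
  cd <- classify_nci(gd)
  expect_gt(cd$counts[["hbond"]], 0)
})

test_that("cube files round-trip and follow the z-fastest convention", {
  pair <- structure_model(data.frame(
    serial = 1:2, name = "C", element = "C", resname = "ATM", resno = 1:2,
    chain = "A", x = c(0, 1.5), y = 0, z = 0, stringsAsFactors = FALSE))
  g <- promolecular_density(pair, origin = c(-1, -1, -1), spacing = 0.25,
                            dims = c(9, 9, 9))
  p <- withr::local_tempfile(fileext = ".cube")
  export_cube(g, "rho", p)
  g2 <- read_cube(p)
  expect_equal(g2$rho, g$rho, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
  expect_identical(nrow(g2$atoms), 2L)
  # hand-indexed 2x3x4 ramp: value = 100 x + 10 y + z (voxel indices)
  ramp <- scalar_field_grid(c(0, 0, 0), 0.5, c(2, 3, 4))
  v <- array(0, c(2, 3, 4))
  for (i in 1:2) for (j in 1:3) for (k in 1:4)
    v[i, j, k] <- 100 * i + 10 * j + k
  ramp$rho <- v
  p2 <- withr::local_tempfile(fileext = ".cube")
  export_cube(ramp, "rho", p2)
  lines <- readLines(p2)
  data_lines <- lines[-(1:6)]
  flat <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  # z runs fastest, then y, then x
  expect_equal(flat[1:4], c(111, 112, 113, 114))
  expect_equal(flat[5], 121)
  expect_equal(flat[13], 211)
  expect_error(export_cube(ramp, "rdg", withr::local_tempfile()),
               "not filled")
})
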
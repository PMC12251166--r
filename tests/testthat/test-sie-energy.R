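# SIE: Coulomb/LJ intermolecular sums, generalized-Born reaction field,
# surface-area change, and the calibrated score.

# complex of two point charges at distance d
charge_pair <- function(d, q1 = 1, q2 = -1, vdw = 1.7) {
  structure_model(data.frame(
    serial = 1:2, name = c("Q1", "Q2"), element = "C",
    resname = c("REC", "LIG"), resno = 1:2, chain = c("R", "L"),
    x = c(0, d), y = 0, z = 0, vdw = vdw, charge = c(q1, q2),
    stringsAsFactors = FALSE))
}

test_that("Coulomb term reproduces hand values and dielectric scaling", {
  cx <- charge_pair(3.320636)
  expect_equal(coulomb_interaction(cx, 1, 2, d_in = 1), -100,
               tolerance = 1e-6)
  expect_equal(coulomb_interaction(cx, 1, 2, d_in = 2.25), -100 / 2.25,
               tolerance = 1e-6)
  neutral <- charge_pair(3.3, q2 = 0)
  expect_equal(coulomb_interaction(neutral, 1, 2), 0)
  expect_error(coulomb_interaction(charge_pair(0.05), 1, 2), "overlapping")
})

test_that("Lennard-Jones term has its root and minimum where expected", {
  lj <- lj_parameters()
  rmin <- 2 * lj$rmin_half[lj$element == "C"]
  eps <- lj$epsilon[lj$element == "C"]
  at_min <- charge_pair(rmin)
  expect_equal(vdw_interaction(at_min, 1, 2), -eps, tolerance = 1e-10)
  at_sigma <- charge_pair(rmin / 2^(1 / 6))
  expect_equal(vdw_interaction(at_sigma, 1, 2), 0, tolerance = 1e-10)
  bad <- charge_pair(3)
  bad$atoms$element[2] <- "P"
  expect_error(vdw_interaction(bad, 1, 2), "LJ parameters")
})

test_that("Coulomb and LJ sums equal brute-force double loops", {
  set.seed(71)
  n_r <- 6; n_l <- 4
  atoms <- data.frame(
    serial = seq_len(n_r + n_l),
    name = paste0("X", seq_len(n_r + n_l)),
    element = sample(c("C", "N", "O", "S", "H"), n_r + n_l, replace = TRUE),
    resname = rep(c("REC", "LIG"), c(n_r, n_l)),
    resno = rep(1:2, c(n_r, n_l)),
    chain = rep(c("R", "L"), c(n_r, n_l)),
    x = c(runif(n_r, 0, 4), runif(n_l, 6, 9)),
    y = runif(n_r + n_l, 0, 4), z = runif(n_r + n_l, 0, 4),
    charge = round(runif(n_r + n_l, -0.5, 0.5), 3),
    stringsAsFactors = FALSE)
  cx <- structure_model(atoms)
  rs <- seq_len(n_r); ls <- n_r + seq_len(n_l)
  xyz <- coords(cx)
  lj <- lj_parameters()
  ec_brute <- 0; ev_brute <- 0
  for (i in rs) for (j in ls) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ec_brute <- ec_brute +
      332.0636 * atoms$charge[i] * atoms$charge[j] / (2.25 * r)
    ei <- lj$epsilon[lj$element == atoms$element[i]]
    ej <- lj$epsilon[lj$element == atoms$element[j]]
    ri <- lj$rmin_half[lj$element == atoms$element[i]]
    rj <- lj$rmin_half[lj$element == atoms$element[j]]
    x6 <- ((ri + rj) / r)^6
    ev_brute <- ev_brute + sqrt(ei * ej) * (x6^2 - 2 * x6)
  }
  expect_equal(coulomb_interaction(cx, rs, ls, 2.25), ec_brute,
               tolerance = 1e-4)
  expect_equal(vdw_interaction(cx, rs, ls), ev_brute, tolerance = 1e-4)
})

test_that("generalized Born recovers the single-ion Born formula", {
  for (a in c(1.5, 2.0, 3.0)) for (q in c(1, -1, 2)) {
    got <- umamidp:::.gb_energy(matrix(0, 1, 3), q, a, d_in = 2.25)
    born <- -0.5 * 332.0636 * (1 / 2.25 - 1 / 78.5) * q^2 / a
    expect_equal(got, born, tolerance = 1e-6)
  }
})

test_that("reaction-field change vanishes for uncharged or separated species", {
  cx0 <- charge_pair(4, q1 = 0, q2 = 0)
  expect_equal(reaction_field_change(cx0, 1, 2), 0)
  # neutral molecules: the change decays away with separation
  lig <- make_dipeptide_structure("DG", seed = 1)
  rec <- make_dipeptide_structure("GG", seed = 2)
  near <- 8; far <- 100
  build <- function(sep) {
    rxyz <- sweep(coords(rec), 2, c(0, sep, 0), "+")
    atoms <- rbind(
      lig$atoms,
      within(set_coords(rec, rxyz)$atoms, {
        chain <- "R"; serial <- serial + nrow(lig$atoms)
      }))
    structure_model(atoms)
  }
  ls <- seq_len(nrow(lig$atoms))
  rs <- nrow(lig$atoms) + seq_len(nrow(rec$atoms))
  dg_near <- reaction_field_change(build(near), rs, ls)
  dg_far <- reaction_field_change(build(far), rs, ls)
  expect_lt(abs(dg_far), 0.02)
  expect_gt(abs(dg_near), abs(dg_far))
})

test_that("the calibrated score is affine in its terms", {
  expect_equal(sie_score()$total, -2.89)
  expect_equal(sie_score(e_vdw = -10)$total, -2.89 + 0.1048 * (-10),
               tolerance = 1e-12)
  # doubling gamma doubles only the surface contribution
  p1 <- sie_params()
  p2 <- sie_params(gamma = 2 * 0.0129)
  s1 <- sie_score(e_coulomb = -5, dg_reaction_field = 3, e_vdw = -12,
                  dmsa = -200, params = p1)
  s2 <- sie_score(e_coulomb = -5, dg_reaction_field = 3, e_vdw = -12,
                  dmsa = -200, params = p2)
  expect_equal(s2$components[["gamma_dmsa"]],
               2 * s1$components[["gamma_dmsa"]])
  expect_equal(s2$components[["e_vdw"]], s1$components[["e_vdw"]])
  # exact affine identity with random terms
  set.seed(72)
  for (i in 1:5) {
    tt <- rnorm(4, sd = 20)
    got <- sie_score(tt[1], tt[2], tt[3], tt[4])$total
    want <- 0.1048 * (tt[1] + tt[2] + tt[3] + 0.0129 * tt[4]) - 2.89
    expect_equal(got, want, tolerance = 1e-12)
  }
  # the alpha-on-Coulomb-only variant stays exposed
  got2 <- sie_score(-5, 3, -12, -200, alpha_ec_only = TRUE)$total
  expect_equal(got2, 0.1048 * (-5) + 3 - 12 + 0.0129 * (-200) - 2.89,
               tolerance = 1e-12)
  expect_error(sie_params(d_in = -1), "positive")
})

test_that("surface burial is negative for a bound complex", {
  lig <- make_dipeptide_structure("DG", seed = 3)
  rec <- make_dipeptide_structure("EK", seed = 4)
  rxyz <- sweep(coords(rec), 2, c(0, 7, 0), "+")
  atoms <- rbind(
    lig$atoms,
    within(set_coords(rec, rxyz)$atoms, {
      chain <- "R"; serial <- serial + nrow(lig$atoms)
    }))
  cx <- structure_model(atoms)
  ls <- seq_len(nrow(lig$atoms))
  rs <- nrow(lig$atoms) + seq_len(nrow(rec$atoms))
  expect_lt(delta_msa(cx, rs, ls), 0)
})

test_that("ensemble SIE is consistent with per-frame scoring", {
  lig <- make_dipeptide_structure("DG", seed = 5)
  rec <- make_dipeptide_structure("GG", seed = 6)
  rxyz <- sweep(coords(rec), 2, c(0, 6.5, 0), "+")
  atoms <- rbind(
    lig$atoms,
    within(set_coords(rec, rxyz)$atoms, {
      chain <- "R"; serial <- serial + nrow(lig$atoms)
    }))
  cx <- structure_model(atoms)
  ls <- seq_len(nrow(lig$atoms))
  rs <- nrow(lig$atoms) + seq_len(nrow(rec$atoms))
  # identical frames: sd = 0 and mean equals the single-frame score
  fr <- array(rep(coords(cx), each = 3), c(3, nrow(atoms), 3))
  tr <- trajectory(cx, fr)
  expect_warning(es <- ensemble_sie(tr, rs, ls, n_samples = 100),
                 "window")
  expect_equal(es$sd, 0)
  single <- sie_single(cx, rs, ls, n_points = 120)
  expect_equal(es$mean, single$total, tolerance = 1e-9)
  # fluctuating frames: mean equals the hand average of per-frame scores
  tn <- make_trajectory(cx, sigma = 0.1, n_frames = 8, seed = 7)$trajectory
  es2 <- suppressWarnings(ensemble_sie(tn, rs, ls, n_samples = 4))
  hand <- vapply(es2$per_frame$frame, function(k) {
    m <- set_coords(cx, frame_coords(tn, k))
    sie_single(m, rs, ls, n_points = 120)$total
  }, numeric(1))
  expect_equal(es2$per_frame$total, hand, tolerance = 1e-9)
  expect_equal(es2$mean, mean(hand), tolerance = 1e-12)
})
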
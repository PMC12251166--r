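# Hydrogen bonds, occupancy, contacts, SASA, pocket hydrophobicity,
# pocket waters.

test_that("hydrogen-bond criteria gate on distance and angle jointly", {
  # both criteria satisfied
  expect_identical(nrow(detect_hbonds(hbond_triad(3.4, 150))), 1L)
  # distance violated
  expect_identical(nrow(detect_hbonds(hbond_triad(3.6, 170))), 0L)
  # angle violated
  expect_identical(nrow(detect_hbonds(hbond_triad(3.0, 120))), 0L)
  # reported geometry matches the construction
  hb <- detect_hbonds(hbond_triad(3.2, 155))
  expect_equal(hb$distance, 3.2, tolerance = 1e-6)
  expect_equal(hb$angle, 155, tolerance = 1e-6)
  # just outside either criterion does not qualify
  expect_identical(nrow(detect_hbonds(hbond_triad(3.5005, 160))), 0L)
  expect_identical(nrow(detect_hbonds(hbond_triad(3.0, 134.95))), 0L)
  # just inside both criteria qualifies
  expect_identical(nrow(detect_hbonds(hbond_triad(3.4995, 135.05))), 1L)
})

test_that("donors without hydrogens are skipped with a warning", {
  tri <- hbond_triad(3.0, 160)
  expect_warning(hb <- detect_hbonds(tri, donors = 3), "without attached")
  expect_identical(nrow(hb), 0L)
})

test_that("occupancy recovers planted fractions and applies the filter", {
  hb <- make_hbond_trajectory(0.5, 100, seed = 2)
  kept <- hbond_occupancy(hb$trajectory, min_occupancy = 0.45)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$occupancy, 0.5)
  low <- make_hbond_trajectory(0.4, 100, seed = 2)
  kept2 <- hbond_occupancy(low$trajectory, min_occupancy = 0.45)
  expect_identical(nrow(kept2), 0L)
  full <- attr(kept2, "full_table")
  expect_identical(full$occupancy, 0.4)
  # threshold zero lists every observed pair
  all_pairs <- hbond_occupancy(low$trajectory, min_occupancy = 0)
  expect_identical(nrow(all_pairs), 1L)
})

test_that("contact fingerprints classify and respect the cutoff", {
  # ligand far from everything
  lig_far <- rbind(c(100, 0, 0), c(101, 0, 0))
  rec <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  s <- cloud_structure(rbind(rec, lig_far))
  expect_identical(nrow(contact_residues(s, 1:2, 3:4)), 0L)
  # one hydrogen-bonding contact, one purely apolar contact
  atoms <- data.frame(
    serial = 1:5,
    name = c("N", "HN", "CB", "O", "CG"),
    element = c("N", "H", "C", "O", "C"),
    resname = c("SER", "SER", "LEU", "GLY", "GLY"),
    resno = c(1L, 1L, 2L, 10L, 10L),
    chain = c("A", "A", "A", "L", "L"),
    x = c(0, 1, 0, 2.9, 3.4),
    y = c(0, 0, 6, 0.05, 6),
    z = 0, stringsAsFactors = FALSE)
  cx <- structure_model(atoms)
  ct <- contact_residues(cx, receptor_sel = 1:3, ligand_sel = 4:5)
  expect_setequal(ct$residue, c("A_1", "A_2"))
  expect_identical(ct$class[ct$residue == "A_1"], "hydrogen-bond")
  expect_identical(ct$class[ct$residue == "A_2"], "hydrophobic")
  # invariant under a global rigid motion of the complex
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cx2 <- set_coords(cx, sweep(coords(cx) %*% t(R), 2, c(4, -7, 2), "+"))
  ct2 <- contact_residues(cx2, receptor_sel = 1:3, ligand_sel = 4:5)
  expect_identical(ct$class, ct2$class)
  expect_equal(ct$min_distance, ct2$min_distance, tolerance = 1e-8)
})

test_that("SASA matches analytic sphere results", {
  one <- cloud_structure(matrix(0, 1, 3), element = "O")
  got <- sasa(one, probe = 1.4, n_points = 960)$total
  expect_equal(got, 4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)
  # far-separated atoms are additive
  two <- cloud_structure(rbind(c(0, 0, 0), c(50, 0, 0)), element = "C")
  expect_equal(sasa(two)$total, 2 * 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)
  # overlapping spheres match the spherical-cap closed form
  for (d in c(2.0, 3.0, 4.0)) {
    pair <- cloud_structure(rbind(c(0, 0, 0), c(d, 0, 0)), element = "C")
    expect_equal(sasa(pair, n_points = 960)$total,
                 oracle_two_sphere_sasa(1.7, 1.7, d, 1.4),
                 tolerance = 0.01)
  }
  expect_error(sasa(structure_model(data.frame(
    serial = 1, name = "Q1", element = "X", resname = "UNK", resno = 1,
    chain = "A", x = 0, y = 0, z = 0, vdw = NA_real_))), "radius")
})

test_that("SASA burial is monotone as a neighbour approaches", {
  ds <- seq(6, 2, by = -0.5)
  areas <- vapply(ds, function(d) {
    pair <- cloud_structure(rbind(c(0, 0, 0), c(d, 0, 0)), element = "C")
    sasa(pair, n_points = 480)$atom_area[[1]]
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("pocket hydrophobicity sign follows residue character", {
  ile <- make_dipeptide_structure("IL", seed = 1)   # Ile-Leu pocket
  expect_gt(pocket_hydrophobicity(ile, seq_len(nrow(ile$atoms)))$score, 0)
  de <- make_dipeptide_structure("DE", seed = 1)    # Asp-Glu pocket
  expect_lt(pocket_hydrophobicity(de, seq_len(nrow(de$atoms)))$score, 0)
  expect_error(pocket_hydrophobicity(ile, integer(0)), "empty")
})

test_that("pocket hydrophobicity ordering matches mean hydropathy", {
  # identical geometry, different residue identity -> uniform SASA weights
  mk <- function(resname) {
    xyz <- as.matrix(expand.grid(c(0, 4), c(0, 4), c(0, 4)))
    s <- cloud_structure(xyz)
    s$atoms$resname <- resname
    s
  }
  score <- function(rn) {
    s <- mk(rn)
    pocket_hydrophobicity(s, seq_len(8))$score
  }
  kd <- kyte_doolittle()
  expect_gt(score("ILE"), score("SER"))
  expect_gt(score("SER"), score("ASP"))
  expect_equal(score("VAL"), kd[["V"]], tolerance = 1e-9)
})

test_that("pocket water counting honours the cutoff and tail mean", {
  pocket_xyz <- matrix(0, 1, 3)
  mk_frame <- function(n_near, n_far) {
    wats <- rbind(
      if (n_near) cbind(3, seq_len(n_near) * 0.01, 0),
      if (n_far) cbind(20, seq_len(n_far) * 0.01, 0))
    rbind(pocket_xyz, wats)
  }
  n_wat <- 53
  atoms <- data.frame(
    serial = seq_len(1 + n_wat),
    name = c("CA", rep("O", n_wat)),
    element = c("C", rep("O", n_wat)),
    resname = c("GLY", rep("HOH", n_wat)),
    resno = seq_len(1 + n_wat), chain = "A",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  topo <- structure_model(atoms)
  fr <- mk_frame(3, 50)
  tr <- frames_trajectory(topo, list(fr, fr))
  res <- count_pocket_waters(tr, pocket_sel = 1, cutoff = 5)
  expect_identical(res$counts, c(3L, 3L))
  expect_identical(count_pocket_waters(tr, 1, cutoff = 0.1)$counts,
                   c(0L, 0L))
  # planted linear decay: tail mean within 1 of the planted tail value
  counts_plan <- round(seq(30, 10, length.out = 20))
  frames <- lapply(counts_plan, function(k) mk_frame(k, n_wat - k))
  tr2 <- frames_trajectory(topo, frames)
  res2 <- count_pocket_waters(tr2, 1, cutoff = 5)
  expect_identical(res2$counts, as.integer(counts_plan))
  expect_lt(abs(res2$tail_mean - mean(counts_plan[16:20])), 1)
  # no waters at all -> zeros with a warning
  dry <- cloud_structure(matrix(0, 1, 3))
  trd <- frames_trajectory(dry, list(matrix(0, 1, 3), matrix(0, 1, 3)))
  expect_warning(resd <- count_pocket_waters(trd, 1), "no water")
  expect_identical(resd$counts, c(0L, 0L))
})
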
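# Conformer-ensemble statistics: distances, satisfaction, hydrogen bonds,
# superposition RMSD and clustering.

make_two_atom_ensemble <- function(n = 3, d = 3.0) {
  atoms <- data.frame(chain = c("A", "A"), resno = 1, resid = "LIG",
                      elety = c("H1", "H2"))
  xyz <- matrix(rep(c(0, 0, 0, 0, 0, d), n), nrow = n, byrow = TRUE)
  conformer_ensemble(atoms, xyz)
}

test_that("interproton distances are Euclidean, in model order", {
  ens <- make_two_atom_ensemble(4, 3.0)
  expect_equal(interproton_distances(ens, c("A:1:H1", "A:1:H2")),
               rep(3.0, 4))
  expect_error(interproton_distances(ens, c("A:1:H1", "A:1:H9")),
               "matches no atom")
  # ambiguous selector
  ens2 <- ens; ens2$atoms$elety <- c("H1", "H1")
  expect_error(interproton_distances(ens2, c("A:1:H1", "A:1:H1")),
               "ambiguous")
  expect_error(resolve_selector(ens, "A:1"), "malformed")
})

test_that("toy-ensemble distances follow the prescribed Gaussian", {
  ens <- gen_toy_ensemble(500, data.frame(mean_A = 4.0, sd_A = 0.2),
                          seed = 11)
  d <- interproton_distances(ens, c("L:1:HA", "D:1:HB"))
  expect_equal(mean(d), 4.0, tolerance = 0.03 / 4.0)
  expect_equal(sd(d), 0.2, tolerance = 0.15)
})

test_that("satisfaction fractions count strict threshold crossings", {
  d <- c(3.2, 3.9, 4.5, 5.1)
  sf <- satisfaction_fractions(d, c(0, 4.0, 5.5))
  expect_equal(sf$percent, c(0, 50, 100))
  # monotone non-decreasing in threshold, always
  sf2 <- satisfaction_fractions(d, seq(2, 6, by = 0.25))
  expect_true(all(diff(sf2$percent) >= 0))
  # strict "<": a distance exactly at the threshold does not count
  expect_equal(satisfaction_fractions(c(4, 4), 4)$percent, 0)
  expect_error(satisfaction_fractions(numeric(0), 4), "non-empty")
})

test_that("satisfaction matches the Gaussian CDF on generated ensembles", {
  mean_A <- 4.0; sd_A <- 0.2; n <- 1000
  thresholds <- c(3.8, 4.0, 4.2)
  for (seed in 1:3) {
    ens <- gen_toy_ensemble(n, data.frame(mean_A = mean_A, sd_A = sd_A),
                            seed = seed)
    d <- interproton_distances(ens, c("L:1:HA", "D:1:HB"))
    sf <- satisfaction_fractions(d, thresholds)
    predicted <- 100 * pnorm(thresholds, mean_A, sd_A)
    # within ~3 Monte-Carlo standard errors (p ~ 0.5 -> se ~ 1.6%)
    expect_true(all(abs(sf$percent - predicted) < 5))
  }
})

test_that("hydrogen-bond occupancy applies both geometric criteria", {
  # linear N-H...O at 2.9 A in every model
  atoms <- data.frame(chain = "A", resno = 1, resid = "RES",
                      elety = c("N", "H", "O"))
  lin <- c(0, 0, 0, 1, 0, 0, 2.9, 0, 0)
  far <- c(0, 0, 0, 1, 0, 0, 4.2, 0, 0)
  bent <- c(0, 0, 0, 1, 0, 0, 1, 2.9, 0)  # 90 degrees at H
  ens_all <- conformer_ensemble(atoms, rbind(lin, lin))
  expect_equal(hbond_occupancy(ens_all, "A:1:N", "A:1:H", "A:1:O"), 100)
  ens_half <- conformer_ensemble(atoms, rbind(lin, far))
  expect_equal(hbond_occupancy(ens_half, "A:1:N", "A:1:H", "A:1:O"), 50)
  ens_bent <- conformer_ensemble(atoms, rbind(bent, bent))
  expect_equal(hbond_occupancy(ens_bent, "A:1:N", "A:1:H", "A:1:O"), 0)
  # monotone non-increasing as the distance cutoff tightens
  occs <- vapply(c(4.5, 3.5, 2.5, 1.5), function(cut)
    hbond_occupancy(ens_half, "A:1:N", "A:1:H", "A:1:O",
                    hbond_criterion(max_DA_distance = cut)),
    numeric(1))
  expect_true(all(diff(occs) <= 0))
})

test_that("generated H-bond triples hit the target occupancy", {
  ens <- gen_toy_ensemble(
    400, data.frame(mean_A = 4, sd_A = 0.1),
    hbond_spec = list(DA_distance = 2.9, DHA_angle = 165,
                      occupancy_fraction = 0.7),
    seed = 21)
  occ <- hbond_occupancy(ens, "L:90:DON", "L:90:HDN", "D:90:ACC")
  expect_equal(occ, 70, tolerance = 8 / 70)
  # tightening the angle past the generated 165 degrees kills them all
  expect_equal(hbond_occupancy(ens, "L:90:DON", "L:90:HDN", "D:90:ACC",
                               hbond_criterion(3.5, 179)), 0)
})

test_that("kabsch_rmsd is zero under rigid motion, symmetric, rotation
           invariant", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  expect_equal(kabsch_rmsd(a, a + 5), 0, tolerance = 1e-10)
  R <- random_rotation(3)
  expect_equal(kabsch_rmsd(a, a %*% R + 2), 0, tolerance = 1e-10)
  b <- a + matrix(rnorm(30, 0, 0.5), 10, 3)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-12)
  # invariant to a global rotation of both models
  expect_equal(kabsch_rmsd(a %*% R, b %*% R), kabsch_rmsd(a, b),
               tolerance = 1e-10)
  expect_gt(kabsch_rmsd(a, b), 0)
  expect_error(kabsch_rmsd(a[1:2, ], b[1:2, ]), "at least 3")
  # single displaced atom: RMSD bounded by displacement / sqrt(n)
  b2 <- a; b2[1, 1] <- b2[1, 1] + 1
  expect_lte(kabsch_rmsd(a, b2), 1 / sqrt(10) + 1e-9)
})

test_that("kabsch_rmsd agrees with independent oracles", {
  # brute-force rotational grid on small atom sets
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    analytic <- kabsch_rmsd(a, b)
    gridmin <- grid_min_rmsd(a, b, n = 30)
    expect_lte(analytic, gridmin + 1e-9)   # analytic optimum is minimal
    expect_lt(gridmin - analytic, 0.3)     # grid approaches it
  }
  # cross-check against bio3d's superposition RMSD
  set.seed(10)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, 0, 0.4), 10, 3)
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(kabsch_rmsd(a, b), ref, tolerance = 1e-3)
})

test_that("clustering recovers planted partitions across seeds", {
  tmpl <- make_templates()
  expect_gt(kabsch_rmsd(tmpl[[1]], tmpl[[2]]), 3)  # well separated
  for (seed in 1:10) {
    g <- gen_planted_ensemble(tmpl, 3, jitter_sd = 0.1, seed = seed)
    cl <- cluster_ensemble(g$ensemble, k = 2, seed = seed)
    expect_equal(sort(cl$populations), c(3, 3))
    # partition identical to construction up to label permutation
    expect_equal(length(unique(cl$labels[g$group == 1])), 1)
    expect_equal(length(unique(cl$labels[g$group == 2])), 1)
    expect_false(cl$labels[1] == cl$labels[4])
  }
})

test_that("clustering handles k = 1, degenerate input and pruning", {
  tmpl <- make_templates()
  g <- gen_planted_ensemble(tmpl[1], 6, jitter_sd = 0.1, seed = 2)
  cl <- cluster_ensemble(g$ensemble, k = 1, seed = 1)
  expect_equal(cl$populations, 6)
  expect_equal(length(cl$pruned), 0)
  # all-identical models with k = 2 collapse to one cluster
  gid <- gen_planted_ensemble(tmpl[1], 5, jitter_sd = 0, seed = 1)
  cl2 <- cluster_ensemble(gid$ensemble, k = 2, seed = 1)
  expect_equal(cl2$populations, 5)
  # a lone outlier conformation is pruned
  set.seed(5); tC <- matrix(rnorm(30, sd = 3), 10, 3)
  g3 <- gen_planted_ensemble(c(tmpl, list(tC)), c(10, 10, 1),
                             jitter_sd = 0.1, seed = 3)
  cl3 <- cluster_ensemble(g3$ensemble, k = 3,
                          min_population_fraction = 0.1, seed = 7)
  expect_equal(cl3$pruned, 21)
  expect_true(is.na(cl3$labels[21]))
  expect_equal(sum(cl3$populations), 20)
  # medoids are members of their clusters
  for (i in seq_along(cl3$medoids))
    expect_equal(cl3$labels[cl3$medoids[i]], i)
  expect_error(cluster_ensemble(g3$ensemble, k = 50), "exceeds")
})

test_that("clustering is deterministic under a fixed seed", {
  tmpl <- make_templates()
  g <- gen_planted_ensemble(tmpl, 5, jitter_sd = 0.3, seed = 4)
  a <- cluster_ensemble(g$ensemble, k = 2, seed = 9)
  b <- cluster_ensemble(g$ensemble, k = 2, seed = 9)
  expect_identical(a, b)
})

test_that("multi-model PDB writing and reading round-trips", {
  ens <- gen_toy_ensemble(5, data.frame(mean_A = c(3, 4), sd_A = 0.2),
                          seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  ens2 <- read_ensemble(f)
  expect_equal(nrow(ens2$xyz), 5)
  expect_equal(ens2$atoms$elety, ens$atoms$elety)
  expect_equal(ens2$xyz, ens$xyz, tolerance = 1e-3,
               ignore_attr = TRUE)
  # identical seed -> byte-identical files
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(gen_toy_ensemble(5, data.frame(mean_A = c(3, 4),
                                                sd_A = 0.2), seed = 6),
                 f2)
  expect_identical(readLines(f), readLines(f2))
})
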
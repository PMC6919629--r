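# Generators: planted proteomes, PSM sets, gradients, biased walks.

test_that("planted proteomes are deterministic and decoys are motif-free", {
  pp1 <- make_proteome(n_decoys = 15,
                       planted_classes = rep("CTERM_GLY_BASIC", 3),
                       seed = 61)
  pp2 <- make_proteome(n_decoys = 15,
                       planted_classes = rep("CTERM_GLY_BASIC", 3),
                       seed = 61)
  expect_identical(vapply(pp1$records, `[[`, character(1), "sequence"),
                   vapply(pp2$records, `[[`, character(1), "sequence"))
  for (rec in pp1$records[1:15]) {
    expect_equal(nrow(scan_cleavage_sites(rec)), 0L)
    expect_equal(nrow(predict_amidation_sites(rec)), 0L)
  }
  expect_error(make_proteome(planted_classes = "WRONG"), "unknown")
  expect_error(make_proteome(scaffold_length = 5), "too short")
})

test_that("screen recovers planted truth exactly across site classes", {
  classes <- c(rep("INTERNAL_PC", 3), rep("INTERNAL_FURIN", 2),
               rep("CTERM_GLY", 4), rep("CTERM_GLY_BASIC", 5))
  pp <- make_proteome(n_decoys = 30, planted_classes = classes, seed = 62)
  s <- screen_proteome(pp$records)$summary
  expect_equal(s$n_pc_amidation, 3L)
  expect_equal(s$n_furin_amidation, 2L)
  expect_equal(s$n_cterm_gly, 4L)
  expect_equal(s$n_cterm_gly_basic, 5L)
  # zero planted: all planted-class tallies zero
  s0 <- screen_proteome(make_proteome(n_decoys = 10, seed = 63)$records)
  expect_equal(s0$summary$n_pc_amidation +
                 s0$summary$n_cterm_gly + s0$summary$n_cterm_gly_basic, 0L)
})

test_that("PSM fixtures are reproducible and decoys avoid candidate windows", {
  ex <- example_amidated_precursors()
  planted <- data.frame(peptide = ex$peptides,
                        parent_protein_id = "p")
  a <- make_psm_sets(planted, ex$records, n_decoys = 20,
                     processing = ex$processing, seed = 64)
  b <- make_psm_sets(planted, ex$records, n_decoys = 20,
                     processing = ex$processing, seed = 64)
  expect_identical(a, b)
  cand <- build_amidation_candidates(ex$records, ex$processing)
  dec <- a$observed_neutral_mass[a$is_decoy]
  min_gap <- vapply(dec, function(m)
    min(abs(m - cand$mono_mass) / cand$mono_mass * 1e6), numeric(1))
  expect_true(all(min_gap >= 30))   # 3x the 10 ppm tolerance
  # planted masses sit within the stated noise band
  pl <- a[!a$is_decoy & a$peptide_sequence == "PLVPAAAG", ]
  theo <- peptide_mass("PLVPAAA", "C_TERM_AMIDE")
  expect_true(all(abs(pl$observed_neutral_mass - theo) / theo * 1e6 <= 3))
  expect_error(make_psm_sets(planted, ex$records, noise_ppm = -1), ">= 0")
})

test_that("diffusion gradient conserves mass and decreases away from the bolus", {
  g <- simulate_gradient(times = c(0, 3600, 21600, 1e8))
  dx <- diff(g$x)[1]
  mass <- apply(g$conc, 2, function(cc)
    sum((cc[-1] + cc[-length(cc)]) / 2) * dx)
  expect_true(all(abs(mass - g$total_mass) < 1e-6 * g$total_mass))
  expect_true(all(apply(g$conc, 2, function(cc) all(diff(cc) <= 1e-9))))
  # t = 0: essentially all mass inside the loading segment
  in_bolus <- g$x <= g$a
  m0 <- sum(g$conc[in_bolus, 1]) * dx
  expect_gt(m0 / g$total_mass, 0.95)
  # t -> infinity: uniform at mass / L
  expect_equal(unname(g$conc[, 4]), rep(g$total_mass / g$L, length(g$x)),
               tolerance = 1e-6)
  # stable regime: 1 h and 6 h profiles highly correlated
  expect_gt(cor(g$conc[, 2], g$conc[, 3]), 0.9)
  expect_error(simulate_gradient(D = -1), "positive")
})

test_that("trajectories keep speeds in band and respond to bias direction", {
  tr <- simulate_trajectories(walk_params(n_cells = 100, lambda = 0.5,
                                          seed = 65))
  st <- population_com(tr)
  expect_true(st$mean_speed > 100 && st$mean_speed < 150)
  expect_lt(st$com[["x"]], 0)       # attraction points up-gradient (-x)
  trn <- simulate_trajectories(walk_params(n_cells = 100, lambda = -0.5,
                                           seed = 65))
  expect_gt(population_com(trn)$com[["x"]], 0)
  # determinism under a fixed seed
  tr2 <- simulate_trajectories(walk_params(n_cells = 100, lambda = 0.5,
                                           seed = 65))
  expect_identical(tr, tr2)
  expect_error(walk_params(lambda = 1.5), "lambda")
})

test_that("bias is recoverable from step headings", {
  for (lam in c(0.2, 0.5)) {
    tr <- simulate_trajectories(walk_params(n_cells = 200, lambda = lam,
                                            seed = 66))
    expect_equal(estimate_bias(tr), lam, tolerance = 0.2 * lam)
  }
})

test_that("region counts show attraction as region-2 enrichment", {
  g <- simulate_gradient(times = 3600 * (1:4))
  rc0 <- simulate_region_counts(walk_params(n_cells = 400, lambda = 0,
                                            seed = 67),
                                gradient = g, times_h = 4)
  rc1 <- simulate_region_counts(walk_params(n_cells = 400, lambda = 0.5,
                                            seed = 67),
                                gradient = g, times_h = 4)
  expect_equal(rc0$n0 + rc0$n1 + rc0$n2, 400L)
  expect_gt(rc1$n2 / rc1$n1, rc0$n2 / rc0$n1)
  # repulsion drives the ratio below the unbiased one
  rcm <- simulate_region_counts(walk_params(n_cells = 400, lambda = -0.5,
                                            seed = 67),
                                gradient = g, times_h = 4)
  expect_lt(rcm$n2 / rcm$n1, rc0$n2 / rc0$n1)
})
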
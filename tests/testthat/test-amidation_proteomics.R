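# Spectral-count operations and the Gly-loss + amide evidence screen.

mat6 <- function(counts, n_samples = 6) {
  m <- matrix(counts, ncol = n_samples, byrow = TRUE)
  dimnames(m) <- list(paste0("p", seq_len(nrow(m))),
                      paste0("S", seq_len(n_samples)))
  m
}

test_that("normalization equalizes sample totals and conserves the grand total", {
  m <- matrix(c(60, 40, 120, 180), 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  nm <- normalize_counts(m)   # totals 100 and 300, mean 200
  expect_equal(attr(nm, "scale_factors"), c(S1 = 2, S2 = 2 / 3),
               tolerance = 1e-9)
  expect_equal(unname(colSums(nm)), c(200, 200))
  expect_equal(sum(nm), sum(m), tolerance = 1e-9 * sum(m))
  # equal totals: identity; single sample: identity
  m2 <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_equal(normalize_counts(m2), m2, ignore_attr = TRUE)
  m3 <- matrix(c(3, 4), 2, dimnames = list(c("a", "b"), "S1"))
  expect_equal(normalize_counts(m3), m3, ignore_attr = TRUE)
  mz <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_error(normalize_counts(mz), "S2")
  # grand total conserved on a random matrix
  set.seed(31)
  mr <- mat6(rpois(60, 20), 6)
  expect_equal(sum(normalize_counts(mr)), sum(mr),
               tolerance = 1e-9 * sum(mr))
})

test_that("presence filter applies the >= min_samples replicate rule", {
  m <- mat6(c(1, 1, 1, 0, 0, 0,
              2, 2, 2, 2, 0, 0,
              1, 1, 1, 1, 1, 1))
  expect_equal(rownames(presence_filter(m, 4)), c("p2", "p3"))
  expect_equal(rownames(presence_filter(m, 6)), "p3")
  expect_equal(presence_filter(m, 1), m)
  expect_error(presence_filter(m, 7), "min_samples")
  expect_error(presence_filter(m, 0), "min_samples")
  # nesting: higher thresholds keep a subset
  for (k in 2:6)
    expect_true(all(rownames(presence_filter(m, k)) %in%
                    rownames(presence_filter(m, k - 1))))
})

test_that("abundance share is the deterministic top-k fraction", {
  x <- c(a = 50, b = 30, c = 20)
  expect_equal(abundance_share(x, 1), 0.5)
  expect_equal(abundance_share(x, 3), 1)
  expect_equal(abundance_share(x, 0), 0)
  # ties broken by stable sort on protein id
  expect_equal(abundance_share(c(d = 5, b = 5, c = 5, a = 5), 2), 0.5)
  expect_error(abundance_share(c(a = 0, b = 0), 1), "zero")
  expect_error(abundance_share(x, 4), "k must be")
  # non-decreasing in k
  set.seed(32)
  y <- setNames(rexp(30), paste0("p", 1:30))
  shares <- vapply(0:30, function(k) abundance_share(y, k), numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[31], 1)
})

test_that("dataset merging keys on protein id with zero fill", {
  a <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("A1", "A2")))
  b <- matrix(2, 2, 2, dimnames = list(c("y", "z"), c("B1", "B2")))
  m <- merge_detection_matrices(a, b)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(m["x", "B1"], 0)
  expect_equal(m["z", "B2"], 2)
  expect_error(merge_detection_matrices(a, a), "disjoint")
})

test_that("screen matches observed masses against candidate amidated peptides", {
  rec <- protein_record("prec", "PLVPAAAGR")
  psm <- data.frame(sample_id = "S1", peptide_sequence = "PLVPAAAG",
                    observed_neutral_mass = 636.3959,
                    parent_protein_id = "prec")
  calls <- gly_loss_amide_screen(psm, list(rec), tol_ppm = 10,
                                 min_samples = 1)
  expect_equal(calls$peptide, "PLVPAAA")
  expect_equal(calls$glycine_extended_parent, "PLVPAAAG")
  expect_lt(calls$max_abs_error_ppm, 1)
  # 50 ppm off at 10 ppm tolerance: no call
  psm_off <- transform(psm, observed_neutral_mass =
                         observed_neutral_mass * (1 + 50e-6))
  expect_equal(nrow(gly_loss_amide_screen(psm_off, list(rec),
                                          min_samples = 1)), 0L)
  # empty candidate set warns and returns no calls
  expect_warning(
    out <- gly_loss_amide_screen(psm, list(protein_record("d", "AAAA")),
                                 min_samples = 1),
    "no candidate")
  expect_equal(nrow(out), 0L)
})

test_that("replicate consensus recovers exactly the planted amidated peptides", {
  ex <- example_amidated_precursors()
  planted <- data.frame(peptide = ex$peptides,
                        parent_protein_id = c("pre_GATI", "pre_PLVPAAA",
                                              "pre_GELN"))
  psms <- make_psm_sets(planted, ex$records, n_replicates = 6,
                        noise_ppm = 3, n_decoys = 25,
                        processing = ex$processing, seed = 33)
  calls <- gly_loss_amide_screen(psms, ex$records, tol_ppm = 10,
                                 min_samples = 6,
                                 processing = ex$processing)
  expect_equal(nrow(calls), 3L)
  expect_setequal(calls$peptide, ex$peptides)
  expect_true(all(calls$n_samples == 6L))
  # a peptide present in only 5 of 6 samples fails the all-6 consensus
  drop_one <- psms[!(psms$sample_id == "S6" &
                       psms$peptide_sequence == "PLVPAAAG"), ]
  calls5 <- gly_loss_amide_screen(drop_one, ex$records, tol_ppm = 10,
                                  min_samples = 6,
                                  processing = ex$processing)
  expect_setequal(calls5$peptide,
                  setdiff(ex$peptides, "PLVPAAA"))
})

test_that("decoy-only PSM sets never produce consensus calls", {
  ex <- example_amidated_precursors()
  for (seed in 1:10) {
    psms <- make_psm_sets(data.frame(peptide = character(),
                                     parent_protein_id = character()),
                          ex$records, n_replicates = 6, n_decoys = 30,
                          processing = ex$processing, seed = seed)
    calls <- gly_loss_amide_screen(psms, ex$records, tol_ppm = 10,
                                   min_samples = 6,
                                   processing = ex$processing)
    expect_equal(nrow(calls), 0L)
  }
})
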
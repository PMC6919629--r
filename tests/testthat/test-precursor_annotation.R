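# Motif scanning, amidation-site prediction, precursor processing,
# topology classification and the proteome screen.

test_that("cleavage motif scan finds all and only the motif windows", {
  s1 <- scan_cleavage_sites("AAKRGA", "PC")
  expect_equal(nrow(s1), 1L)
  expect_equal(unlist(s1[1, c("start", "end", "cleavage_after")]),
               c(start = 3L, end = 4L, cleavage_after = 4L))
  expect_equal(nrow(scan_cleavage_sites("AAAA")), 0L)
  # overlapping dipeptide windows are both reported
  s2 <- scan_cleavage_sites("AKRRA", "PC")
  expect_equal(s2$start, c(2L, 3L))
  # furin R-X-(K/R)-R, cleaved after the final R
  s3 <- scan_cleavage_sites("ARAKRA", "FURIN")
  expect_equal(unlist(s3[1, c("start", "end", "cleavage_after")]),
               c(start = 2L, end = 5L, cleavage_after = 5L))
  # X inside a candidate motif rejects the motif
  expect_equal(nrow(scan_cleavage_sites("AKXRA")), 0L)
  expect_equal(nrow(scan_cleavage_sites("RXKR", "FURIN")), 0L)
  expect_error(scan_cleavage_sites(""), "non-empty")
  expect_error(scan_cleavage_sites("AKRA", character(0)), "non-empty subset")
})

test_that("scan agrees with an exhaustive window oracle on random sequences", {
  set.seed(21)
  for (i in 1:30) {
    s <- random_peptide(sample(4:60, 1))
    got <- scan_cleavage_sites(s)
    want <- oracle_scan_sites(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$start, want$end), ]
      expect_equal(got[, c("kind", "start", "end")], want,
                   ignore_attr = TRUE)
    }
    # dropping a motif kind never increases the number of sites
    expect_lte(nrow(scan_cleavage_sites(s, "PC")), nrow(got))
    expect_lte(nrow(scan_cleavage_sites(s, "FURIN")), nrow(got))
  }
})

test_that("amidation sites require a donor Gly with an N-terminal neighbor", {
  # intact precursor terminus -G R: Gly(K/R)n route
  a1 <- predict_amidation_sites("PLVPAAAGR")
  expect_equal(a1$class, "CTERM_GLY_BASIC")
  expect_equal(a1$glycine_index, 8L)
  expect_equal(a1$amidated_residue, 7L)
  a2 <- predict_amidation_sites("AAAAG")
  expect_equal(a2$class, "CTERM_GLY")
  expect_equal(a2$glycine_index, 5L)
  a3 <- predict_amidation_sites("AAGKRAA")
  expect_equal(a3$class, "INTERNAL_PC")
  expect_equal(a3$glycine_index, 3L)
  # Gly at position 1 never yields a site
  expect_equal(nrow(predict_amidation_sites("GKRAA")), 0L)
  expect_equal(nrow(predict_amidation_sites("G")), 0L)
  # a basic run longer than max_basic_run blocks the C-terminal class
  # (the G-before-RRRR context still scores as an internal furin site)
  expect_false("CTERM_GLY_BASIC" %in%
                 predict_amidation_sites("AAGRRRR", max_basic_run = 3)$class)
  expect_true("CTERM_GLY_BASIC" %in%
                predict_amidation_sites("AAGRRRR", max_basic_run = 4)$class)
  expect_error(predict_amidation_sites("AAG", max_basic_run = 0), ">= 1")
  # a glycine abutting both a furin motif and its embedded PC pair is
  # classified once, as furin
  af <- predict_amidation_sites("AAGRKKRAA")
  expect_equal(af$class, "INTERNAL_FURIN")
  expect_equal(nrow(af), 1L)
})

test_that("precursor processing reproduces the three worked routes", {
  # carboxypeptidase-B trimming of an intact -GRRR terminus
  p1 <- process_precursor("VLYPNDPAAYAAYAPGTGGGATIGRRR")
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$sequence, "VLYPNDPAAYAAYAPGTGGGATI")
  expect_true(p1$amidated)
  expect_equal(p1$glycine_extended_sequence, "VLYPNDPAAYAAYAPGTGGGATIG")
  # endoproteolysis then Arg + His removal exposes the donor Gly
  p2 <- suppressWarnings(
    process_precursor("GELNPAGGQLPGGHRKRA",
                      processing_config(his_trim = TRUE)))
  expect_equal(p2$sequence[p2$amidated], "GELNPAGGQLPG")
  # without His trimming the route is blocked
  p3 <- suppressWarnings(process_precursor("GELNPAGGQLPGGHRKRA"))
  expect_false(any(p3$amidated))
  # no sites, no Gly: the intact chain is returned non-amidated
  p4 <- process_precursor("AAAA")
  expect_equal(p4$sequence, "AAAA")
  expect_false(p4$amidated)
  # short products are dropped with a warning
  expect_warning(process_precursor("AAAKRAG"), "min_length")
})

test_that("signal peptide region is excluded from products", {
  rec <- protein_record("p", "MKLLLLLLLLAAAKRVLYPNDPAAYAAYAPGTGGGATIGRRR",
                        has_signal_peptide = TRUE, signal_peptide_end = 13L)
  p <- process_precursor(rec)
  expect_true(all(p$start > 13L))
  expect_true("VLYPNDPAAYAAYAPGTGGGATI" %in% p$sequence)
})

test_that("re-processing an amidated product returns it unchanged", {
  set.seed(22)
  pp <- make_proteome(n_decoys = 0,
                      planted_classes = rep(c("CTERM_GLY_BASIC",
                                              "INTERNAL_PC"), 5),
                      seed = 22)
  for (rec in pp$records) {
    prods <- suppressWarnings(process_precursor(rec))
    for (s in prods$sequence[prods$amidated]) {
      again <- suppressWarnings(process_precursor(s))
      expect_equal(again$sequence, s)
      expect_false(any(again$amidated))
    }
  }
})

test_that("topology classification is a deterministic annotation rule", {
  rec <- function(sig, tmh) protein_record("p", strrep("A", 200),
                                           has_signal_peptide = sig,
                                           tmh_spans = tmh)
  expect_equal(classify_topology(rec(TRUE, list())), "SECRETED")
  expect_equal(classify_topology(rec(TRUE, list(c(10, 32)))),
               "TYPE_I_MEMBRANE")
  expect_equal(classify_topology(rec(FALSE, list(c(10, 32)))),
               "TYPE_II_MEMBRANE")
  expect_equal(classify_topology(rec(FALSE, list(c(10, 32), c(100, 122)))),
               "MULTIPASS")
  expect_equal(classify_topology(rec(FALSE, list())), "NON_SECRETORY")
  expect_equal(classify_topology(rec(FALSE, list(c(100, 122)))),
               "NON_SECRETORY")
  expect_error(classify_topology(protein_record("p", "AAAA")),
               "annotation required")
})

test_that("proteome screen tallies proteins per hallmark category", {
  r <- protein_record("p1", "MAAKRGAG", has_signal_peptide = TRUE,
                      tmh_spans = list())
  scr <- screen_proteome(list(r))
  expect_equal(scr$summary$n_signal, 1L)
  expect_equal(scr$summary$n_pc_sites, 1L)
  expect_equal(scr$summary$n_cterm_gly, 1L)
  expect_equal(scr$summary$n_pc_amidation, 0L)
  empty <- screen_proteome(list())
  expect_true(all(unlist(empty$summary) == 0L))
  # count invariants on a mixed synthetic proteome
  pp <- make_proteome(n_decoys = 20,
                      planted_classes = c(rep("INTERNAL_PC", 4),
                                          rep("CTERM_GLY", 3)), seed = 23)
  s <- screen_proteome(pp$records)$summary
  expect_lte(s$n_pc_amidation, s$n_pc_sites)
  expect_lte(s$n_furin_amidation, s$n_furin_sites)
  expect_lte(s$n_signal, s$n_total)
  expect_equal(s$n_pc_amidation, 4L)
  expect_equal(s$n_cterm_gly, 3L)
})

test_that("heuristic annotations flag themselves and find planted features", {
  # hydrophobic signal-like N-terminus with a basic n-region
  sp <- predict_signal_peptide(paste0("MKV", strrep("L", 17),
                                      strrep("STAQ", 20)))
  expect_true(sp$has_signal_peptide)
  expect_equal(sp$source, "heuristic")
  expect_false(predict_signal_peptide(strrep("DDES", 25))$has_signal_peptide)
  tm <- predict_tmh(paste0(strrep("Q", 30), strrep("L", 21),
                           strrep("Q", 30)))
  expect_equal(nrow(tm), 1L)
  expect_true(tm[1, "start"] >= 25 && tm[1, "end"] <= 57)
  expect_equal(nrow(predict_tmh(strrep("Q", 100))), 0L)
})
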
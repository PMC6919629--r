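#!/usr/bin/env Rscript
# Stage 2 — Gly-loss + amide evidence screen over six PSM replicates.
#
# Builds the three precursor C-terminal contexts known to generate
# amidated peptides (-GRRR trimming, -GR trimming, and endoproteolysis
# followed by Arg/His removal), simulates six PSM replicates with <= 5 ppm
# mass noise plus mass-separated decoys, and runs the screen at the
# 10 ppm search tolerance with all-six replicate consensus.

library(ciliapep)
dir.create("results", showWarnings = FALSE)

ex <- example_amidated_precursors()
planted <- data.frame(peptide = ex$peptides,
                      parent_protein_id = c("pre_GATI", "pre_PLVPAAA",
                                            "pre_GELN"))
psms <- make_psm_sets(planted, ex$records, n_replicates = 6, noise_ppm = 5,
                      n_decoys = 50, processing = ex$processing, seed = 1)
message(sprintf("Simulated %d PSMs across 6 replicates (%d decoys/replicate)",
                nrow(psms), 50))
write_psms(psms, "results/synthetic_psms.tsv")

calls <- gly_loss_amide_screen(psms, ex$records, tol_ppm = 10,
                               min_samples = 6, processing = ex$processing)
print(calls[, c("peptide", "parent_protein_id", "n_samples",
                "max_abs_error_ppm")])
write.table(calls, "results/amidation_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

stopifnot(nrow(calls) == 3,
          setequal(calls$peptide, ex$peptides))
message("Consensus screen recovered exactly the three amidated peptides; ",
        "no decoy produced a call.")
message("Wrote results/amidation_calls.tsv")
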
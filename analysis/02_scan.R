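#!/usr/bin/env Rscript
# Step 2 — sliding-window log-likelihood scan.
#
# Contrasts the no-conversion topology (branch lengths re-optimized per
# window) against the per-window constrained ML tree uniting the candidate
# converted pair, over 50-column windows advanced by 10 columns.  Positive
# delta = lnL(Tree_conv) - lnL(Tree_global) marks windows supporting
# conversion.  Reads results/01_simulate/, writes results/02_scan/.

suppressMessages(library(paraconv))
seed <- 2026
out <- "results/02_scan"

aln <- read_alignment("results/01_simulate/alignment.fasta", alphabet = "AA")
truth <- jsonlite::read_json("results/01_simulate/truth.json")
clade <- unlist(truth$conv_clade)

prof <- delta_lnl_profile(aln, clade, build_model("LG", alpha = 0.7),
                          width = 50, step = 10, seed = seed)
write_profile(prof, out)
write_run_manifest(out, "scan",
                   params = list(seed = seed, conv_clade = clade,
                                 model = "LG", width = 50, step = 10,
                                 alpha_hat = prof$alpha),
                   inputs = "results/01_simulate/alignment.fasta")

pos <- prof$windows$window[prof$windows$delta > 0]
cat("Wrote", out, "\n")
cat("Estimated gamma shape:", round(prof$alpha, 3), "\n")
cat("Windows with positive delta:", paste(pos, collapse = ", "),
    "(true tract spans windows 12-15)\n")
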
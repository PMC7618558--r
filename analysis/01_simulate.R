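#!/usr/bin/env Rscript
# Generate the synthetic two-sample dataset used by the downstream analysis
# scripts: a FinnGen-scale venous-thromboembolism-style exposure GWAS (35
# genome-wide significant instruments, log-odds effect 0.19 on the outcome),
# a Long COVID HGI-scale outcome GWAS with three outcome-specific
# instruments (no reverse effect), 200 null variants in AR(1) LD blocks,
# and the matching LD matrix. Everything is written as plain text under
# results/sim/ so the later scripts run from files, as a real analysis would.

library(mrforge)

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

truth <- sim_truth(theta = 0.19, L = 35,
                   reverse = list(L_rev = 3, eta_sd = 0.25, theta_rev = 0),
                   seed = 20260801)
sim <- simulate_pair(truth)

write_results(sim$exposure, "results/sim/exposure.tsv")
write_results(sim$outcome, "results/sim/outcome.tsv")
writeLines(sim$ld$variant_ids, "results/sim/ld_variants.txt")
write.table(format(sim$ld$r, digits = 10), "results/sim/ld_matrix.txt",
            row.names = FALSE, col.names = FALSE, quote = FALSE)
write_results(list(theta = truth$theta, L = truth$L, seed = truth$seed,
                   gamma = sim$truth$gamma,
                   instrument_ids = sim$truth$instrument_ids),
              "results/sim/truth.json", "json")

message(sprintf(
  "wrote %d exposure and %d outcome variant records (%d true instruments, ",
  nrow(sim$exposure), nrow(sim$outcome), truth$L),
  "theta = ", truth$theta, ") under results/sim/")
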
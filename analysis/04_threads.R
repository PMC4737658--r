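#!/usr/bin/env Rscript
# Stage 4: lag threads.
#
# Spatial PCA of the column-centered group TD matrix per state, with the
# Laplace-evidence (maximum-likelihood) dimensionality estimate, plus a
# planted-thread recovery check at the study's noise level.

suppressPackageStartupMessages(library(boldlag))

study <- read_study_container("results/03_td.rds")
td_state <- study$payload$td_by_state

scree <- list()
for (st in names(td_state)) {
  th <- lag_threads(td_state[[st]], k_max = 10)
  scree[[st]] <- data.frame(state = st,
                            component = seq_along(th$eigenvalues),
                            eigenvalue = th$eigenvalues,
                            share = th$eigenvalues / sum(th$eigenvalues))
  cat(sprintf("%s: ML dimensionality %s; leading eigenvalue carries %.1f%% of variance\n",
              st, th$dimensionality_ml, 100 * th$eigenvalues[1] /
                sum(th$eigenvalues)))
}
write.csv(do.call(rbind, scree), "results/04_scree.csv", row.names = FALSE)

# recovery control: planted 1-3 threads at SNR 5, 30 replicates each
set.seed(study$provenance$seed)
rec <- sapply(1:3, function(k) {
  mean(vapply(1:30, function(r) {
    td <- planted_thread_td(60, k, snr = 5,
                            seed = study$provenance$seed + 100 * k + r)
    lag_threads(td, k_max = 10)$dimensionality_ml == k
  }, logical(1)))
})
write.csv(data.frame(planted_k = 1:3, recovery_rate = rec),
          "results/04_thread_recovery.csv", row.names = FALSE)
cat(sprintf("planted-thread recovery at SNR 5 (30 reps): k=1 %.0f%%, k=2 %.0f%%, k=3 %.0f%%\n",
            100 * rec[1], 100 * rec[2], 100 * rec[3]))
cat("note: single-source group TD matrices estimated from noisy epochs carry\n")
cat("estimation noise that is not isotropic, so their ML dimensionality is\n")
cat("read qualitatively; the planted control quantifies recovery.\n")
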
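#!/usr/bin/env Rscript
# Stage 1: simulate the two-state synthetic study.
#
# Builds the reference study design — a wake-like and an SWS-like state on a
# 4 x 7 x 2 voxel lattice with seven named networks — and generates every
# subject-epoch from band-limited 1/f sources with planted per-voxel delays.
# Planted state differences: the subcortex-analog network reverses from
# early (wake) to late (SWS), the VIS network becomes uniformly early in
# SWS, and the SWS delay spread is doubled.

suppressPackageStartupMessages(library(boldlag))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 11L
dir.create("results", showWarnings = FALSE)

ex <- example_study_design(seed = seed)
epochs <- generate_study(ex$design)

# plant motion-like global spikes in a quarter of the epochs so the
# censoring stage has something to flag
set.seed(seed + 1L)
spiked <- sample(length(epochs), length(epochs) %/% 4)
for (i in spiked) {
  frames <- sample(10:140, 4)
  epochs[[i]] <- inject_artifacts(epochs[[i]], frames, spike_amplitude = 8)
}

write_study_container(list(epochs = epochs, lattice = ex$lattice,
                           partition = ex$partition,
                           delays_wake = ex$delays_wake,
                           delays_sws = ex$delays_sws,
                           subcortex_voxels = ex$subcortex_voxels,
                           early_network_voxels = ex$early_network_voxels),
                      "results/01_study.rds", seed = seed,
                      params = list(stage = "simulate"))

meta <- data.frame(
  subject = vapply(epochs, function(e) e$subject_id, ""),
  state = vapply(epochs, function(e) e$state_label, ""),
  epoch = vapply(epochs, function(e) e$epoch_id, 1L),
  n_voxels = vapply(epochs, function(e) nrow(e$data), 1L),
  n_frames = vapply(epochs, function(e) ncol(e$data), 1L),
  tr = vapply(epochs, function(e) e$tr, 1))
write.csv(meta, "results/01_epochs.csv", row.names = FALSE)

cat(sprintf("simulated %d epochs (%d voxels, %d frames, TR %.2f s) across %s\n",
            length(epochs), nrow(epochs[[1]]$data), ncol(epochs[[1]]$data),
            epochs[[1]]$tr,
            paste(unique(meta$state), collapse = " / ")))
cat(sprintf("planted: reversal in %d subcortex-analog voxels, %d all-early VIS voxels, 2x delay spread in sws\n",
            length(ex$subcortex_voxels), length(ex$early_network_voxels)))
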
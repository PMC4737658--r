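#!/usr/bin/env Rscript
# Stage 5: state-contrast statistics.
#
# Block-wise Spearman correlation of wake vs SWS lag structure, block mean
# lags with subject-level permutation, the lag-SD contrast, the cluster-
# extent permutation test on lag projections, and FC-difference PCA.

suppressPackageStartupMessages(library(boldlag))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 11L

study <- read_study_container("results/03_td.rds")
pay <- study$payload
pre <- read_study_container("results/02_preprocessed.rds")$payload$epochs
part <- pay$partition
td_subject <- pay$td_by_subject
subj_states <- pay$subject_states
sts <- unique(subj_states)

# block Spearman: intra- vs inter-network preservation of lag structure
bs <- block_spearman_test(pay$td_by_state[[sts[1]]], pay$td_by_state[[sts[2]]],
                          part, n_perm = 1000, seed = seed)
write.csv(bs, "results/05_block_spearman.csv", row.names = FALSE)
cat(sprintf("block Spearman rho (%s vs %s): diagonal median %.2f, off-diagonal median %.2f\n",
            sts[1], sts[2], median(bs$spearman_rho[bs$diagonal], na.rm = TRUE),
            median(bs$spearman_rho[!bs$diagonal], na.rm = TRUE)))

# block mean lags
bm <- block_mean_test(td_subject, subjects = names(td_subject),
                      states = subj_states, partition = part,
                      n_perm = 1000, seed = seed)
write.csv(bm$table, "results/05_block_means.csv", row.names = FALSE)
sig <- bm$table[bm$table$significant, ]
cat(sprintf("block mean-lag contrast: %d/%d off-diagonal blocks significant (%s)\n",
            nrow(sig), nrow(bm$table),
            paste(sig$block, collapse = ", ")))
cat(sprintf("diagonal-block means are zero by anti-symmetry (max |.| = %.1e)\n",
            max(abs(unlist(bm$diagonal_means)))))

# lag-SD contrast
sdres <- lag_sd_contrast(td_subject, subjects = names(td_subject),
                         states = subj_states, n_perm = 10000, seed = seed)
write.csv(data.frame(state = names(sdres$sd_mean), mean_lag_sd = sdres$sd_mean),
          "results/05_lag_sd.csv", row.names = FALSE)
cat(sprintf("lag SD: %s %.2f s vs %s %.2f s (p = %.4g, 10000 permutations)\n",
            names(sdres$sd_mean)[1], sdres$sd_mean[1],
            names(sdres$sd_mean)[2], sdres$sd_mean[2], sdres$p_value))

# cluster-extent test on per-subject lag projections
proj <- t(vapply(td_subject, function(td) lag_projection(td)$values,
                 numeric(td_subject[[1]]$n)))
adj <- lattice_adjacency(pay$lattice)
cl <- cluster_permutation_test(proj, subjects = names(td_subject),
                               states = subj_states, adjacency = adj,
                               z_threshold = 2.5, n_perm = 1000, seed = seed)
cl_tab <- do.call(rbind, lapply(seq_along(cl$clusters), function(i) {
  c0 <- cl$clusters[[i]]
  data.frame(cluster = i, extent = c0$extent, corrected_p = c0$corrected_p,
             significant = c0$significant,
             networks = paste(unique(part$names[part$labels[c0$voxels]]),
                              collapse = "+"))
}))
if (is.null(cl_tab)) cl_tab <- data.frame()
write.csv(cl_tab, "results/05_clusters.csv", row.names = FALSE)
cat(sprintf("cluster-extent test (|z| > 2.5): %d cluster(s), %d significant\n",
            length(cl$clusters),
            sum(vapply(cl$clusters, `[[`, logical(1), "significant"))))

# FC-difference PCA
subjects <- vapply(pre, function(e) e$subject_id, "")
fcs <- lapply(pre, function(e) zero_lag_fc(e)$z)
fc_subject <- group_average(fcs, subjects = subjects, states = subjects)
fp <- fc_difference_pca(lapply(fc_subject, function(g) g$mean),
                        subjects = names(fc_subject),
                        states = subj_states[match(names(fc_subject),
                                                   names(td_subject))],
                        n_perm = 500, seed = seed)
write.csv(data.frame(rank = seq_along(fp$null_q95),
                     eigenvalue = fp$eigenvalues[seq_along(fp$null_q95)],
                     null_q95 = fp$null_q95, significant = fp$significant),
          "results/05_fc_pca.csv", row.names = FALSE)
cat(sprintf("FC-difference PCA: %d significant component(s)\n",
            fp$n_significant))
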
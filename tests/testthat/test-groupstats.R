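make_td_set <- function(n_sub, n_vox, sd = 0.5, seed = 1, scale = 1) {
  lapply(seq_len(n_sub), function(s) {
    td <- random_td(n_vox, sd = sd, seed = seed * 1000 + s)
    td$td <- td$td * scale
    td
  })
}

test_that("a 7-network partition yields 28 unique blocks, 21 off-diagonal", {
  part <- network_partition(42)
  blocks <- boldlag:::block_entry_index(part)
  expect_length(blocks, 28)
  offd <- vapply(blocks, function(b) b$row_net != b$col_net, logical(1))
  expect_equal(sum(offd), 21)
  # block entry sets are disjoint and cover the upper-triangle orientation
  total <- sum(vapply(blocks, function(b) nrow(b$idx), integer(1)))
  expect_equal(total, 42 * 41 / 2)
})

test_that("block Spearman is 1 for identical matrices and ~0 for independent ones", {
  part <- network_partition(28, names = c("N1", "N2"))
  td <- random_td(28, seed = 5)
  bs <- block_spearman_test(td, td, part, n_perm = 100, seed = 1)
  expect_equal(nrow(bs), 3)
  expect_true(all(bs$spearman_rho == 1))
  expect_true(all(bs$significant))
  # independent anti-symmetric matrices: |rho| within the sampling bound
  td2 <- random_td(28, seed = 6)
  bs2 <- block_spearman_test(td, td2, part, n_perm = 100, seed = 1)
  expect_true(all(abs(bs2$spearman_rho) <= 3 / sqrt(bs2$n_pairs)))
  # blocks with <10 valid pairs are flagged without p-values
  part_small <- network_partition(8, names = c("A", "B", "C", "D"))
  tds <- random_td(8, seed = 7)
  bs3 <- block_spearman_test(tds, tds, part_small, n_perm = 50, seed = 1)
  expect_true(any(bs3$flagged))
  expect_true(all(is.na(bs3$p_value[bs3$flagged])))
})

test_that("diagonal-block means are exactly zero by anti-symmetry", {
  part <- network_partition(42)
  tds <- make_td_set(8, 42, seed = 2)
  states <- rep(c("A", "B"), each = 4)
  bm <- block_mean_test(tds, subjects = paste0("s", 1:8), states = states,
                        partition = part, n_perm = 100, seed = 3)
  for (st in c("A", "B"))
    expect_true(all(abs(bm$diagonal_means[[st]]) < 1e-12))
  expect_equal(nrow(bm$table), 21)
})

test_that("a planted all-early network is detected by the block-mean contrast", {
  part <- network_partition(42)
  vis <- which(part$labels == 4)
  mk <- function(s, early) {
    set.seed(400 + s)
    d <- rnorm(42, sd = 0.3)
    if (early) d[vis] <- d[vis] - 0.8
    td <- td_from_delays(d)
    td$td <- td$td + {E <- matrix(rnorm(42 * 42, sd = 0.05), 42, 42); E - t(E)}
    diag(td$td) <- 0
    td
  }
  tds <- c(lapply(1:5, mk, early = FALSE), lapply(6:10, mk, early = TRUE))
  bm <- block_mean_test(tds, subjects = paste0("s", 1:10),
                        states = rep(c("A", "B"), each = 5),
                        partition = part, n_perm = 300, seed = 4)
  tab <- bm$table
  vis_rows <- tab$net_row == "VIS" | tab$net_col == "VIS"
  expect_gt(sum(tab$significant[vis_rows]), 0)
  # direction: VIS early in state B means VIS rows negative, columns positive
  sigvis <- tab[vis_rows & tab$significant, ]
  dir_ok <- ifelse(sigvis$net_row == "VIS",
                   sigvis$difference < 0, sigvis$difference > 0)
  expect_true(all(dir_ok))
  # no spurious detections away from VIS
  expect_equal(sum(tab$significant[!vis_rows]), 0)
})

test_that("lag-SD contrast detects doubled spread and degenerates gracefully", {
  tdsA <- make_td_set(6, 30, seed = 11)
  tdsB <- make_td_set(6, 30, seed = 12, scale = 2)
  res <- lag_sd_contrast(c(tdsA, tdsB), subjects = paste0("s", 1:12),
                         states = rep(c("A", "B"), each = 6),
                         n_perm = 2000, seed = 5)
  expect_equal(unname(res$sd_mean["B"] / res$sd_mean["A"]), 2,
               tolerance = 0.05)
  expect_lt(res$p_value, 0.01)
  # one subject per state: p undefined
  res1 <- lag_sd_contrast(list(tdsA[[1]], tdsB[[1]]),
                          subjects = c("s1", "s2"), states = c("A", "B"),
                          n_perm = 100, seed = 6)
  expect_true(is.na(res1$p_value))
})

test_that("cluster test: degenerate thresholds, adjacency-free reduction, planted blob", {
  lat <- voxel_lattice(c(6, 6, 2))
  adj <- lattice_adjacency(lat)
  nv <- lat$n
  set.seed(7)
  maps <- matrix(rnorm(12 * nv), 12, nv)
  states <- rep(c("A", "B"), each = 6)
  # infinite threshold: no clusters ever
  r0 <- cluster_permutation_test(maps, paste0("s", 1:12), states, adj,
                                 z_threshold = Inf, n_perm = 100, seed = 1)
  expect_length(r0$clusters, 0)
  # planted blob: one lattice-contiguous region shifted in state B
  blob <- which(lat$coords[, 1] <= 1 & lat$coords[, 2] <= 1 &
                  lat$coords[, 3] == 0)
  maps2 <- maps
  maps2[states == "B", blob] <- maps2[states == "B", blob] + 6
  r1 <- cluster_permutation_test(maps2, paste0("s", 1:12), states, adj,
                                 z_threshold = 3, n_perm = 200, seed = 2)
  sig <- Filter(function(cl) cl$significant, r1$clusters)
  expect_gte(length(sig), 1)
  found <- sort(unique(unlist(lapply(sig, `[[`, "voxels"))))
  jaccard <- length(intersect(found, blob)) / length(union(found, blob))
  expect_gte(jaccard, 0.5)
  # empty adjacency: every supra-threshold voxel is its own cluster
  r2 <- cluster_permutation_test(maps2, paste0("s", 1:12), states, NULL,
                                 z_threshold = 3, n_perm = 100, seed = 3)
  expect_true(all(vapply(r2$clusters, `[[`, integer(1), "extent") == 1L))
  expect_warning(
    cluster_permutation_test(maps, paste0("s", 1:12), states, adj,
                             n_perm = 50, seed = 4),
    "coarse")
})

test_that("permutation procedures are reproducible under a seed", {
  part <- network_partition(42)
  tds <- make_td_set(8, 42, seed = 21)
  states <- rep(c("A", "B"), each = 4)
  b1 <- block_mean_test(tds, paste0("s", 1:8), states, part,
                        n_perm = 100, seed = 9)
  b2 <- block_mean_test(tds, paste0("s", 1:8), states, part,
                        n_perm = 100, seed = 9)
  expect_identical(b1$table, b2$table)
  s1 <- lag_sd_contrast(tds, paste0("s", 1:8), states, n_perm = 500, seed = 9)
  s2 <- lag_sd_contrast(tds, paste0("s", 1:8), states, n_perm = 500, seed = 9)
  expect_identical(s1$p_value, s2$p_value)
})

test_that("FC-difference PCA flags planted network-confined FC changes", {
  set.seed(8)
  n <- 30
  net <- 1:8                                # voxels with the planted change
  mk_fc <- function(bump) {
    base <- matrix(rnorm(n * n, sd = 0.05), n, n)
    z <- (base + t(base)) / 2
    if (bump) z[net, net] <- z[net, net] + 0.4
    diag(z) <- 0
    z
  }
  fcs <- c(lapply(1:5, function(i) mk_fc(FALSE)),
           lapply(1:5, function(i) mk_fc(TRUE)))
  res <- fc_difference_pca(fcs, subjects = paste0("s", 1:10),
                           states = rep(c("A", "B"), each = 5),
                           n_perm = 200, seed = 10)
  expect_gte(res$n_significant, 1)
  lead <- abs(res$topographies[, 1])
  expect_gt(mean(lead[net]), 3 * mean(lead[-net]))
  # zero difference: eigenvalues zero, nothing significant
  same <- lapply(1:10, function(i) fcs[[1]])
  res0 <- fc_difference_pca(same, subjects = paste0("s", 1:10),
                            states = rep(c("A", "B"), each = 5),
                            n_perm = 100, seed = 11)
  expect_lt(max(abs(res0$eigenvalues)), 1e-12)
  expect_equal(res0$n_significant, 0)
})
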
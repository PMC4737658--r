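#' @keywords internal
#' Permute subject state labels respecting pairing
#'
#' Subjects contributing maps to both states have their two labels swapped as
#' a pair (exchangeable within subject); subjects seen in a single state have
#' their labels shuffled freely. Returns a character matrix, one permuted
#' label vector per row.
permute_state_labels <- function(subjects, states, n_perm) {
  states <- as.character(states)
  n <- length(states)
  paired <- names(which(tapply(states, subjects, function(s) length(unique(s)) > 1)))
  is_paired <- subjects %in% paired
  out <- matrix(NA_character_, nrow = n_perm, ncol = n)
  free_idx <- which(!is_paired)
  for (r in seq_len(n_perm)) {
    lab <- states
    for (sj in paired) {
      idx <- which(subjects == sj)
      if (stats::runif(1) < 0.5) lab[idx] <- rev(lab[idx])
    }
    if (length(free_idx) > 1L)
      lab[free_idx] <- lab[sample(free_idx)]
    out[r, ] <- lab
  }
  out
}

voxelwise_z <- function(maps, grp) {
  a <- maps[grp, , drop = FALSE]
  b <- maps[!grp, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a * a) - na * ma * ma) / (na - 1)
  vb <- (colSums(b * b) - nb * mb * mb) / (nb - 1)
  z <- (ma - mb) / sqrt(va / na + vb / nb)
  z[!is.finite(z)] <- 0
  z
}

# connected components of `members` (voxel indices) under a neighbour list
connected_clusters <- function(members, adjacency) {
  if (length(members) == 0L) return(list())
  if (is.null(adjacency) || length(adjacency) == 0L)
    return(as.list(members))               # no adjacency: voxelwise clusters
  inset <- logical(length(adjacency))
  inset[members] <- TRUE
  seen <- logical(length(adjacency))
  clusters <- list()
  for (v in members) {
    if (seen[v]) next
    comp <- integer(0)
    stack <- v; seen[v] <- TRUE
    while (length(stack) > 0L) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, u)
      nb <- adjacency[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters
}

#' Cluster-extent permutation test on lag projection maps
#'
#' Two-state voxelwise comparison with family-wise error control by
#' threshold-extent permutation: the voxelwise z statistic (difference of
#' state means over its pooled standard error across subjects) is
#' thresholded at `|z| > z_threshold`, supra-threshold voxels are grouped
#' into connected clusters under the lattice adjacency, and each observed
#' cluster's extent is referred to the permutation null distribution of the
#' maximal cluster extent obtained by re-assigning state labels at the
#' subject level.
#'
#' @param maps `n_subjects x n_voxels` matrix of per-subject(-state) lag
#'   projection values.
#' @param subjects,states vectors labelling the rows of `maps`; `states`
#'   must have exactly 2 levels, each with >= 3 subjects.
#' @param adjacency neighbour list from [lattice_adjacency()]; `NULL` makes
#'   every voxel its own cluster (a voxelwise max-extent test).
#' @param z_threshold cluster-forming threshold on `|z|` (default 4.5).
#' @param alpha corrected significance level (default 0.05).
#' @param n_perm number of label permutations (values < 100 trigger a
#'   warning).
#' @param seed RNG seed for the permutations.
#' @return a `"cluster_result"`: list with `voxelwise_z`, `clusters` (list of
#'   `voxels`, `extent`, `corrected_p`, `significant`), `threshold_z`,
#'   `n_permutations`, `null_max_extent`.
#' @export
cluster_permutation_test <- function(maps, subjects, states, adjacency = NULL,
                                     z_threshold = 4.5, alpha = 0.05,
                                     n_perm = 1000L, seed = 1L) {
  maps <- as.matrix(maps)
  states <- as.character(states)
  lv <- unique(states)
  if (length(lv) != 2L) stop("need exactly 2 states")
  if (min(table(states)) < 3L) stop("need >= 3 subjects per state")
  if (n_perm < 100L) warning("n_perm < 100: corrected p-values are coarse")
  set.seed(as.integer(seed))
  grp <- states == lv[1L]
  z <- voxelwise_z(maps, grp)
  obs_clusters <- connected_clusters(which(abs(z) > z_threshold), adjacency)
  perm_labels <- permute_state_labels(subjects, states, n_perm)
  null_max <- integer(n_perm)
  for (r in seq_len(n_perm)) {
    zp <- voxelwise_z(maps, perm_labels[r, ] == lv[1L])
    cl <- connected_clusters(which(abs(zp) > z_threshold), adjacency)
    null_max[r] <- if (length(cl) == 0L) 0L else max(lengths(cl))
  }
  clusters <- lapply(obs_clusters, function(cc) {
    p <- (1 + sum(null_max >= length(cc))) / (n_perm + 1)
    list(voxels = cc, extent = length(cc), corrected_p = p,
         significant = p <= alpha)
  })
  structure(list(voxelwise_z = z, clusters = clusters,
                 threshold_z = z_threshold, n_permutations = n_perm,
                 null_max_extent = null_max, alpha = alpha,
                 state_order = lv),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(vapply(x$clusters, `[[`, logical(1), "significant"))
  cat(sprintf("<cluster_result> |z| > %g: %d cluster(s), %d significant at alpha = %g (%d permutations)\n",
              x$threshold_z, length(x$clusters), sig, x$alpha,
              x$n_permutations))
  invisible(x)
}

# entry indices of each unique network block: diagonal blocks use the upper
# triangle within the block, off-diagonal blocks the full row-net x col-net
# rectangle oriented p < q
block_entry_index <- function(partition) {
  m <- length(partition$names)
  lab <- partition$labels
  out <- list()
  for (p in seq_len(m)) for (q in p:m) {
    if (p == q) {
      vox <- which(lab == p)
      pairs <- which(upper.tri(diag(length(vox))), arr.ind = TRUE)
      idx <- cbind(vox[pairs[, 1L]], vox[pairs[, 2L]])
    } else {
      idx <- as.matrix(expand.grid(which(lab == p), which(lab == q)))
    }
    out[[paste(partition$names[p], partition$names[q], sep = "-")]] <-
      list(row_net = p, col_net = q, idx = unname(idx))
  }
  out
}

#' Block-wise Spearman correlation between two TD matrices
#'
#' For each of the `m(m+1)/2` unique network blocks (diagonal blocks =
#' within-network voxel pairs, off-diagonal = cross-network pairs) the
#' Spearman rank correlation between the two states' lag values is computed
#' over the block's entries valid in both matrices. Significance of a
#' non-zero block correlation comes from permuting the entry correspondence
#' within the block; family-wise correction uses the max-|rho| statistic
#' across blocks. Blocks with fewer than 10 valid pairs are flagged and get
#' no p-value.
#'
#' @param td_a,td_b `td_matrix` objects on the same voxel ordering.
#' @param partition a [network_partition()].
#' @param n_perm permutations (default 1000).
#' @param alpha corrected level (default 0.05).
#' @param seed RNG seed.
#' @return data.frame, one row per unique block: `block`, `net_row`,
#'   `net_col`, `diagonal`, `n_pairs`, `spearman_rho`, `p_value`,
#'   `p_corrected`, `significant`, `flagged`.
#' @export
block_spearman_test <- function(td_a, td_b, partition, n_perm = 1000L,
                                alpha = 0.05, seed = 1L) {
  if (!all(dim(td_a$td) == dim(td_b$td)))
    stop("TD matrices differ in size")
  if (length(partition$labels) != nrow(td_a$td))
    stop("partition does not match TD dimension")
  set.seed(as.integer(seed))
  blocks <- block_entry_index(partition)
  nb <- length(blocks)
  rho <- rep(NA_real_, nb)
  vals <- vector("list", nb)
  for (b in seq_len(nb)) {
    idx <- blocks[[b]]$idx
    ok <- td_a$validity[idx] & td_b$validity[idx]
    x <- td_a$td[idx][ok]; y <- td_b$td[idx][ok]
    vals[[b]] <- list(x = x, y = y)
    if (length(x) >= 10L)
      rho[b] <- stats::cor(x, y, method = "spearman")
  }
  flagged <- vapply(vals, function(v) length(v$x) < 10L, logical(1))
  perm_rho <- matrix(NA_real_, nrow = n_perm, ncol = nb)
  for (r in seq_len(n_perm)) {
    for (b in which(!flagged)) {
      v <- vals[[b]]
      perm_rho[r, b] <- stats::cor(v$x, v$y[sample.int(length(v$y))],
                                   method = "spearman")
    }
  }
  p_unc <- p_cor <- rep(NA_real_, nb)
  max_rho <- if (any(!flagged))
    apply(abs(perm_rho[, !flagged, drop = FALSE]), 1L, max)
  else rep(NA_real_, n_perm)
  for (b in which(!flagged)) {
    p_unc[b] <- (1 + sum(abs(perm_rho[, b]) >= abs(rho[b]))) / (n_perm + 1)
    p_cor[b] <- (1 + sum(max_rho >= abs(rho[b]))) / (n_perm + 1)
  }
  data.frame(
    block = names(blocks),
    net_row = partition$names[vapply(blocks, `[[`, integer(1), "row_net")],
    net_col = partition$names[vapply(blocks, `[[`, integer(1), "col_net")],
    diagonal = vapply(blocks, function(b) b$row_net == b$col_net, logical(1)),
    n_pairs = vapply(vals, function(v) length(v$x), integer(1)),
    spearman_rho = rho,
    p_value = p_unc,
    p_corrected = p_cor,
    significant = !is.na(p_cor) & p_cor <= alpha,
    flagged = flagged,
    row.names = NULL)
}

# per-subject block means of off-diagonal (and optionally diagonal) blocks
subject_block_means <- function(td, blocks) {
  vapply(blocks, function(b) {
    idx <- b$idx
    ok <- td$validity[idx]
    if (!any(ok)) return(NA_real_)
    mean(td$td[idx][ok])
  }, numeric(1))
}

#' Block mean-lag state contrast
#'
#' Computes the mean lag of every off-diagonal (inter-network) block per
#' state (grand mean of per-subject block means) and tests the state
#' difference by subject-level state-label permutation with max-statistic
#' correction over the off-diagonal blocks. Diagonal-block means are
#' reported too: anti-symmetry forces them to equal zero exactly, which is
#' asserted.
#'
#' @param td_list list of per-subject `td_matrix` objects (one per
#'   subject-state; average epochs first, e.g. via [group_average()]).
#' @param subjects,states labels per element of `td_list`; 2 states, >= 3
#'   subjects each.
#' @param partition a [network_partition()].
#' @param n_perm,alpha,seed as in [block_spearman_test()].
#' @return list with `table` (data.frame over off-diagonal blocks:
#'   per-state means, difference, corrected p, significance) and
#'   `diagonal_means` (per state, all exactly 0 up to floating point).
#' @export
block_mean_test <- function(td_list, subjects, states, partition,
                            n_perm = 1000L, alpha = 0.05, seed = 1L) {
  states <- as.character(states)
  lv <- unique(states)
  if (length(lv) != 2L) stop("need exactly 2 states")
  if (min(table(states)) < 3L) stop("need >= 3 subjects per state")
  set.seed(as.integer(seed))
  blocks <- block_entry_index(partition)
  offdiag <- Filter(function(b) b$row_net != b$col_net, blocks)
  ondiag <- Filter(function(b) b$row_net == b$col_net, blocks)
  BM <- do.call(rbind, lapply(td_list, subject_block_means, blocks = offdiag))
  colnames(BM) <- names(offdiag)
  DM <- do.call(rbind, lapply(td_list, function(td) {
    vapply(ondiag, function(b) {
      # diagonal-block mean over ALL ordered within-network pairs: exactly 0
      vox <- which(partition$labels == b$row_net)
      sub <- td$td[vox, vox]
      ok <- td$validity[vox, vox]; diag(ok) <- FALSE
      if (!any(ok)) return(NA_real_)
      mean(c(sub[ok]))
    }, numeric(1))
  }))
  colnames(DM) <- names(ondiag)
  grp <- states == lv[1L]
  stat <- colMeans(BM[!grp, , drop = FALSE], na.rm = TRUE) -
          colMeans(BM[grp, , drop = FALSE], na.rm = TRUE)
  perm_labels <- permute_state_labels(subjects, states, n_perm)
  perm_stat <- matrix(NA_real_, n_perm, length(offdiag))
  for (r in seq_len(n_perm)) {
    g <- perm_labels[r, ] == lv[1L]
    perm_stat[r, ] <- colMeans(BM[!g, , drop = FALSE], na.rm = TRUE) -
                      colMeans(BM[g, , drop = FALSE], na.rm = TRUE)
  }
  max_stat <- apply(abs(perm_stat), 1L, max)
  p_cor <- vapply(seq_along(stat), function(b)
    (1 + sum(max_stat >= abs(stat[b]))) / (n_perm + 1), numeric(1))
  tab <- data.frame(
    block = names(offdiag),
    net_row = partition$names[vapply(offdiag, `[[`, integer(1), "row_net")],
    net_col = partition$names[vapply(offdiag, `[[`, integer(1), "col_net")],
    mean_a = colMeans(BM[grp, , drop = FALSE], na.rm = TRUE),
    mean_b = colMeans(BM[!grp, , drop = FALSE], na.rm = TRUE),
    difference = stat,
    p_corrected = p_cor,
    significant = p_cor <= alpha,
    row.names = NULL)
  names(tab)[names(tab) == "mean_a"] <- paste0("mean_", lv[1L])
  names(tab)[names(tab) == "mean_b"] <- paste0("mean_", lv[2L])
  diag_means <- list()
  for (st in lv)
    diag_means[[st]] <- colMeans(DM[states == st, , drop = FALSE], na.rm = TRUE)
  list(table = tab, diagonal_means = diag_means,
       subject_block_means = BM, state_order = lv)
}

#' Lag standard-deviation state contrast
#'
#' The spread of the lag structure — the standard deviation over each
#' subject's valid upper-triangle TD entries — is compared between states:
#' statistic = difference of state mean SDs, null by subject-level
#' state-label permutation (default 10,000 trials), two-sided.
#'
#' @inheritParams block_mean_test
#' @param n_perm permutations (default 10000).
#' @return list with `sd_by_subject`, per-state `sd_mean`, `statistic`
#'   (second state minus first), `p_value` (`NA` with a message when only
#'   one subject per state makes the permutation space degenerate).
#' @export
lag_sd_contrast <- function(td_list, subjects, states, n_perm = 10000L,
                            seed = 1L) {
  states <- as.character(states)
  lv <- unique(states)
  if (length(lv) != 2L) stop("need exactly 2 states")
  sds <- vapply(td_list, function(td) {
    up <- td$td[upper.tri(td$td)]
    ok <- td$validity[upper.tri(td$validity)]
    stats::sd(up[ok])
  }, numeric(1))
  grp <- states == lv[1L]
  sd_mean <- c(mean(sds[grp]), mean(sds[!grp]))
  names(sd_mean) <- lv
  stat <- sd_mean[2L] - sd_mean[1L]
  if (min(table(states)) < 2L) {
    return(list(sd_by_subject = sds, sd_mean = sd_mean, statistic = stat,
                p_value = NA_real_,
                note = "one subject per state: permutation space degenerate, p undefined"))
  }
  set.seed(as.integer(seed))
  perm_labels <- permute_state_labels(subjects, states, n_perm)
  perm_stat <- vapply(seq_len(n_perm), function(r) {
    g <- perm_labels[r, ] == lv[1L]
    mean(sds[!g]) - mean(sds[g])
  }, numeric(1))
  p <- (1 + sum(abs(perm_stat) >= abs(stat))) / (n_perm + 1)
  list(sd_by_subject = sds, sd_mean = sd_mean, statistic = unname(stat),
       p_value = p)
}

#' PCA of the state difference in functional connectivity
#'
#' Averages the subjects' Fisher-z FC matrices per state, eigendecomposes the
#' (symmetric) state-difference matrix, and flags components whose
#' eigenvalue magnitude exceeds the 95th percentile of the same-rank null
#' eigenvalue magnitude obtained by permuting state labels at the subject
#' level.
#'
#' @param fc_list list of per-subject `fc_matrix` objects (or plain symmetric
#'   z matrices).
#' @param subjects,states labels per element.
#' @param n_perm permutations (default 500).
#' @param alpha per-rank level (default 0.05).
#' @param n_ranks number of leading ranks to test (default 10).
#' @param seed RNG seed.
#' @return list with `eigenvalues` (by |value|, descending), `topographies`
#'   (matching eigenvectors), `null_q95` per rank, `significant` flags,
#'   `n_significant`, `difference` matrix (second state minus first).
#' @export
fc_difference_pca <- function(fc_list, subjects, states, n_perm = 500L,
                              alpha = 0.05, n_ranks = 10L, seed = 1L) {
  states <- as.character(states)
  lv <- unique(states)
  if (length(lv) != 2L) stop("need exactly 2 states")
  zs <- lapply(fc_list, function(f) {
    m <- if (inherits(f, "fc_matrix")) f$z else as.matrix(f)
    diag(m) <- 0
    m
  })
  n <- nrow(zs[[1L]])
  n_ranks <- min(as.integer(n_ranks), n)
  set.seed(as.integer(seed))
  diff_of <- function(g) {
    Reduce(`+`, zs[!g]) / sum(!g) - Reduce(`+`, zs[g]) / sum(g)
  }
  grp <- states == lv[1L]
  D <- diff_of(grp)
  eg <- eigen(D, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  ev <- eg$values[ord]; topo <- eg$vectors[, ord, drop = FALSE]
  perm_labels <- permute_state_labels(subjects, states, n_perm)
  null_abs <- matrix(NA_real_, n_perm, n_ranks)
  for (r in seq_len(n_perm)) {
    g <- perm_labels[r, ] == lv[1L]
    pe <- eigen(diff_of(g), symmetric = TRUE, only.values = TRUE)$values
    null_abs[r, ] <- sort(abs(pe), decreasing = TRUE)[seq_len(n_ranks)]
  }
  q95 <- apply(null_abs, 2L, stats::quantile, probs = 1 - alpha)
  sig <- abs(ev[seq_len(n_ranks)]) > q95
  list(eigenvalues = ev, topographies = topo,
       null_q95 = q95, significant = sig, n_significant = sum(sig),
       difference = D, state_order = lv)
}
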
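#' Lag projection of a TD matrix
#'
#' Projects the voxel-by-voxel TD matrix onto a one-dimensional map by taking
#' each voxel's mean lag against all other voxels (the mean over that voxel's
#' row, restricted to valid pairs). Under the sign convention `td[i, j] > 0`
#' when `i` is late, positive projection values mark voxels that are late on
#' average and negative values voxels that are early — the usual blue-early /
#' red-late reading. For a fully valid TD matrix anti-symmetry forces the
#' projection entries to sum to zero.
#'
#' @param td a [build_td_matrix()] result (or an object with `td` and
#'   `validity` members).
#' @return a `"lag_projection"`: list with `values` (seconds; `NA` where a
#'   voxel has no valid pair) and `coverage` (valid off-diagonal pairs per
#'   voxel).
#' @export
lag_projection <- function(td) {
  M <- td$td
  ok <- td$validity
  diag(ok) <- FALSE
  cov <- rowSums(ok)
  Mz <- M
  Mz[!ok] <- 0
  vals <- ifelse(cov > 0, rowSums(Mz) / cov, NA_real_)
  structure(list(values = vals, coverage = cov), class = "lag_projection")
}

#' Seed-based lag map
#'
#' Lags every voxel against the mean time series of a seed region: the
#' reference series is the across-voxel mean over the seed, and each voxel's
#' value is its [estimate_pair_lag()] against that reference (positive =
#' voxel later than the seed). Voxels inside a large seed can legitimately
#' show non-zero lags against the seed mean. Alternatively
#' (`method = "td_column"`), the map is the mean over the TD-matrix columns
#' of the seed voxels — a related but not identical reading.
#'
#' @param epoch a preprocessed [ts_epoch()].
#' @param seed_voxels non-empty integer index set.
#' @param method `"reference"` (lag against seed-mean series; default) or
#'   `"td_column"` (mean of seed columns of a freshly built TD matrix).
#' @inheritParams build_td_matrix
#' @return a `"seed_lag_map"`: list with `values` (seconds) and
#'   `seed_voxels`.
#' @export
seed_lag_map <- function(epoch, seed_voxels, method = c("reference", "td_column"),
                         max_lag_frames = 4L, normalize = TRUE,
                         min_overlap = 30L) {
  stopifnot_epoch(epoch)
  method <- match.arg(method)
  seed_voxels <- as.integer(seed_voxels)
  if (length(seed_voxels) == 0L) stop("`seed_voxels` must be non-empty")
  if (any(seed_voxels < 1L | seed_voxels > nrow(epoch$data)))
    stop("seed voxel index out of range")
  n <- nrow(epoch$data)
  if (method == "td_column") {
    td <- build_td_matrix(epoch, max_lag_frames, normalize, min_overlap)
    sub <- td$td[, seed_voxels, drop = FALSE]
    okm <- td$validity[, seed_voxels, drop = FALSE]
    sub[!okm] <- 0
    vals <- ifelse(rowSums(okm) > 0, rowSums(sub) / rowSums(okm), NA_real_)
    return(structure(list(values = vals, seed_voxels = seed_voxels),
                     class = "seed_lag_map"))
  }
  ref <- colMeans(epoch$data[seed_voxels, , drop = FALSE])
  if (stats::sd(ref[epoch$valid]) == 0)
    stop("seed reference series has zero variance over valid frames")
  vals <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    est <- tryCatch(
      estimate_pair_lag(epoch$data[v, ], ref, mask = epoch$valid,
                        tr = epoch$tr, max_lag_frames = max_lag_frames,
                        normalize = normalize, min_overlap = min_overlap),
      error = function(e) invalid_lag_estimate())
    if (est$valid) vals[v] <- est$tau
  }
  structure(list(values = vals, seed_voxels = seed_voxels),
            class = "seed_lag_map")
}

#' Two-stage group averaging of maps or TD matrices
#'
#' Group quantities are formed by first averaging each subject's epochs, then
#' averaging (unweighted) across subjects within each state — so a subject
#' with many epochs counts the same as a subject with one. Works on per-epoch
#' numeric vectors (lag projections, seed maps) or `td_matrix` objects;
#' averaging is validity-aware: each entry is averaged over the contributors
#' for which it is valid (non-`NA`).
#'
#' @param items list of per-epoch objects: numeric vectors, `lag_projection`
#'   / `seed_lag_map` objects, or `td_matrix` objects.
#' @param subjects,states character vectors labelling each item. Defaults are
#'   taken from `ts_epoch`-style attributes if absent.
#' @param weight_by_epochs if `TRUE`, subjects are weighted by their epoch
#'   count (pooled-epoch mean); default `FALSE` (unweighted subject mean).
#' @return named list (one entry per state). For vector inputs each entry is
#'   a list with `mean` and `n_valid`; for TD inputs a `td_matrix`-like list
#'   with averaged `td`, `amp`, a `validity` matrix (entries with >= 1
#'   contributor), and `n_contrib`.
#' @export
group_average <- function(items, subjects, states, weight_by_epochs = FALSE) {
  if (length(items) == 0L) stop("no items to average")
  if (length(subjects) != length(items) || length(states) != length(items))
    stop("`subjects` and `states` must label every item")
  as_mat <- function(x) {
    if (inherits(x, "td_matrix")) { m <- x$td; m[!x$validity] <- NA; m }
    else if (inherits(x, "lag_projection") || inherits(x, "seed_lag_map")) x$values
    else x
  }
  is_td <- inherits(items[[1L]], "td_matrix")
  mats <- lapply(items, as_mat)
  nanmean <- function(lst) {
    acc <- NULL; cnt <- NULL
    for (m in lst) {
      ok <- !is.na(m)
      m0 <- m; m0[!ok] <- 0
      if (is.null(acc)) { acc <- m0; cnt <- ok + 0 }
      else { acc <- acc + m0; cnt <- cnt + ok }
    }
    res <- acc / cnt
    res[cnt == 0] <- NA
    list(mean = res, n = cnt)
  }
  out <- list()
  for (st in unique(states)) {
    in_state <- which(states == st)
    if (length(in_state) == 0L) next
    subj_means <- list()
    for (sj in unique(subjects[in_state])) {
      idx <- in_state[subjects[in_state] == sj]
      sm <- nanmean(mats[idx])
      if (weight_by_epochs)
        subj_means <- c(subj_means, mats[idx])
      else
        subj_means <- c(subj_means, list(sm$mean))
    }
    g <- nanmean(subj_means)
    if (is_td) {
      tdm <- g$mean
      validity <- g$n > 0
      tdm[!validity] <- NA
      diag(tdm) <- 0; diag(validity) <- TRUE
      amps <- lapply(items[in_state], function(x) {
        a <- x$amp; a[!x$validity] <- NA; a })
      ga <- nanmean(amps)$mean
      out[[st]] <- structure(
        list(td = tdm, amp = ga, validity = validity, n = nrow(tdm),
             tr = items[[in_state[1L]]]$tr,
             max_lag_frames = items[[in_state[1L]]]$max_lag_frames,
             n_contrib = g$n),
        class = "td_matrix")
    } else {
      out[[st]] <- list(mean = g$mean, n_valid = g$n)
    }
  }
  missing_states <- setdiff(unique(states), names(out))
  if (length(missing_states) > 0L)
    warning("states with no contributing subjects: ",
            paste(missing_states, collapse = ", "))
  out
}
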
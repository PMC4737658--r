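#' Construct a voxel-by-frame time-series epoch
#'
#' The unit of per-epoch computation: an `n_voxels x n_frames` real matrix of
#' BOLD-like signal, the repetition time (TR, seconds per frame), and a
#' boolean valid-frame mask. Identifiers tag the epoch with its subject,
#' state (e.g. `"wake"` vs `"sws"`) and epoch index so that group-level
#' averaging and permutation tests can treat subject-state as the
#' exchangeable unit.
#'
#' @param data numeric matrix, voxels in rows, frames in columns.
#' @param tr repetition time in seconds (> 0).
#' @param valid logical vector of length `ncol(data)`; `TRUE` marks frames
#'   usable for covariance computation. Defaults to all valid.
#' @param subject_id,state_label,epoch_id identifiers (scalar character /
#'   integer); free-form.
#' @return an object of class `"ts_epoch"`.
#' @export
ts_epoch <- function(data, tr, valid = NULL, subject_id = "s1",
                     state_label = "A", epoch_id = 1L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive number (seconds)")
  if (is.null(valid)) valid <- rep(TRUE, ncol(data))
  valid <- as.logical(valid)
  if (length(valid) != ncol(data))
    stop("`valid` must have one entry per frame (got ", length(valid),
         " for ", ncol(data), " frames)")
  if (anyNA(data[, valid, drop = FALSE]))
    stop("epoch data contain NA in valid frames")
  structure(
    list(data = data, tr = tr, valid = valid,
         subject_id = as.character(subject_id),
         state_label = as.character(state_label),
         epoch_id = as.integer(epoch_id)),
    class = "ts_epoch")
}

#' @export
print.ts_epoch <- function(x, ...) {
  cat(sprintf(
    "<ts_epoch> %d voxels x %d frames, TR = %g s, %d/%d frames valid\n",
    nrow(x$data), ncol(x$data), x$tr, sum(x$valid), length(x$valid)))
  cat(sprintf("  subject=%s state=%s epoch=%d\n",
              x$subject_id, x$state_label, x$epoch_id))
  invisible(x)
}

#' @export
dim.ts_epoch <- function(x) dim(x$data)

n_valid_frames <- function(epoch) sum(epoch$valid)

stopifnot_epoch <- function(epoch) {
  if (!inherits(epoch, "ts_epoch")) stop("expected a `ts_epoch` object")
  invisible(epoch)
}
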
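#' Read a 4D NIfTI series (and optional label volume) as an epoch
#'
#' Voxels are flattened x-fastest with 0-based coordinates recorded, and the
#' repetition time is taken from the header's time pixdim unless overridden.
#'
#' @param path 4D NIfTI file.
#' @param label_path optional integer label volume aligned with `path`;
#'   converted into a [network_partition()].
#' @param tr override for the repetition time (seconds); required when the
#'   header carries none.
#' @param subject_id,state_label,epoch_id identifiers for the epoch.
#' @return list with `epoch` (a [ts_epoch()]), `lattice` (a
#'   [voxel_lattice()]), and `partition` (or `NULL`).
#' @export
read_nifti_series <- function(path, label_path = NULL, tr = NULL,
                              subject_id = "s1", state_label = "A",
                              epoch_id = 1L) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D volume, got ", length(d), "D")
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4L) pd[4L] else 0
    if (!is.finite(tr) || tr <= 0)
      stop("header carries no repetition time; pass `tr` explicitly")
  }
  data <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4L])
  lattice <- voxel_lattice(d[1:3])
  partition <- NULL
  if (!is.null(label_path)) {
    lab <- RNifti::readNifti(label_path)
    if (!all(dim(lab)[1:3] == d[1:3]))
      stop("label volume shape does not match the series")
    labv <- as.integer(round(as.numeric(lab)))
    ulab <- sort(unique(labv))
    partition <- structure(
      list(labels = match(labv, ulab), names = as.character(ulab)),
      class = "network_partition")
  }
  list(epoch = ts_epoch(data, tr = tr, subject_id = subject_id,
                        state_label = state_label, epoch_id = epoch_id),
       lattice = lattice, partition = partition)
}

#' Write an epoch (and optional labels) as NIfTI
#'
#' @param epoch a [ts_epoch()] whose voxels enumerate `lattice` x-fastest.
#' @param lattice the [voxel_lattice()] giving the 3D shape.
#' @param path output 4D NIfTI path.
#' @param partition optional [network_partition()]; written as an integer
#'   label volume to `label_path`.
#' @param label_path output path for the label volume.
#' @return `path`, invisibly.
#' @export
write_nifti_series <- function(epoch, lattice, path, partition = NULL,
                               label_path = NULL) {
  stopifnot_epoch(epoch)
  if (nrow(epoch$data) != lattice$n) stop("epoch does not match lattice")
  arr <- array(epoch$data, dim = c(lattice$dims, ncol(epoch$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, epoch$tr)
  RNifti::writeNifti(img, path)
  if (!is.null(partition)) {
    if (is.null(label_path)) stop("`label_path` needed to write the partition")
    lab <- array(as.numeric(partition$labels), dim = lattice$dims)
    RNifti::writeNifti(RNifti::asNifti(lab), label_path)
  }
  invisible(path)
}

#' Write / read a study container
#'
#' A single-file store for epochs, TD matrices, maps, decompositions and
#' stats tables, carrying a provenance record (creation time, package
#' version, seed and parameters used). Round-trip is lossless for all
#' numeric content.
#'
#' @param objects named list of payload objects.
#' @param path file path (`.rds`).
#' @param seed,params optional provenance fields.
#' @return `path` invisibly (write); the container list (read), with
#'   `$payload` and `$provenance`.
#' @export
write_study_container <- function(objects, path, seed = NULL, params = NULL) {
  container <- list(
    payload = objects,
    provenance = list(
      created = format(Sys.time(), tz = "UTC"),
      package_version = as.character(utils::packageVersion("boldlag")),
      seed = seed, params = params))
  saveRDS(container, path)
  invisible(path)
}

#' @rdname write_study_container
#' @export
read_study_container <- function(path) readRDS(path)

#' Run the full synthetic-study pipeline
#'
#' simulate -> preprocess -> TD matrices -> lag projections / group averages
#' -> lag threads -> state statistics, from a single config list.
#' Deterministic under `config$seed`: identical config and seed give
#' identical tables.
#'
#' @param config list with elements `design` (a [study_design()]), and
#'   optionally `cutoff_hz`, `censor_threshold_pct`, `min_run`,
#'   `include_global`, `max_lag_frames`, `min_overlap`, `normalize`,
#'   `k_max`, `n_perm`, `alpha`, `seed`. Unknown elements are an error (the
#'   config is validated before anything runs).
#' @return named list ("container") with epochs, per-subject TD matrices,
#'   group TD and lag projections per state, thread decompositions per
#'   state, and the stats tables; `censored_fraction` per epoch logged in
#'   `$log`. Epochs in which censoring leaves no usable frames are dropped
#'   with a log entry; if nothing survives the result carries
#'   `empty = TRUE`.
#' @export
run_study_pipeline <- function(config) {
  known <- c("design", "cutoff_hz", "censor_threshold_pct", "min_run",
             "include_global", "max_lag_frames", "min_overlap", "normalize",
             "k_max", "n_perm", "alpha", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop("unknown config element(s): ", paste(unknown, collapse = ", "))
  if (!inherits(config$design, "study_design"))
    stop("config$design must be a study_design")
  cfg <- utils::modifyList(
    list(cutoff_hz = 0.1, censor_threshold_pct = 0.5, min_run = 10L,
         include_global = FALSE, max_lag_frames = 4L, min_overlap = 30L,
         normalize = TRUE, k_max = 10L, n_perm = 1000L, alpha = 0.05,
         seed = 1L),
    config[setdiff(names(config), "design")])
  design <- config$design
  epochs <- generate_study(design)
  log <- list()
  pre <- list()
  for (e in epochs) {
    pe <- preprocess_epoch(e, cutoff_hz = cfg$cutoff_hz,
                           include_global = cfg$include_global,
                           censor_threshold_pct = cfg$censor_threshold_pct,
                           min_run = cfg$min_run)
    log[[length(log) + 1L]] <- list(
      subject = e$subject_id, state = e$state_label, epoch = e$epoch_id,
      censored_fraction = attr(pe, "censored_fraction"),
      empty = isTRUE(attr(pe, "empty")))
    if (!isTRUE(attr(pe, "empty"))) pre[[length(pre) + 1L]] <- pe
  }
  if (length(pre) == 0L)
    return(list(empty = TRUE, log = log,
                note = "no epoch survived censoring"))
  subjects <- vapply(pre, function(e) e$subject_id, character(1))
  states <- vapply(pre, function(e) e$state_label, character(1))
  tds <- lapply(pre, build_td_matrix, max_lag_frames = cfg$max_lag_frames,
                normalize = cfg$normalize, min_overlap = cfg$min_overlap)
  td_subject <- group_average(tds, subjects = subjects, states = subjects)
  subj_states <- states[match(names(td_subject), subjects)]
  td_state <- group_average(tds, subjects = subjects, states = states)
  projections <- lapply(td_subject, lag_projection)
  proj_state <- lapply(td_state, lag_projection)
  threads <- lapply(td_state, lag_threads, k_max = cfg$k_max)
  stats_out <- list()
  if (length(unique(states)) == 2L && min(table(subj_states)) >= 3L) {
    maps <- do.call(rbind, lapply(projections, function(p) p$values))
    stats_out$lag_sd <- lag_sd_contrast(
      td_subject, subjects = names(td_subject), states = subj_states,
      n_perm = cfg$n_perm, seed = cfg$seed)
    if (!is.null(design$partition)) {
      stats_out$block_mean <- block_mean_test(
        td_subject, subjects = names(td_subject), states = subj_states,
        partition = design$partition, n_perm = cfg$n_perm,
        alpha = cfg$alpha, seed = cfg$seed)
      sts <- unique(states)
      stats_out$block_spearman <- block_spearman_test(
        td_state[[sts[1L]]], td_state[[sts[2L]]],
        partition = design$partition, n_perm = cfg$n_perm,
        alpha = cfg$alpha, seed = cfg$seed)
    }
    fcs <- lapply(pre, zero_lag_fc)
    fc_subject <- group_average(lapply(fcs, function(f) f$z),
                                subjects = subjects, states = subjects)
    stats_out$fc_pca <- fc_difference_pca(
      lapply(fc_subject, function(g) g$mean),
      subjects = names(fc_subject), states = subj_states,
      n_perm = min(cfg$n_perm, 500L), alpha = cfg$alpha, seed = cfg$seed)
  }
  list(epochs = pre, subjects = subjects, states = states,
       td_by_subject = td_subject, subject_states = subj_states,
       td_by_state = td_state, projection_by_subject = projections,
       projection_by_state = proj_state, threads_by_state = threads,
       stats = stats_out, log = log, config = cfg, empty = FALSE)
}
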
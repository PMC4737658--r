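#' Two-state example study with planted lag reorganization
#'
#' Builds the package's reference synthetic study: a wake-like state and an
#' SWS-like state on a small voxel lattice, with three planted differences
#' that mirror the canonical state-dependent reorganization motifs of
#' infra-slow lag structure:
#'
#' * a "subcortex-analog" network (the first network) that is early
#'   relative to the rest in the wake-like state and late in the SWS-like
#'   state (seed-map reversal);
#' * an "all-early" visual-analog network (VIS) whose delays are uniformly
#'   shifted earlier in the SWS-like state (block-mean earliness);
#' * a doubled spread of delays in the SWS-like state (lag-SD increase).
#'
#' Defaults: 8 subjects per state with 3 five-minute epochs each (150 frames
#' at TR 2.08 s), one latent 1/f source band-limited to 0.1 Hz, per-voxel
#' delays drawn with SD 0.4 s, additive noise SD 0.15 (signal units; the
#' sources have unit SD).
#'
#' @param n_subjects_per_state,epochs_per_subject study size.
#' @param dims lattice dimensions (default 4 x 7 x 2 = 56 voxels, giving 8
#'   voxels per network).
#' @param delay_sd SD of the base per-voxel delays (seconds).
#' @param reversal_shift early/late shift of the subcortex-analog network
#'   (seconds; applied as -shift in wake, +shift in SWS).
#' @param early_shift uniform earliness of the VIS-analog network in the
#'   SWS-like state (seconds).
#' @param spread_factor multiplier on delay spread in the SWS-like state.
#' @param noise_sd additive voxel noise SD.
#' @param tr,n_frames sampling parameters.
#' @param seed master seed.
#' @return list with `design` (a [study_design()]), `lattice`, `partition`,
#'   `adjacency`, ground-truth delay vectors `delays_wake` / `delays_sws`,
#'   and index sets `subcortex_voxels`, `early_network_voxels`.
#' @export
example_study_design <- function(n_subjects_per_state = 8L,
                                 epochs_per_subject = 3L,
                                 dims = c(4L, 7L, 2L),
                                 delay_sd = 0.4, reversal_shift = 0.4,
                                 early_shift = 0.6, spread_factor = 2,
                                 noise_sd = 0.15, tr = 2.08,
                                 n_frames = 150L, seed = 11L) {
  lattice <- voxel_lattice(dims)
  partition <- network_partition(lattice)
  n <- lattice$n
  set.seed(as.integer(seed))
  base <- stats::rnorm(n, sd = delay_sd)
  subc <- which(partition$labels == 1L)
  vis <- which(partition$labels == match("VIS", partition$names))
  # centre the subcortex-analog base delays on the rest of the brain so the
  # planted reversal shift, not a random network-mean offset, sets its
  # early/late position in each state
  base[subc] <- base[subc] - mean(base[subc]) + mean(base[-subc])
  d_wake <- base
  d_wake[subc] <- base[subc] - reversal_shift
  d_sws <- spread_factor * base
  d_sws[subc] <- spread_factor * base[subc] + reversal_shift
  d_sws[vis] <- d_sws[vis] - early_shift
  w <- matrix(1, n, 1L)
  plans <- list(
    wake = lag_plan(w, matrix(d_wake, n, 1L), noise_sd = noise_sd,
                    tr = tr, n_frames = n_frames),
    sws = lag_plan(w, matrix(d_sws, n, 1L), noise_sd = noise_sd,
                   tr = tr, n_frames = n_frames))
  design <- study_design(n_subjects_per_state = n_subjects_per_state,
                         epochs_per_subject = epochs_per_subject,
                         state_plans = plans, partition = partition,
                         rng_seed = as.integer(seed))
  list(design = design, lattice = lattice, partition = partition,
       adjacency = lattice_adjacency(lattice),
       delays_wake = d_wake, delays_sws = d_sws,
       subcortex_voxels = subc, early_network_voxels = vis)
}
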
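#' Pipeline configuration with documented defaults
#'
#' Returns the full nested configuration used by the feature extractor, the
#' classifier, the rule engine and the simulator. Every threshold the
#' framework uses is exposed here; pass overrides as named arguments at any
#' nesting level (partial lists are merged over the defaults).
#'
#' Signal thresholds:
#' * `resp_band_hz` band-pass for the respiration channel, default 0.2-2.0 Hz
#'   (12-120 cycles/min, the infant breathing range).
#' * `regularity_threshold_cpm` the regularity criterion: respiration is
#'   regular when the minute-extrapolated rates of the longest and shortest
#'   breath cycles in an epoch differ by less than 20 cycles/min; a range of
#'   exactly 20 is called irregular.
#' * `min_cycles` minimum breath cycles per epoch for a regularity verdict
#'   (default 5); fewer yields UNDETERMINED and the movement fallback decides.
#' * `burst_k` movement-burst threshold in robust spreads above the baseline
#'   median of the smoothed envelope (default 4).
#' * `twitch_max_duration_s` / `twitch_amp_frac` split bursts into twitches
#'   (brief, small: duration <= 0.5 s and amplitude <= 25% of the 95th
#'   percentile gross amplitude) versus gross movements.
#'
#' Classifier thresholds mirror the qualitative wake/sleep movement contrasts:
#' twitches and sparse movement favour sleep, frequent (`wake_burst_count`,
#' default 4 per epoch at intervals under `wake_interval_s`) or sustained
#' (`sustained_s`, default 5 s) movement favours wake; heavy movement noise in
#' the respiration signal (`active_noise_fraction` of the epoch, default 0.3)
#' marks the active states.
#'
#' @param ... named overrides, e.g. `bsa_config(rules = list(min_run_epochs = 4))`.
#' @return A nested list of class `bsa_config`.
#' @export
bsa_config <- function(...) {
  cfg <- list(
    epoch_length_s = 30,
    signals = list(
      resp_band_hz = c(0.2, 2.0),
      min_cycle_s = 0.35,
      amp_gate_frac = 0.25,
      min_cycles = 5,
      regularity_threshold_cpm = 20,
      envelope_smooth_s = 0.25,
      burst_k = 4,
      merge_gap_s = 1.0,
      min_burst_s = 0.1,
      twitch_max_duration_s = 0.5,
      twitch_amp_frac = 0.25
    ),
    classify = list(
      eyes_open_min_fraction = 0.5,
      cry_min_fraction = 0.2,
      sleep_interval_s = 30,
      wake_burst_count = 4,
      wake_interval_s = 10,
      sustained_s = 5,
      active_noise_fraction = 0.3
    ),
    rules = list(
      min_run_epochs = 6,
      repair = FALSE
    ),
    sim = sim_config(),
    seed = 1L
  )
  overrides <- list(...)
  .merge_cfg(cfg, overrides)
}

.merge_cfg <- function(base, over) {
  for (nm in names(over)) {
    v <- over[[nm]]
    if (is.list(v) && is.list(base[[nm]]) && !is.null(names(v))) {
      base[[nm]] <- .merge_cfg(base[[nm]], v)
    } else if (is.list(v) && is.atomic(base[[nm]]) &&
               length(base[[nm]]) > 1L) {
      # a named parameter vector deserialized as a list (e.g. from YAML)
      base[[nm]] <- unlist(v)
    } else {
      base[[nm]] <- v
    }
  }
  base
}

# YAML drops the names of atomic vectors; serialize them as maps instead
.cfg_serializable <- function(x) {
  if (is.list(x)) {
    lapply(x, .cfg_serializable)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML; unknown keys are
#' rejected by being merged over the documented defaults only.
#'
#' @param path file path.
#' @param cfg a configuration list from [bsa_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(bsa_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(.cfg_serializable(cfg), path)
  invisible(path)
}
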
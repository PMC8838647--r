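#' Read / write a hypnogram CSV
#'
#' Format: header `epoch,start_s,state`, one row per epoch, epochs
#' contiguous from 0, state tokens exactly those of the declared label
#' space.
#'
#' @param path file path.
#' @param label_space `"behavioral"`, `"psg"` or `"three-class"`.
#' @export
read_hypnogram <- function(path, label_space = c("behavioral", "psg",
                                                 "three-class")) {
  label_space <- match.arg(label_space)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch", "start_s", "state")
  if (!all(need %in% names(d))) {
    stop("hypnogram file must have header epoch,start_s,state")
  }
  d <- d[order(d$epoch), ]
  if (!identical(as.integer(d$epoch), seq_len(nrow(d)) - 1L)) {
    stop("epoch indices must be contiguous from 0")
  }
  labs <- .space_labels(label_space)
  bad <- which(!d$state %in% labs)
  if (length(bad) > 0L) {
    stop("unknown state token '", d$state[bad[1]], "' at row ", bad[1])
  }
  el <- if (nrow(d) > 1L) d$start_s[2] - d$start_s[1] else 30
  hypnogram(d$state, epoch_length_s = el, start_time_s = d$start_s[1],
            label_space = label_space)
}

#' @rdname read_hypnogram
#' @param h a `hypnogram`.
#' @export
write_hypnogram <- function(h, path) {
  .assert_hypnogram(h)
  n <- n_epochs(h)
  d <- data.frame(
    epoch = seq_len(n) - 1L,
    start_s = h$start_time_s + (seq_len(n) - 1L) * h$epoch_length_s,
    state = h$labels
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a multichannel recording CSV
#'
#' Format: header `t_s,resp,move,audio_env,eyes,cry`, rows at the waveform
#' sample rate with the 1-Hz eyes/cry channels forward-filled; `eyes` is
#' 0/1/NA, `cry` 0/1. Waveform columns must be dense.
#'
#' @param path file path.
#' @export
read_channels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "resp", "move", "audio_env", "eyes", "cry")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("channel file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(diff(d$t_s) <= 0)) stop("time column must be strictly increasing")
  if (anyNA(d$resp) || anyNA(d$move)) {
    stop("waveform columns must be dense (no NA)")
  }
  fs <- 1 / stats::median(diff(d$t_s))
  fs <- round(fs, 6)
  nsec <- floor(nrow(d) / fs)
  # downsample the forward-filled 1 Hz channels back to one value per second
  sec_idx <- floor(d$t_s) + 1L
  eyes <- vapply(seq_len(nsec), function(k) {
    v <- d$eyes[sec_idx == k]
    if (all(is.na(v))) NA_integer_ else as.integer(stats::median(v, na.rm = TRUE))
  }, integer(1))
  cry <- vapply(seq_len(nsec), function(k) {
    as.integer(round(stats::median(d$cry[sec_idx == k])))
  }, integer(1))
  channel_set(d$resp, d$move, d$audio_env, eyes, cry, fs)
}

#' @rdname read_channels
#' @param channels a [channel_set()].
#' @export
write_channels <- function(channels, path) {
  if (!inherits(channels, "channel_set")) stop("expected a channel_set")
  n <- length(channels$resp)
  t_s <- (seq_len(n) - 1L) / channels$fs
  sec <- pmin(floor(t_s) + 1L, length(channels$eyes))
  d <- data.frame(
    t_s = t_s,
    resp = channels$resp,
    move = channels$move,
    audio_env = channels$audio_env,
    eyes = channels$eyes[sec],
    cry = channels$cry[sec]
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full annotation pipeline
#'
#' Simulate (or load) a recording, extract features, classify, smooth,
#' validate, and compare against the ground truth when available. Artifacts
#' are written under `out_dir` when given: channels, raw and smoothed
#' hypnograms, the audit table, and a `report.json` aggregating the
#' agreement statistics.
#'
#' @param config a [bsa_config()] list.
#' @param channels optional [channel_set()]; when `NULL` a nap is simulated
#'   from `config$sim`.
#' @param truth optional behavioral `hypnogram` ground truth (supplied
#'   automatically when simulating).
#' @param out_dir optional output directory.
#' @return A list with `hypnogram` (smoothed), `raw_hypnogram`, `audit`,
#'   `violations`, and (when truth is known) `agreement` with three-class
#'   kappa against the merged truth.
#' @export
run_pipeline <- function(config = bsa_config(), channels = NULL,
                         truth = NULL, out_dir = NULL) {
  sim <- NULL
  if (is.null(channels)) {
    sim <- simulate_nap(config$sim)
    channels <- sim$channels
    truth <- sim$truth
  }
  cls <- classify_recording(channels, config)
  sm <- smooth_hypnogram(cls$hypnogram, config)
  h <- sm$hypnogram
  viol <- validate_hypnogram(h)
  if (nrow(viol) > 0L && isTRUE(config$rules$repair)) {
    h <- repair_hypnogram(h)
    viol <- validate_hypnogram(h)
  }
  agreement <- NULL
  if (!is.null(truth)) {
    m <- confusion(merge_bsa_to_three(h), merge_bsa_to_three(truth))
    agreement <- list(
      kappa_three_class = cohens_kappa(m),
      observed_agreement = sum(diag(m)) / attr(m, "n"),
      confusion = m
    )
  }
  out <- list(hypnogram = h, raw_hypnogram = cls$hypnogram,
              audit = cls$audit, smoothing_log = sm$log,
              violations = viol, agreement = agreement)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_channels(channels, file.path(out_dir, "channels.csv"))
    write_hypnogram(cls$hypnogram, file.path(out_dir, "hypnogram_raw.csv"))
    write_hypnogram(h, file.path(out_dir, "hypnogram.csv"))
    if (!is.null(truth)) {
      write_hypnogram(truth, file.path(out_dir, "truth.csv"))
    }
    utils::write.csv(cls$audit, file.path(out_dir, "audit.csv"),
                     row.names = FALSE, quote = FALSE)
    rep <- list(
      n_epochs = n_epochs(h),
      n_violations = nrow(viol),
      kappa_three_class = if (!is.null(agreement)) {
        agreement$kappa_three_class
      } else {
        NULL
      }
    )
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
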
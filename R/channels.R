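#' Synchronized multichannel nap recording
#'
#' Bundles the unobtrusive channels the framework scores from: the
#' respiration and body-movement waveforms from an under-mattress pressure
#' sensor, an audio envelope, and the per-second eyes-open and crying
#' indicators that stand in for the human video observations.
#'
#' @param resp respiration waveform (arbitrary units).
#' @param move body-movement waveform (arbitrary units).
#' @param audio_env nonnegative audio envelope.
#' @param eyes per-second eyes-open indicator: 1 open, 0 closed, NA unknown.
#' @param cry per-second crying indicator: 1 crying, 0 not.
#' @param fs sample rate in Hz of the three waveform channels.
#' @return An object of class `channel_set`.
#' @export
channel_set <- function(resp, move, audio_env, eyes, cry, fs) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  n <- length(resp)
  if (length(move) != n || length(audio_env) != n) {
    stop("resp, move and audio_env must have equal length")
  }
  if (anyNA(resp) || anyNA(move)) {
    stop("waveform channels must be dense (no NA)")
  }
  duration_s <- n / fs
  nsec <- length(eyes)
  if (length(cry) != nsec) stop("eyes and cry must have equal length (1 Hz)")
  if (abs(nsec - duration_s) > 1) {
    stop("eyes/cry channels (1 Hz) do not cover the waveform duration")
  }
  if (any(!cry %in% c(0, 1))) stop("cry must be 0/1")
  if (any(!is.na(eyes) & !eyes %in% c(0, 1))) stop("eyes must be 0/1/NA")
  structure(
    list(resp = as.numeric(resp), move = as.numeric(move),
         audio_env = as.numeric(audio_env), eyes = eyes, cry = cry,
         fs = fs, duration_s = duration_s),
    class = "channel_set"
  )
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set: %.1f s at %g Hz (%d epochs of 30 s)>\n",
              x$duration_s, x$fs, floor(x$duration_s / 30)))
  invisible(x)
}
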
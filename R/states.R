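#' State taxonomies
#'
#' Three label spaces are used throughout: the five Prechtl behavioral states
#' (QS quiet sleep, AS active sleep, QA quiet awake, AA active awake,
#' V vocalization/crying), the five polysomnography stages
#' (WAKE, REM, N1, N2, N3), and the three-class space every merging scheme
#' targets (WAKE3, ACTIVE3, QUIET3).
#'
#' @format Character vectors of state tokens.
#' @name state_spaces
NULL

#' @rdname state_spaces
#' @export
BEHAVIORAL_STATES <- c("QS", "AS", "QA", "AA", "V")

#' @rdname state_spaces
#' @export
PSG_STATES <- c("WAKE", "REM", "N1", "N2", "N3")

#' @rdname state_spaces
#' @export
THREE_CLASS_STATES <- c("WAKE3", "ACTIVE3", "QUIET3")

.space_labels <- function(label_space) {
  switch(label_space,
    behavioral = BEHAVIORAL_STATES,
    psg = PSG_STATES,
    `three-class` = THREE_CLASS_STATES,
    stop("unknown label_space: ", label_space)
  )
}

#' Construct an epoch-labelled hypnogram
#'
#' A hypnogram is the time-ordered sequence of per-epoch state labels for a
#' recording. Epoch `i` (0-based) covers the half-open interval
#' `[start_time_s + i * epoch_length_s, start_time_s + (i + 1) * epoch_length_s)`.
#'
#' @param labels character vector of state labels, one per epoch.
#' @param epoch_length_s epoch duration in seconds (default 30).
#' @param start_time_s recording start time in seconds (default 0).
#' @param label_space one of `"behavioral"`, `"psg"`, `"three-class"`.
#' @return An object of class `hypnogram`.
#' @examples
#' h <- hypnogram(c("AS", "AS", "QS"))
#' n_epochs(h)
#' @export
hypnogram <- function(labels, epoch_length_s = 30, start_time_s = 0,
                      label_space = c("behavioral", "psg", "three-class")) {
  label_space <- match.arg(label_space)
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(labels), .space_labels(label_space))
  if (length(bad) > 0L) {
    stop("labels not in label space '", label_space, "': ",
         paste(bad, collapse = ", "))
  }
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) {
    stop("epoch_length_s must be positive")
  }
  structure(
    list(labels = labels, epoch_length_s = epoch_length_s,
         start_time_s = start_time_s, label_space = label_space),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d epochs x %gs, space '%s'>\n",
              length(x$labels), x$epoch_length_s, x$label_space))
  r <- runs_of(x)
  cat(paste0(r$state, "x", r$length_epochs, collapse = " "), "\n")
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param h a `hypnogram`.
#' @export
n_epochs <- function(h) length(h$labels)

.assert_hypnogram <- function(h, space = NULL) {
  if (!inherits(h, "hypnogram")) stop("expected a hypnogram object")
  if (!is.null(space) && h$label_space != space) {
    stop("expected a hypnogram in label space '", space,
         "', got '", h$label_space, "'")
  }
  invisible(h)
}

#' Maximal runs of a hypnogram
#'
#' Decomposes the label sequence into maximal constant runs; adjacent runs
#' always have different states and the run lengths sum to the epoch count.
#'
#' @param h a `hypnogram`.
#' @return A data.frame with columns `state`, `start_epoch` (0-based),
#'   `length_epochs`.
#' @export
runs_of <- function(h) {
  .assert_hypnogram(h)
  r <- rle(h$labels)
  ends <- cumsum(r$lengths)
  data.frame(
    state = r$values,
    start_epoch = ends - r$lengths,
    length_epochs = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Merge behavioral states into the three-class space
#'
#' Epochs annotated QA, AA or V are pooled into a single wake class; AS maps
#' to ACTIVE3 and QS to QUIET3.
#'
#' @param h a behavioral `hypnogram`.
#' @return A three-class `hypnogram` with the same epoch grid.
#' @export
merge_bsa_to_three <- function(h) {
  .assert_hypnogram(h, "behavioral")
  map <- c(QA = "WAKE3", AA = "WAKE3", V = "WAKE3",
           AS = "ACTIVE3", QS = "QUIET3")
  hypnogram(unname(map[h$labels]), h$epoch_length_s, h$start_time_s,
            "three-class")
}

#' Merge polysomnography stages into the three-class space
#'
#' Two schemes are supported. Scheme `"A_remplus"` pools REM with the light
#' NREM stages N1 and N2 into a REM+ category opposed to N3 alone (NREM-);
#' scheme `"B_standard"` keeps REM separate and pools N1, N2 and N3 into the
#' conventional NREM category.
#'
#' @param h a psg `hypnogram`.
#' @param scheme `"A_remplus"` or `"B_standard"`.
#' @return A three-class `hypnogram`.
#' @export
merge_psg <- function(h, scheme = c("A_remplus", "B_standard")) {
  .assert_hypnogram(h, "psg")
  scheme <- match.arg(scheme)
  map <- if (scheme == "A_remplus") {
    c(WAKE = "WAKE3", REM = "ACTIVE3", N1 = "ACTIVE3", N2 = "ACTIVE3",
      N3 = "QUIET3")
  } else {
    c(WAKE = "WAKE3", REM = "ACTIVE3", N1 = "QUIET3", N2 = "QUIET3",
      N3 = "QUIET3")
  }
  hypnogram(unname(map[h$labels]), h$epoch_length_s, h$start_time_s,
            "three-class")
}
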
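#' Confusion matrix between two hypnograms
#'
#' Cross-tabulates per-epoch labels of two hypnograms over the same epoch
#' grid and label space. Cell `[i, j]` counts epochs labelled `i` by `h1`
#' and `j` by `h2`.
#'
#' @param h1,h2 hypnograms with equal epoch counts, epoch lengths and
#'   label space.
#' @return An object of class `confusion`: the count matrix with attributes
#'   `n` and `labels`.
#' @export
confusion <- function(h1, h2) {
  .assert_hypnogram(h1); .assert_hypnogram(h2)
  if (h1$label_space != h2$label_space) {
    stop("hypnograms are in different label spaces")
  }
  if (n_epochs(h1) != n_epochs(h2)) {
    stop("hypnograms have different epoch counts (",
         n_epochs(h1), " vs ", n_epochs(h2), ")")
  }
  if (h1$epoch_length_s != h2$epoch_length_s) {
    stop("hypnograms have different epoch lengths")
  }
  labs <- .space_labels(h1$label_space)
  m <- table(factor(h1$labels, levels = labs),
             factor(h2$labels, levels = labs))
  m <- unclass(matrix(as.integer(m), nrow = length(labs),
                      dimnames = list(labs, labs)))
  structure(m, n = sum(m), class = c("confusion", class(m)))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/n` and chance agreement
#' `p_e = sum_k (row_k/n)(col_k/n)`. When both raters are constant and
#' identical (`p_e = 1` with perfect agreement) kappa is 1 by convention.
#'
#' @param m a square count matrix (e.g. from [confusion()]).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(m) {
  m <- as.matrix(unclass(m))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix: no epochs")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    return(if (p_o >= 1 - .Machine$double.eps) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-state kappa (one-vs-rest)
#'
#' Binarizes both hypnograms to `state` versus everything else and returns
#' Cohen's kappa of the resulting 2x2 table — the standard construction for
#' reporting a separate agreement per state.
#'
#' @param h1,h2 hypnograms over a common space.
#' @param state a label of that space, present in at least one hypnogram.
#' @export
per_state_kappa <- function(h1, h2, state) {
  .assert_hypnogram(h1); .assert_hypnogram(h2)
  if (!state %in% .space_labels(h1$label_space)) {
    stop("state '", state, "' is not in label space '", h1$label_space, "'")
  }
  if (n_epochs(h1) != n_epochs(h2)) stop("hypnograms have different lengths")
  a <- h1$labels == state
  b <- h2$labels == state
  if (!any(a) && !any(b)) {
    stop("state '", state,
         "' absent from both hypnograms: agreement undefined")
  }
  m <- table(factor(a, levels = c(TRUE, FALSE)),
             factor(b, levels = c(TRUE, FALSE)))
  cohens_kappa(matrix(as.integer(m), 2, 2))
}

#' Per-subject kappas
#'
#' Computes Cohen's kappa for each subject's pair of hypnograms and
#' summarizes the distribution across subjects with mean and standard
#' deviation — the per-infant reporting style of inter-rater studies.
#'
#' @param pairs a list of length-2 lists/pairs of hypnograms.
#' @return A list with `kappas`, `mean`, `sd`.
#' @export
per_subject_kappas <- function(pairs) {
  if (length(pairs) == 0L) stop("no subject pairs supplied")
  k <- vapply(pairs, function(p) cohens_kappa(confusion(p[[1]], p[[2]])),
              numeric(1))
  list(kappas = k, mean = mean(k), sd = stats::sd(k))
}

#' Paired comparison of two kappa lists
#'
#' Wilcoxon signed-rank test on paired per-subject differences, with
#' Bonferroni correction for a family of `n_comparisons` tests. The null
#' distribution is exact (full enumeration of sign assignments) for up to
#' 12 nonzero differences and a normal approximation with continuity
#' correction beyond; all-zero differences give p = 1 by convention.
#'
#' @param kappas_a,kappas_b equal-length numeric vectors paired by subject.
#' @param n_comparisons size of the comparison family (default 1).
#' @return A list with `statistic` (signed-rank V), `p_value`,
#'   `p_adjusted`, `significant` (at 0.05 after correction), `n_nonzero`.
#' @export
paired_compare <- function(kappas_a, kappas_b, n_comparisons = 1L) {
  if (length(kappas_a) != length(kappas_b)) {
    stop("paired lists must have equal length")
  }
  if (length(kappas_a) < 2L) stop("need at least 2 subjects")
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1")
  d <- kappas_a - kappas_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, p_adjusted = 1,
                significant = FALSE, n_nonzero = 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12L) {
    # exact: enumerate all 2^n sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  p_adj <- min(1, p * n_comparisons)
  list(statistic = v, p_value = p, p_adjusted = p_adj,
       significant = p_adj < 0.05, n_nonzero = n)
}

#' Compare a behavioral hypnogram against a PSG hypnogram
#'
#' Merges both sources into the shared three-class space — the behavioral
#' side pools QA/AA/V into wake, the PSG side is merged under both schemes
#' (REM+N1+N2 vs N3, and REM vs N1+N2+N3) — and reports the confusion
#' matrix, overall kappa, observed agreement, and per-state kappas for each
#' scheme.
#'
#' @param bsa a behavioral `hypnogram`.
#' @param psg a psg `hypnogram` on the same epoch grid.
#' @return A named list (`A_remplus`, `B_standard`) of agreement reports,
#'   each with `matrix`, `kappa_overall`, `observed_agreement`,
#'   `kappa_per_state`.
#' @export
compare_bsa_psg <- function(bsa, psg) {
  b3 <- merge_bsa_to_three(bsa)
  out <- lapply(c(A_remplus = "A_remplus", B_standard = "B_standard"),
                function(s) {
    p3 <- merge_psg(psg, s)
    m <- confusion(b3, p3)
    per_state <- sapply(THREE_CLASS_STATES, function(st) {
      if (!st %in% b3$labels && !st %in% p3$labels) return(NA_real_)
      per_state_kappa(b3, p3, st)
    })
    list(matrix = m,
         kappa_overall = cohens_kappa(m),
         observed_agreement = sum(diag(m)) / attr(m, "n"),
         kappa_per_state = per_state)
  })
  out
}
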
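# Performance measures: per-pattern Pearson correlation (computed across
# units), mean-pattern baselines, doppelganger profiles, capacity estimation
# and relaxation tallies.

#' Pearson correlation between two patterns
#'
#' The model's performance measure: the Pearson correlation between a
#' retrieved pattern and its ground truth, computed across units for each
#' pattern. If either vector has zero variance (e.g. an all-off retrieved
#' state, a legitimate failure output) the correlation is defined as 0 and
#' the result carries the attribute `zero_variance = TRUE` instead of
#' raising an error.
#'
#' @param a,b Numeric vectors of equal length (at least 2).
#' @return A single correlation in \[-1, 1\].
#' @export
#' @examples
#' pearson(c(1, 0, 1, 0), c(1, 0, 0, 1))  # 0
pearson <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(0, zero_variance = TRUE))
  stats::cor(a, b)
}

#' Correlation curve over sequence positions
#'
#' Bundles per-position retrieval correlations with the mean-pattern
#' baseline and a least-squares trend line, mirroring the standard
#' per-pattern performance plots (main curve, trend, baseline).
#'
#' @param positions Integer sequence positions (1-based).
#' @param values Per-position correlations.
#' @param baseline Per-position baseline correlations (against the mean
#'   ground-truth pattern), same length.
#' @return An object of class `correlation_curve` with a fitted `trend`
#'   (intercept, slope).
#' @export
correlation_curve <- function(positions, values, baseline = NULL) {
  stopifnot(length(positions) == length(values),
            is.null(baseline) || length(baseline) == length(values))
  fit <- stats::lm.fit(cbind(1, positions), values)
  structure(list(positions = positions, values = values,
                 baseline = baseline,
                 trend = c(intercept = unname(fit$coefficients[1L]),
                           slope = unname(fit$coefficients[2L]))),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "<correlation_curve> %d positions, mean %.3f, trend slope %.2g/position\n",
    length(x$values), mean(x$values), x$trend[["slope"]]))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(position = x$positions, value = x$values,
             baseline = if (is.null(x$baseline)) NA_real_ else x$baseline)
}

#' Plot a correlation curve
#'
#' Line plot of per-position correlation with the trend line (dashed) and
#' the mean-pattern baseline (dash-dotted), in the layout of the standard
#' recall-performance figures.
#'
#' @param x A [correlation_curve()].
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.correlation_curve <- function(x, main = "Recall performance", ...) {
  graphics::plot(x$positions, x$values, type = "l", col = "blue",
                 ylim = c(min(-0.05, min(x$values)), 1),
                 xlab = "pattern index", ylab = "correlation",
                 main = main, ...)
  graphics::abline(a = x$trend[["intercept"]], b = x$trend[["slope"]],
                   col = "darkorange", lty = 2)
  if (!is.null(x$baseline))
    graphics::lines(x$positions, x$baseline, col = "darkgreen", lty = 4)
  invisible(x)
}

#' Baseline: correlation of retrieved patterns with the mean pattern
#'
#' The trivial-solution reference: for each position, the correlation of
#' the retrieved pattern with the mean over all ground-truth patterns of
#' the sequence. A model that merely outputs the average pattern would sit
#' exactly on this curve.
#'
#' @param retrieved Matrix of retrieved patterns (rows) or list of vectors.
#' @param ground_truth A [binary_sequence()] (or matrix) of ground truth.
#' @return Numeric vector of baseline correlations, one per retrieved row.
#' @export
baseline_curve <- function(retrieved, ground_truth) {
  if (is.list(retrieved) && !is.matrix(retrieved))
    retrieved <- do.call(rbind, retrieved)
  gt <- if (inherits(ground_truth, "binary_sequence"))
    as.matrix(ground_truth) else ground_truth
  mean_pat <- colMeans(gt)
  vapply(seq_len(nrow(retrieved)),
         function(t) as.numeric(pearson(retrieved[t, ], mean_pat)),
         numeric(1))
}

#' Doppelganger profile: max correlation with any other pattern
#'
#' For every pattern in a sequence, the maximum Pearson correlation with
#' all *other* patterns. High values mark "doppelgangers": patterns so
#' similar to another stored pattern that a cue may trigger the wrong
#' (typically more recent) subsequence.
#'
#' @param seq A [binary_sequence()] or pattern matrix (rows = patterns).
#' @return Numeric vector of length `T`.
#' @export
max_correlation_profile <- function(seq) {
  m <- if (inherits(seq, "binary_sequence")) as.matrix(seq) else seq
  T_len <- nrow(m)
  stopifnot(T_len >= 2)
  sds <- apply(m, 1L, stats::sd)
  cm <- matrix(0, T_len, T_len)
  ok <- sds > 0
  if (sum(ok) >= 2) cm[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  diag(cm) <- -Inf
  apply(cm, 1L, max)
}

#' Pattern-separation summary between two representations
#'
#' Quantifies how a transformation (typically EC -> DG) changes the worst
#' pairwise overlap of a pattern set: finds the most-correlated pair in the
#' source representation and reports that same pair's correlation in the
#' target representation, alongside the overall maxima. Effective pattern
#' separation shows up as `target_at_source_max` far below `source_max`.
#'
#' @param source Pattern matrix (or [binary_sequence()]) in the source
#'   space, rows = patterns.
#' @param target Matrix of the same patterns in the target space.
#' @return List with `source_max`, `target_at_source_max`, `target_max`
#'   and `pair` (the 1-based indices of the most-correlated source pair).
#' @export
decorrelation_summary <- function(source, target) {
  s <- if (inherits(source, "binary_sequence")) as.matrix(source) else source
  stopifnot(nrow(s) == nrow(target), nrow(s) >= 2)
  cs <- suppressWarnings(stats::cor(t(s)))
  cs[is.na(cs)] <- 0
  diag(cs) <- -Inf
  pair <- which(cs == max(cs), arr.ind = TRUE)[1L, ]
  list(source_max = max(cs),
       target_at_source_max = as.numeric(pearson(target[pair[1L], ],
                                                 target[pair[2L], ])),
       target_max = max(max_correlation_profile(target)),
       pair = unname(pair))
}

#' Empirical capacity from a correlation curve
#'
#' The number of patterns the model can still hold: the length of the
#' maximal contiguous suffix (the most recently stored block) whose
#' per-pattern correlation is at least `threshold`. Under graded forgetting
#' the curve rises with storage recency, so the recent block is the natural
#' capacity measure; no sharp criterion exists in general, and the
#' threshold is exposed.
#'
#' @param curve A [correlation_curve()] or plain numeric vector ordered by
#'   storage position (earliest first).
#' @param threshold Correlation threshold (default 0.9).
#' @return Integer capacity (0 if even the most recent pattern fails).
#' @export
estimate_capacity <- function(curve, threshold = 0.9) {
  v <- if (inherits(curve, "correlation_curve")) curve$values else curve
  below <- which(v < threshold)
  if (length(below) == 0) return(length(v))
  length(v) - max(below)
}

#' Tally relaxation outcomes over a set of recalls
#'
#' @param results List of `recall_result` objects (see [retrieve()]).
#' @return Named integer vector with counts for `correct`, `shifted` and
#'   `spurious`.
#' @export
relaxation_stats <- function(results) {
  stopifnot(length(results) >= 1)
  cls <- vapply(results, function(r) r$relaxation, character(1))
  out <- c(correct = sum(cls == "correct"),
           shifted = sum(cls == "shifted"),
           spurious = sum(cls == "spurious"))
  out
}
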
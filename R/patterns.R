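#' Binary pattern sequence
#'
#' Container for an ordered set of binary patterns: a `T x n` 0/1 matrix
#' (row `t` is the pattern at sequence position `t`), the nominal activity
#' level (fraction of active units per pattern) and the seed it was generated
#' from. Positions are reported 1-based.
#'
#' @param patterns `T x n` matrix with entries in \{0,1\}.
#' @param activity Nominal activity in (0,1).
#' @param seed Integer seed recorded for provenance (may be `NA`).
#' @return An object of class `binary_sequence`.
#' @export
binary_sequence <- function(patterns, activity, seed = NA_integer_) {
  stopifnot(is.matrix(patterns), all(patterns %in% c(0, 1)),
            activity > 0, activity < 1)
  structure(list(patterns = patterns, activity = activity, seed = seed),
            class = "binary_sequence")
}

#' @export
print.binary_sequence <- function(x, ...) {
  cat(sprintf("<binary_sequence> %d patterns x %d units, activity %.3g (mean row sum %.1f)\n",
              nrow(x$patterns), ncol(x$patterns), x$activity,
              mean(rowSums(x$patterns))))
  invisible(x)
}

#' @export
as.matrix.binary_sequence <- function(x, ...) x$patterns

#' @export
length.binary_sequence <- function(x) nrow(x$patterns)

# One random binary pattern with exactly k ones out of n.
rand_pattern <- function(n, k) {
  x <- numeric(n)
  x[sample.int(n, k)] <- 1
  x
}

#' Generate an uncorrelated random binary sequence (RAND)
#'
#' Every pattern independently has exactly `round(activity * n)` randomly
#' placed active units, mirroring the statistics of entorhinal-cortex codes
#' in which a fixed fraction of units is active at any time. Pairwise
#' correlations are zero in expectation.
#'
#' @param n Number of units per pattern.
#' @param T_len Number of patterns in the sequence.
#' @param activity Fraction of active units, in (0,1); the per-pattern count
#'   is exact, not Bernoulli.
#' @param seed Integer seed; identical seeds give bit-identical sequences.
#' @return A [binary_sequence()].
#' @export
#' @examples
#' s <- gen_rand(n = 200, T_len = 5, activity = 0.35, seed = 1)
#' rowSums(as.matrix(s))  # all exactly 70
gen_rand <- function(n, T_len, activity, seed) {
  stopifnot(T_len >= 1, activity > 0, activity < 1)
  k <- round(activity * n)
  if (k == 0)
    stop("gen_rand: activity*n rounds to zero active units", call. = FALSE)
  pats <- with_seed(seed,
                    t(vapply(seq_len(T_len), function(i) rand_pattern(n, k),
                             numeric(n))))
  binary_sequence(pats, activity, seed)
}

#' Generate a temporally correlated random binary sequence (RAND-CORR)
#'
#' The first pattern is drawn as in [gen_rand()]. Each subsequent pattern
#' starts from its predecessor, from which `flip_frac` of all units are
#' selected -- half of them currently on, half currently off -- and flipped.
#' Activity is conserved exactly. With the defaults of the model
#' (activity 0.35, `flip_frac` 0.1) consecutive patterns have an expected
#' Pearson correlation of (0.30 - 0.35^2) / (0.35 * 0.65) ~= 0.78, i.e. the
#' "high correlation of about 0.8" regime, while distant patterns
#' decorrelate.
#'
#' @inheritParams gen_rand
#' @param flip_frac Fraction of all units flipped per step (split evenly
#'   between on-to-off and off-to-on).
#' @return A [binary_sequence()].
#' @export
gen_rand_corr <- function(n, T_len, activity, flip_frac = 0.1, seed) {
  stopifnot(T_len >= 1, activity > 0, activity < 1,
            flip_frac >= 0, flip_frac <= 1)
  k <- round(activity * n)
  if (k == 0)
    stop("gen_rand_corr: activity*n rounds to zero active units",
         call. = FALSE)
  f <- round(flip_frac * n / 2)
  if (f > min(k, n - k))
    stop(sprintf(
      "gen_rand_corr: flip count %d exceeds available on (%d) or off (%d) units",
      f, k, n - k), call. = FALSE)
  pats <- with_seed(seed, {
    m <- matrix(0, T_len, n)
    m[1L, ] <- rand_pattern(n, k)
    if (T_len > 1L) {
      for (t in 2:T_len) {
        x <- m[t - 1L, ]
        if (f > 0) {
          on <- which(x == 1)
          off <- which(x == 0)
          x[sample(on, f)] <- 0
          x[sample(off, f)] <- 1
        }
        m[t, ] <- x
      }
    }
    m
  })
  binary_sequence(pats, activity, seed)
}

#' Corrupt a binary pattern with activity-conserving flip noise
#'
#' `noise_pct` is interpreted relative to the number of active units:
#' `k = round(noise_pct * n_on)` on-units are switched off and the same
#' number of off-units switched on, so total activity is conserved and the
#' Hamming distance to the original is exactly `2k`.
#'
#' @param x Binary vector.
#' @param noise_pct Noise level in \[0,1\] relative to the on-unit count.
#' @param seed Integer seed.
#' @return Corrupted binary vector with the same number of active units.
#' @export
add_binary_noise <- function(x, noise_pct, seed) {
  stopifnot(all(x %in% c(0, 1)), noise_pct >= 0)
  n_on <- sum(x == 1)
  k <- round(noise_pct * n_on)
  if (k > min(n_on, length(x) - n_on))
    stop(sprintf("add_binary_noise: cannot flip %d units (on=%d, off=%d)",
                 k, n_on, length(x) - n_on), call. = FALSE)
  if (k == 0) return(x)
  with_seed(seed, {
    on <- which(x == 1)
    off <- which(x == 0)
    x[sample(on, k)] <- 0
    x[sample(off, k)] <- 1
    x
  })
}

#' Grayscale image set
#'
#' @param images `M x H x W` array with values in \[0,1\].
#' @param labels Optional integer labels of length `M`.
#' @return An object of class `gray_image_set`.
#' @export
gray_image_set <- function(images, labels = NULL) {
  stopifnot(is.array(images), length(dim(images)) == 3L,
            min(images) >= 0, max(images) <= 1)
  if (!is.null(labels)) stopifnot(length(labels) == dim(images)[1L])
  structure(list(images = images, labels = labels), class = "gray_image_set")
}

#' @export
print.gray_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<gray_image_set> %d images of %dx%d, values in [%.2f, %.2f]\n",
              d[1L], d[2L], d[3L], min(x$images), max(x$images)))
  invisible(x)
}

#' Flatten an image set to a pattern matrix
#'
#' @param imgs A [gray_image_set()].
#' @return `M x (H*W)` matrix, each row an image in row-major pixel order.
#' @export
flatten_images <- function(imgs) {
  d <- dim(imgs$images)
  matrix(aperm(imgs$images, c(2, 3, 1)), nrow = d[1L], byrow = TRUE)
}

# Smooth random blob field on an H x W grid: a sum of Gaussian bumps.
blob_field <- function(H, W, n_bumps) {
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  field <- matrix(0, H, W)
  sdv <- max(H, W) / 5
  for (b in seq_len(n_bumps)) {
    cy <- stats::runif(1, 1, H)
    cx <- stats::runif(1, 1, W)
    amp <- stats::runif(1, 0.6, 1.4)
    field <- field + amp * exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * sdv^2))
  }
  field
}

#' Generate synthetic near-binary grayscale images
#'
#' Produces smoothed random blob images passed through a steep soft
#' threshold, emulating the key statistics of handwritten-digit images:
#' values in \[0,1\] with most pixel mass concentrated near 0 and 1, and a
#' per-image foreground fraction between 0.1 and 0.5. Intended as a
#' self-contained stand-in stimulus set for training and testing the sensory
#' binarizing codec without any external download.
#'
#' @param M Number of images.
#' @param H,W Image height and width in pixels.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A [gray_image_set()] of dimension `M x H x W`.
#' @export
gen_synthetic_images <- function(M, H = 16, W = 16, seed = 1) {
  stopifnot(M >= 1, H >= 1, W >= 1)
  with_seed(seed, {
    arr <- array(0, c(M, H, W))
    for (m in seq_len(M)) {
      field <- blob_field(H, W, n_bumps = sample(3:6, 1))
      fg <- stats::runif(1, 0.15, 0.45)
      thr <- stats::quantile(field, 1 - fg, names = FALSE)
      sc <- stats::sd(field)
      if (sc < 1e-12) sc <- 1
      img <- stats::plogis(35 * (field - thr) / sc)
      arr[m, , ] <- img
    }
    gray_image_set(arr)
  })
}

#' Export a binary sequence as CSV
#'
#' One row per pattern, columns `u1..un`, preceded by a `position` column.
#'
#' @param seq A [binary_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(seq, path) {
  m <- as.matrix(seq)
  df <- data.frame(position = seq_len(nrow(m)), m)
  names(df) <- c("position", paste0("u", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
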
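# Offline pre-training of the three fixed pathways: the CA3 recurrent
# intrinsic-sequence generator, the generic DG pattern separator, and the
# sensory (SI <-> EC) binarizing codec. These are trained once, before any
# one-shot storage, and are not plastic on the fast timescale.

#' Cyclic intrinsic CA3 sequence
#'
#' A fixed cyclic sequence of pairwise-distinct random binary CA3 patterns.
#' The successor of the last position is position 1. Input sequences are
#' later hetero-associated with this scaffold rather than stored in the
#' recurrent weights themselves.
#'
#' @param n_ca3 CA3 layer size.
#' @param T_intr Sequence length.
#' @param activity CA3 activity level (fraction of active units).
#' @param seed Integer seed.
#' @return An object of class `intrinsic_sequence` (also a
#'   [binary_sequence()]).
#' @export
intrinsic_sequence <- function(n_ca3, T_intr, activity = 0.25, seed = 1) {
  k <- round(activity * n_ca3)
  if (k == 0)
    stop("intrinsic_sequence: activity*n_ca3 rounds to zero", call. = FALSE)
  pats <- with_seed(seed, {
    m <- matrix(0, T_intr, n_ca3)
    seen <- new.env(hash = TRUE)
    for (t in seq_len(T_intr)) {
      repeat { # reject duplicates so every position is unambiguous
        x <- rand_pattern(n_ca3, k)
        key <- paste(which(x == 1), collapse = ",")
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          break
        }
      }
      m[t, ] <- x
    }
    m
  })
  out <- binary_sequence(pats, activity, seed)
  class(out) <- c("intrinsic_sequence", class(out))
  out
}

# Successor position in a cyclic sequence (1-based).
next_pos <- function(t, T_len) (t %% T_len) + 1L

#' One recurrent transition of the intrinsic CA3 dynamics
#'
#' Applies the pre-trained recurrent associator to a CA3 state and
#' binarizes, yielding the next state of the intrinsic sequence.
#'
#' @param ca3_recurrent The recurrent [centered_associator()].
#' @param state Binary CA3 state vector.
#' @return Binary CA3 state vector.
#' @export
ca3_transition <- function(ca3_recurrent, state) {
  binarize(activate(ca3_recurrent, state))
}

#' Pre-train CA3 as an intrinsic sequence generator
#'
#' Trains the recurrent CA3 pathway by hetero-associative Hebbian descent so
#' that each pattern of a cyclic random sequence maps to its successor. In
#' every epoch the inputs are corrupted by flipping a fraction of randomly
#' chosen units, which makes the learned transitions robust to noisy states;
#' the targets stay clean. Multiple epochs are used here only because this
#' is offline pre-training, in contrast to the one-shot storage phase.
#'
#' @param n_ca3 CA3 layer size.
#' @param T_intr Length of the intrinsic sequence.
#' @param activity CA3 activity level; also used as the input offset `mu`.
#' @param epochs Training epochs (default 100).
#' @param flip_frac Fraction of input units flipped per presentation
#'   (default 0.10).
#' @param batch Mini-batch size (default 10; updates average over the
#'   batch).
#' @param eta Learning rate (default 1.0).
#' @param seed Integer seed covering sequence generation and noise.
#' @return `list(assoc, intrinsic, report)` where `report` is a
#'   `pretrain_report` with `epochs_run` and `self_consistency` (mean
#'   correlation of one-step transitions from clean patterns against their
#'   true successors; a warning is recorded below 0.99).
#' @export
pretrain_ca3 <- function(n_ca3, T_intr = n_ca3, activity = 0.25,
                         epochs = 100, flip_frac = 0.10, batch = 10,
                         eta = 1.0, seed = 1) {
  intr <- intrinsic_sequence(n_ca3, T_intr, activity,
                             seed = child_seed(seed, 1))
  pats <- as.matrix(intr)
  succ <- if (T_intr == 1L) 1L else c(2:T_intr, 1L)
  targets <- pats[succ, , drop = FALSE]
  assoc <- centered_associator(n_ca3, n_ca3, mu = activity, mode = "hetero")
  us <- update_state(assoc, eta = eta)
  n_flip <- round(flip_frac * n_ca3)
  if (epochs > 0) {
    with_seed(child_seed(seed, 2), {
      for (ep in seq_len(epochs)) {
        X <- pats
        if (n_flip > 0) {
          for (t in seq_len(T_intr)) {
            idx <- sample.int(n_ca3, n_flip)
            X[t, idx] <- 1 - X[t, idx]
          }
        }
        ord <- sample.int(T_intr)
        for (start in seq(1L, T_intr, by = batch)) {
          sel <- ord[start:min(start + batch - 1L, T_intr)]
          st <- hetero_step(assoc, us, X[sel, , drop = FALSE],
                            targets[sel, , drop = FALSE])
          assoc <- st$assoc
          us <- st$us
        }
      }
    })
  }
  trans <- binarize(activate(assoc, pats))
  sc <- mean(vapply(seq_len(T_intr),
                    function(t) pearson(trans[t, ], targets[t, ]),
                    numeric(1)))
  report <- structure(list(
    epochs_run = epochs,
    self_consistency = sc,
    warning = if (sc < 0.99)
      sprintf("self-consistency %.3f below 0.99: intrinsic dynamics unreliable", sc)
    else NULL,
    config = list(n_ca3 = n_ca3, T_intr = T_intr, activity = activity,
                  epochs = epochs, flip_frac = flip_frac, batch = batch,
                  eta = eta, seed = seed)
  ), class = "pretrain_report")
  list(assoc = assoc, intrinsic = intr, report = report)
}

#' @export
print.pretrain_report <- function(x, ...) {
  cat(sprintf("<pretrain_report> %d epochs, self-consistency %.4f%s\n",
              x$epochs_run, x$self_consistency,
              if (is.null(x$warning)) "" else " [WARNING]"))
  if (!is.null(x$warning)) cat("  ", x$warning, "\n")
  invisible(x)
}

#' Pre-train DG as a generic pattern separator
#'
#' Trains the EC to DG pathway as a tied-weight autoencoder with Hebbian
#' descent on random binary patterns, independent of any later input
#' statistics. The hidden (DG) representation is regularized towards a
#' sparse target activity via the hidden offsets and the optional hidden
#' bias update, so that after training the encoder expands an EC pattern
#' (default 35% activity) into a much larger, much sparser DG code (default
#' target 3%). Sparse expansion is what reduces the overlap between
#' correlated EC patterns ("pattern separation").
#'
#' The defaults follow the reference protocol: 4000 training patterns, one
#' epoch, mini-batch 10 (400 updates) and a very large learning rate of 100,
#' with `mu` = EC activity and `lam = lam_tilde` = DG target activity.
#' Weights start from small random values (seeded); see
#' [centered_associator()] for why the tied-weight update cannot break
#' symmetry from exact zeros.
#'
#' @param n_ec EC layer size.
#' @param n_dg DG layer size (default `round(10.9 * n_ec)`, the anatomical
#'   size ratio).
#' @param n_samples Number of random training patterns.
#' @param ec_activity EC activity level.
#' @param dg_activity Target DG activity level.
#' @param eta Learning rate.
#' @param batch Mini-batch size.
#' @param seed Integer seed.
#' @return The trained auto-associative [centered_associator()]. Its
#'   binarized forward output is the DG code. Errors if the DG code
#'   collapses to complete silence on held-out patterns.
#' @export
pretrain_dg <- function(n_ec, n_dg = round(10.9 * n_ec), n_samples = 4000,
                        ec_activity = 0.35, dg_activity = 0.03,
                        eta = 100, batch = 10, seed = 1) {
  train <- gen_rand(n_ec, n_samples, ec_activity,
                    seed = child_seed(seed, 1))
  assoc <- centered_associator(
    n_ec, n_dg, mu = ec_activity, mode = "auto",
    lam = dg_activity, lam_tilde = dg_activity,
    init_sd = 0.01, init_seed = child_seed(seed, 2))
  us <- update_state(assoc, eta = eta)
  X <- as.matrix(train)
  for (start in seq(1L, n_samples, by = batch)) {
    sel <- start:min(start + batch - 1L, n_samples)
    st <- auto_step(assoc, us, X[sel, , drop = FALSE],
                    update_output_bias = TRUE)
    assoc <- st$assoc
    us <- st$us
  }
  held <- as.matrix(gen_rand(n_ec, 200, ec_activity,
                             seed = child_seed(seed, 3)))
  act <- mean(binarize(activate(assoc, held)))
  if (act == 0)
    stop("pretrain_dg: DG code collapsed to all-inactive (degenerate)",
         call. = FALSE)
  assoc
}

#' Encode an EC pattern into its sparse DG code
#'
#' @param dg The pre-trained DG associator from [pretrain_dg()].
#' @param x_ec Binary EC pattern (vector or matrix of rows).
#' @return Binary DG code(s).
#' @export
dg_encode <- function(dg, x_ec) binarize(activate(dg, x_ec))

#' Pre-train the sensory binarizing codec (SI <-> EC)
#'
#' Trains a tied-weight autoencoder that maps flattened grayscale images to
#' binary EC codes and back. The visible offsets `mu` are the per-pixel mean
#' of the training set; hidden offsets and the target hidden activity are
#' the EC activity level, so the binary codes come out at roughly that
#' activity. At inference the encoder uses a step output (binary EC codes)
#' and the decoder a sigmoid (grayscale reconstruction); inside the learning
#' updates both directions are sigmoid.
#'
#' @param images A [gray_image_set()] of training images.
#' @param n_ec EC layer size.
#' @param ec_activity Target EC activity level (default 0.35).
#' @param eta Learning rate (default 0.01).
#' @param momentum Momentum coefficient (default 0.9).
#' @param epochs Training epochs (default 10).
#' @param batch Mini-batch size (default 100).
#' @param seed Integer seed (presentation order shuffling).
#' @return The trained auto-associative [centered_associator()]; forward
#'   direction is SI -> EC (step), reconstruction EC -> SI (sigmoid).
#' @export
pretrain_sensory <- function(images, n_ec, ec_activity = 0.35, eta = 0.01,
                             momentum = 0.9, epochs = 10, batch = 100,
                             seed = 1) {
  X <- flatten_images(images)
  if (min(X) < 0 || max(X) > 1)
    stop("pretrain_sensory: image values outside [0,1]", call. = FALSE)
  n_si <- ncol(X)
  M <- nrow(X)
  assoc <- centered_associator(
    n_si, n_ec, mu = colMeans(X), mode = "auto",
    lam = ec_activity, lam_tilde = ec_activity,
    act_fwd = activation_spec("step"),
    act_rec = activation_spec("sigmoid"),
    init_sd = 0.01, init_seed = child_seed(seed, 1))
  # mu must lie in [0,1]; colMeans of [0,1] images always does.
  us <- update_state(assoc, eta = eta, momentum = momentum)
  if (epochs > 0) {
    with_seed(child_seed(seed, 2), {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(M)
        for (start in seq(1L, M, by = batch)) {
          sel <- ord[start:min(start + batch - 1L, M)]
          st <- auto_step(assoc, us, X[sel, , drop = FALSE],
                          update_output_bias = TRUE)
          assoc <- st$assoc
          us <- st$us
        }
      }
    })
  }
  assoc
}

#' Encode images into binary EC codes
#'
#' @param sensory The codec from [pretrain_sensory()].
#' @param images A [gray_image_set()] or an already-flattened matrix.
#' @return Matrix of binary EC codes (one row per image).
#' @export
sensory_encode <- function(sensory, images) {
  X <- if (inherits(images, "gray_image_set")) flatten_images(images) else images
  activate(sensory, X, act = activation_spec("step"))
}

#' Decode binary EC codes back to images
#'
#' @param sensory The codec from [pretrain_sensory()].
#' @param codes Binary EC code vector or matrix.
#' @return Grayscale reconstruction(s) in \[0,1\] (flattened pixel rows).
#' @export
sensory_decode <- function(sensory, codes) {
  reconstruct(sensory, codes, act = activation_spec("sigmoid"))
}
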
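#' Activation specification for a centered neuron layer
#'
#' The model uses two elementwise activation functions: the logistic sigmoid,
#' which yields graded outputs in (0,1) and is used inside all learning
#' updates, and the Heaviside step, which yields binary outputs in \{0,1\} and
#' is used when a state must be propagated as a binary pattern. The step fires
#' only for membrane potentials strictly above `step_threshold`; an exact tie
#' maps to 0, which keeps sparse codes sparse.
#'
#' @param kind `"sigmoid"` or `"step"`.
#' @param step_threshold Threshold on the membrane potential for the step
#'   activation (ignored for sigmoid). Default 0, which makes
#'   `step(a)` equivalent to thresholding `sigmoid(a)` at 0.5.
#' @return An object of class `activation_spec`.
#' @export
#' @examples
#' activation_spec("sigmoid")
#' activation_spec("step", step_threshold = 0)
activation_spec <- function(kind = c("sigmoid", "step"), step_threshold = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(step_threshold), length(step_threshold) == 1L,
            is.finite(step_threshold))
  structure(list(kind = kind, step_threshold = step_threshold),
            class = "activation_spec")
}

# Apply an activation spec to a matrix of membrane potentials.
apply_activation <- function(spec, a) {
  switch(spec$kind,
         sigmoid = stats::plogis(a),
         step = (a > spec$step_threshold) + 0)
}

#' Centered associator: one plastic pathway between two layers
#'
#' A centered associator holds the parameters of a single pathway between an
#' input layer of `n_in` neurons and an output layer of `n_out` neurons:
#' a weight matrix `W` (`n_in x n_out`), an output bias `b`, input offsets
#' `mu` (subtracted from the pre-synaptic input, normally the mean activity
#' of the input layer), and -- for auto-associative (tied-weight autoencoder)
#' use -- a reconstruction bias `c`, hidden offsets `lam` and a target hidden
#' activity `lam_tilde`. The same `W` serves both directions in auto mode
#' (tied weights): the reconstruction uses its transpose.
#'
#' @param n_in,n_out Layer sizes.
#' @param mu Input offsets, scalar (recycled) or length `n_in`, each in
#'   \[0,1\].
#' @param mode `"hetero"` for pure input-to-output association, `"auto"` for
#'   a tied-weight autoencoder with a reconstruction path.
#' @param lam Hidden offsets (auto mode), scalar or length `n_out`.
#' @param lam_tilde Target mean hidden activity (auto mode), scalar in
#'   \[0,1\]; broadcast over output units.
#' @param act_fwd,act_rec [activation_spec()] for the forward and (auto mode)
#'   reconstruction direction.
#' @param init_sd Standard deviation of the Gaussian weight initialization.
#'   Default 0 (zero weights). Auto-associative pre-training requires a small
#'   positive value to break the symmetry between hidden units, because the
#'   tied-weight update is identical for every hidden unit when all weights
#'   (and hence all hidden activities) coincide.
#' @param init_seed Seed used when `init_sd > 0`.
#' @return An object of class `centered_associator`.
#' @export
centered_associator <- function(n_in, n_out, mu = 0.5,
                                mode = c("hetero", "auto"),
                                lam = NULL, lam_tilde = NULL,
                                act_fwd = activation_spec("sigmoid"),
                                act_rec = activation_spec("sigmoid"),
                                init_sd = 0, init_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_in >= 1, n_out >= 1, all(mu >= 0 & mu <= 1),
            length(mu) %in% c(1L, n_in), init_sd >= 0)
  if (init_sd > 0) {
    W <- with_seed(init_seed,
                   matrix(stats::rnorm(n_in * n_out, sd = init_sd), n_in, n_out))
  } else {
    W <- matrix(0, n_in, n_out)
  }
  obj <- list(
    W = W,
    b = numeric(n_out),
    c = if (mode == "auto") numeric(n_in) else NULL,
    mu = rep_len(as.numeric(mu), n_in),
    lam = NULL, lam_tilde = NULL,
    act_fwd = act_fwd, act_rec = act_rec,
    mode = mode
  )
  if (mode == "auto") {
    if (is.null(lam)) lam <- 0.5
    if (is.null(lam_tilde)) lam_tilde <- lam[1L]
    stopifnot(all(lam >= 0 & lam <= 1), length(lam) %in% c(1L, n_out),
              length(lam_tilde) == 1L, lam_tilde >= 0, lam_tilde <= 1)
    obj$lam <- rep_len(as.numeric(lam), n_out)
    obj$lam_tilde <- as.numeric(lam_tilde)
  }
  structure(obj, class = "centered_associator")
}

#' @export
print.centered_associator <- function(x, ...) {
  cat(sprintf("<centered_associator> %d -> %d (%s), act %s/%s\n",
              nrow(x$W), ncol(x$W), x$mode, x$act_fwd$kind,
              if (is.null(x$act_rec)) "-" else x$act_rec$kind))
  cat(sprintf("  |W| in [%.3g, %.3g], mu[1]=%.3g",
              min(x$W), max(x$W), x$mu[1L]))
  if (x$mode == "auto")
    cat(sprintf(", lam[1]=%.3g, lam_tilde=%.3g", x$lam[1L], x$lam_tilde))
  cat("\n")
  invisible(x)
}

n_in <- function(assoc) nrow(assoc$W)
n_out <- function(assoc) ncol(assoc$W)

# Forward membrane potential for a batch X (B x n_in): (x - mu) W + b.
membrane_fwd <- function(assoc, X) {
  Xc <- sweep(X, 2L, assoc$mu, "-")
  sweep(Xc %*% assoc$W, 2L, assoc$b, "+")
}

# Reconstruction membrane potential for hidden batch H (B x n_out):
# (h - lam) W' + c. Uses the transpose of the SAME weight matrix (tied).
membrane_rec <- function(assoc, H) {
  if (assoc$mode != "auto")
    stop("reconstruct() requires an auto-associative (tied-weight) associator",
         call. = FALSE)
  Hc <- sweep(H, 2L, assoc$lam, "-")
  sweep(Hc %*% t(assoc$W), 2L, assoc$c, "+")
}

#' Forward activation of a centered associator
#'
#' Computes `h_j = phi(sum_i (x_i - mu_i) w_ij + b_j)` for a single pattern
#' or a batch (rows are patterns).
#'
#' @param assoc A [centered_associator()].
#' @param x Numeric vector of length `n_in`, or a `B x n_in` matrix.
#' @param act Optional [activation_spec()] overriding `assoc$act_fwd`.
#' @return A vector (if `x` was a vector) or matrix of output activities.
#' @export
activate <- function(assoc, x, act = assoc$act_fwd) {
  vec <- !is.matrix(x)
  X <- as_row_matrix(x, n_in(assoc), "activate input")
  if (!all(is.finite(X))) stop("activate: non-finite input", call. = FALSE)
  H <- apply_activation(act, membrane_fwd(assoc, X))
  if (vec) drop(H) else H
}

#' Reconstruction through the tied weights of an auto-associator
#'
#' Computes `z_i = phi(sum_j (h_j - lam_j) w_ij + c_i)`, the decoder
#' direction of a tied-weight autoencoder. Errors when called on a
#' hetero-only associator.
#'
#' @inheritParams activate
#' @param h Hidden activity vector of length `n_out`, or a `B x n_out`
#'   matrix.
#' @return Reconstructed input activities.
#' @export
reconstruct <- function(assoc, h, act = assoc$act_rec) {
  vec <- !is.matrix(h)
  H <- as_row_matrix(h, n_out(assoc), "reconstruct input")
  Z <- apply_activation(act, membrane_rec(assoc, H))
  if (vec) drop(Z) else Z
}

#' Update state for Hebbian descent training
#'
#' Carries the learning rate, the momentum coefficient and the previous
#' update buffers (initialized to zero) that momentum accumulates into.
#' With `momentum = 0` the buffers are inert and training is plain Hebbian
#' descent.
#'
#' @param assoc The associator that will be trained (fixes buffer shapes).
#' @param eta Learning rate, positive.
#' @param momentum Fraction of the previous update added to the current one,
#'   in \[0, 1).
#' @return An object of class `update_state`.
#' @export
update_state <- function(assoc, eta, momentum = 0) {
  stopifnot(eta > 0, momentum >= 0, momentum < 1)
  structure(list(
    eta = eta, momentum = momentum,
    prev_dW = matrix(0, n_in(assoc), n_out(assoc)),
    prev_db = numeric(n_out(assoc)),
    prev_dc = if (assoc$mode == "auto") numeric(n_in(assoc)) else NULL
  ), class = "update_state")
}

check_finite_update <- function(dW, db, dc = NULL, context = "update") {
  bad <- !all(is.finite(dW)) || !all(is.finite(db)) ||
    (!is.null(dc) && !all(is.finite(dc)))
  if (bad) {
    stop(sprintf(
      "%s produced non-finite values (max|dW|=%g, max|db|=%g); check eta",
      context, suppressWarnings(max(abs(dW[is.finite(dW)]), 0)),
      suppressWarnings(max(abs(db[is.finite(db)]), 0))), call. = FALSE)
  }
}

#' One hetero-associative Hebbian descent step
#'
#' Trains the pathway to map inputs `X` onto targets `Tg`. For each sample
#' the weight update is the outer product of the centered input and the
#' output error:
#' `dw_ij = -eta (x_i - mu_i)(h_j - t_j)`, `db_j = -eta (h_j - t_j)`,
#' where `h` is the output computed with the pathway's own forward
#' activation before the update, averaged over the mini-batch. With the
#' default sigmoid activation the error is graded; with a step activation
#' the update vanishes as soon as the binary output is correct
#' (perceptron-like). When `h == t` the update is exactly zero:
#' already-stored pairs are a fixed point, which is what gives Hebbian
#' descent its graded, on-demand forgetting. Momentum, if configured in
#' `us`, adds `momentum * previous_update`.
#'
#' @param assoc A [centered_associator()].
#' @param us An [update_state()].
#' @param X Batch of inputs (`B x n_in`, or a single vector).
#' @param Tg Batch of targets in \[0,1\] (`B x n_out`, or a vector).
#' @param update_bias Apply the bias update (default `TRUE`). Setting it to
#'   `FALSE` gives the interference-free idealization used in
#'   theoretical-capacity analyses of orthogonal codes: the bias update
#'   accumulates every pattern's error into an offset shared by all
#'   patterns, which is exactly the cross-talk that the orthogonality
#'   argument excludes.
#' @return `list(assoc = updated associator, us = updated state)`.
#' @export
hetero_step <- function(assoc, us, X, Tg, update_bias = TRUE) {
  X <- as_row_matrix(X, n_in(assoc), "hetero_step X")
  Tg <- as_row_matrix(Tg, n_out(assoc), "hetero_step targets")
  if (nrow(X) != nrow(Tg)) stop_dims("hetero_step batch", nrow(X), nrow(Tg))
  if (any(Tg < 0 | Tg > 1)) stop("hetero_step: targets outside [0,1]",
                                 call. = FALSE)
  B <- nrow(X)
  H <- apply_activation(assoc$act_fwd, membrane_fwd(assoc, X))
  E <- H - Tg
  Xc <- sweep(X, 2L, assoc$mu, "-")
  dW <- -(us$eta / B) * crossprod(Xc, E) + us$momentum * us$prev_dW
  db <- if (update_bias) {
    -us$eta * colMeans(E) + us$momentum * us$prev_db
  } else {
    numeric(n_out(assoc))
  }
  check_finite_update(dW, db, context = "hetero_step")
  assoc$W <- assoc$W + dW
  assoc$b <- assoc$b + db
  us$prev_dW <- dW
  us$prev_db <- db
  list(assoc = assoc, us = us)
}

#' One auto-associative Hebbian descent step (tied weights)
#'
#' Trains a tied-weight autoencoder on a batch of inputs. With hidden
#' activity `h = activate(x)` and reconstruction `z = reconstruct(h)` (both
#' sigmoid during learning), the updates are
#' `dw_ij = -eta (h_j - lam_j)(z_i - x_i)`, `dc_i = -eta (z_i - x_i)`, and
#' optionally `db_j = -eta (h_j - lam_tilde)`, batch-averaged. The single
#' weight matrix receives the one tied update; encoder and decoder can never
#' drift apart.
#'
#' @inheritParams hetero_step
#' @param update_output_bias If `TRUE`, also apply the optional hidden-bias
#'   update that regularizes the mean hidden activity towards `lam_tilde`.
#' @return `list(assoc, us)` as in [hetero_step()].
#' @export
auto_step <- function(assoc, us, X, update_output_bias = FALSE) {
  if (assoc$mode != "auto")
    stop("auto_step requires an auto-associative associator", call. = FALSE)
  X <- as_row_matrix(X, n_in(assoc), "auto_step X")
  B <- nrow(X)
  sig <- activation_spec("sigmoid")
  H <- apply_activation(sig, membrane_fwd(assoc, X))
  Z <- apply_activation(sig, membrane_rec(assoc, H))
  Hc <- sweep(H, 2L, assoc$lam, "-")
  R <- Z - X
  dW <- -(us$eta / B) * crossprod(R, Hc) + us$momentum * us$prev_dW
  dc <- -us$eta * colMeans(R) + us$momentum * us$prev_dc
  db <- if (update_output_bias) {
    -us$eta * colMeans(H - assoc$lam_tilde) + us$momentum * us$prev_db
  } else {
    numeric(n_out(assoc))
  }
  check_finite_update(dW, db, dc, context = "auto_step")
  assoc$W <- assoc$W + dW
  assoc$c <- assoc$c + dc
  assoc$b <- assoc$b + db
  us$prev_dW <- dW
  us$prev_dc <- dc
  us$prev_db <- db
  list(assoc = assoc, us = us)
}

#' Size-scaled default learning rate for one-shot storage
#'
#' Returns `20 / N`, which works well in practice for the plastic one-shot
#' pathways of networks with `N` between roughly 20 and 2000 input units
#' (giving e.g. 0.1 at `N = 200`).
#'
#' @param N Network (input layer) size, at least 1.
#' @return The learning rate `20 / N`.
#' @export
default_learning_rate <- function(N) {
  stopifnot(N >= 1)
  20 / N
}

#' Threshold graded activities into a binary pattern
#'
#' @param h Numeric vector or matrix of activities.
#' @param threshold Values strictly above it map to 1, everything else
#'   (including an exact tie) to 0.
#' @return Binary vector/matrix of the same shape.
#' @export
binarize <- function(h, threshold = 0.5) {
  if (!all(is.finite(h))) stop("binarize: non-finite input", call. = FALSE)
  (h > threshold) + 0
}
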
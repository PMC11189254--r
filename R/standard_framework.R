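#' Baseline: online sequence storage through recurrent CA3 plasticity
#'
#' The classical alternative to intrinsic sequences: the sequence is stored
#' directly in CA3's recurrent collaterals by hetero-associating each
#' pattern with its successor, online and one pattern pair at a time, with
#' Hebbian descent. Recall then asks how well the pattern `k` steps after a
#' given start can be reproduced by iterating the learned recurrent
#' dynamics `k` times from the ground-truth start pattern.
#'
#' This simulation is performed purely in CA3 space on uncorrelated random
#' patterns with the same dimensionality and activity as the intrinsic
#' sequence of the full model. Performance is highly sensitive to the
#' learning rate (useful values lie roughly between 0.01 and 0.025) and
#' collapses as the number of transitions grows -- the comparison that
#' motivates hetero-association onto a pre-trained intrinsic sequence
#' instead.
#'
#' @param n_ca3 CA3 layer size.
#' @param T_len Sequence length.
#' @param activity CA3 activity level (also the input offset `mu`).
#' @param eta Learning rate for the recurrent one-shot updates.
#' @param transitions_list Integer vector of transition counts `k` to
#'   evaluate.
#' @param seed Integer seed for the pattern sequence.
#' @return A named list, one [correlation_curve()] per `k` (names
#'   `"k<k>"`), each over the start positions `t` with `t + k <= T_len`;
#'   `k = 0` is the identity check and gives correlation 1 everywhere.
#' @export
standard_framework_run <- function(n_ca3, T_len, activity = 0.25, eta = 0.01,
                                   transitions_list = c(1, 5, 25),
                                   seed = 1) {
  stopifnot(all(transitions_list >= 0), T_len >= 2)
  seq <- gen_rand(n_ca3, T_len, activity, seed = seed)
  pats <- as.matrix(seq)
  assoc <- centered_associator(n_ca3, n_ca3, mu = activity, mode = "hetero")
  us <- update_state(assoc, eta = eta)
  for (t in seq_len(T_len - 1L)) {
    st <- hetero_step(assoc, us, pats[t, ], pats[t + 1L, ])
    assoc <- st$assoc
    us <- st$us
  }
  out <- list()
  for (k in transitions_list) {
    starts <- seq_len(T_len - k)
    vals <- numeric(length(starts))
    retrieved <- matrix(0, length(starts), n_ca3)
    for (t in starts) {
      state <- pats[t, ]
      i <- 0L
      while (i < k) {
        state <- ca3_transition(assoc, state)
        i <- i + 1L
      }
      retrieved[t, ] <- state
      vals[t] <- if (k == 0) 1 else as.numeric(pearson(state, pats[t + k, ]))
    }
    out[[paste0("k", k)]] <- correlation_curve(
      starts, vals, baseline_curve(retrieved, pats))
  }
  out
}
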
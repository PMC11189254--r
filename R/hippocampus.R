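# Assembly of the hippocampal circuit and its dynamical modes: one-shot
# storage, cued retrieval with sequence relaxation, full intrinsic recall,
# offline replay, and DG ablation.

#' Build a hippocampus model
#'
#' Assembles the circuit around an EC layer of `n_ec` neurons: an optional
#' sensory codec (SI <-> EC), an optional pre-trained DG pattern separator
#' (EC -> DG), a pre-trained recurrent CA3 intrinsic-sequence generator, and
#' the two plastic one-shot pathways -- the encoder (DG -> CA3, or EC -> CA3
#' when `use_dg = FALSE`) and the decoder (CA3 -> EC). Subregion sizes
#' follow the anatomical ratios CA3 = 2.3 N and DG = 10.9 N by default, with
#' activity levels scaled up for small models (35% EC, 3% DG, 25% CA3).
#'
#' The plastic pathways start from zero weights; their input offsets `mu`
#' are the mean activity of their source layer (DG activity for the encoder
#' with DG, EC activity without, CA3 activity for the decoder). Pre-training
#' the recurrent pathway can be skipped (`pretrain_recurrent = FALSE`) for
#' analyses that never run the intrinsic dynamics, such as direct
#' encode-decode capacity scans; the intrinsic sequence itself is always
#' generated.
#'
#' @param n_ec Number of EC neurons (the reference size N).
#' @param n_ca3_factor,n_dg_factor Size ratios for CA3 and DG.
#' @param ec_activity,dg_activity,ca3_activity Activity levels per layer.
#' @param T_intr Length of the intrinsic CA3 sequence (default `n_ec`).
#' @param use_dg Include the DG pattern separator in the encoding path.
#' @param sensory Optional pre-trained codec from [pretrain_sensory()].
#' @param dg Optional pre-trained DG associator; trained here via
#'   [pretrain_dg()] when `NULL` and `use_dg = TRUE`.
#' @param pretrain_recurrent Train the CA3 recurrent pathway (default
#'   `TRUE`).
#' @param ca3_epochs Epochs for CA3 pre-training.
#' @param plastic_act Forward activation of the plastic pathways:
#'   `"sigmoid"` (default; graded Hebbian descent error) or `"step"`
#'   (perceptron-like error that vanishes once the binary output is
#'   correct; used for exactness demonstrations on orthogonal codes).
#' @param seed Integer seed for all pre-training randomness.
#' @return An object of class `hippocampus_model`.
#' @export
build_hippocampus <- function(n_ec, n_ca3_factor = 2.3, n_dg_factor = 10.9,
                              ec_activity = 0.35, dg_activity = 0.03,
                              ca3_activity = 0.25, T_intr = n_ec,
                              use_dg = TRUE, sensory = NULL, dg = NULL,
                              pretrain_recurrent = TRUE, ca3_epochs = 100,
                              plastic_act = c("sigmoid", "step"),
                              seed = 1) {
  plastic_act <- match.arg(plastic_act)
  stopifnot(n_ec >= 1, T_intr >= 1)
  n_ca3 <- round(n_ca3_factor * n_ec)
  n_dg <- round(n_dg_factor * n_ec)
  if (use_dg && is.null(dg)) {
    dg <- pretrain_dg(n_ec, n_dg, ec_activity = ec_activity,
                      dg_activity = dg_activity,
                      seed = child_seed(seed, 11))
  }
  if (!use_dg) dg <- NULL
  ca3 <- pretrain_ca3(n_ca3, T_intr = T_intr, activity = ca3_activity,
                      epochs = if (pretrain_recurrent) ca3_epochs else 0,
                      seed = child_seed(seed, 12))
  act <- activation_spec(plastic_act)
  enc <- if (use_dg) {
    centered_associator(ncol(dg$W), n_ca3, mu = dg_activity, mode = "hetero",
                        act_fwd = act)
  } else {
    centered_associator(n_ec, n_ca3, mu = ec_activity, mode = "hetero",
                        act_fwd = act)
  }
  dec <- centered_associator(n_ca3, n_ec, mu = ca3_activity, mode = "hetero",
                             act_fwd = act)
  structure(list(
    sensory = sensory, dg = dg,
    ca3_recurrent = ca3$assoc, intrinsic = ca3$intrinsic,
    pretrain_report = ca3$report,
    enc_plastic = enc, dec_plastic = dec,
    config = list(n_ec = n_ec, n_ca3 = n_ca3, n_dg = n_dg,
                  ec_activity = ec_activity, dg_activity = dg_activity,
                  ca3_activity = ca3_activity, T_intr = T_intr,
                  use_dg = use_dg, plastic_act = plastic_act, seed = seed),
    clock = 0L, stored = NULL
  ), class = "hippocampus_model")
}

#' @export
print.hippocampus_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hippocampus_model> N=%d (EC) -> DG=%s -> CA3=%d, T_intr=%d\n",
              cfg$n_ec, if (cfg$use_dg) cfg$n_dg else "ablated",
              cfg$n_ca3, cfg$T_intr))
  cat(sprintf("  activities EC %.2f / DG %.2f / CA3 %.2f; stored patterns: %d\n",
              cfg$ec_activity, cfg$dg_activity, cfg$ca3_activity, x$clock))
  invisible(x)
}

# Encoding-path code that feeds the plastic encoder: the sparse DG code, or
# the EC pattern itself when DG is ablated.
encoder_input <- function(model, x_ec) {
  if (is.null(model$dg)) x_ec else dg_encode(model$dg, x_ec)
}

# Cue -> CA3 state through the plastic encoder (retrieval step 0).
encode_cue <- function(model, cue_ec) {
  binarize(activate(model$enc_plastic, encoder_input(model, cue_ec)))
}

# CA3 state -> binary EC pattern through the plastic decoder.
decode_ca3 <- function(model, x_ca3) {
  binarize(activate(model$dec_plastic, x_ca3))
}

#' One-shot storage of an EC pattern sequence
#'
#' Stores a sequence online: each pattern is seen exactly once and triggers
#' exactly one Hebbian descent update per plastic pathway. At step `t` the
#' EC pattern is propagated to its encoding code (DG, or EC itself without
#' DG) and hetero-associated in both directions with the current intrinsic
#' CA3 pattern; the intrinsic state then advances to its successor. During
#' storage the CA3 state follows the clean intrinsic sequence (theta-phase
#' suppression of the DG -> CA3 input), so the encoder's own output never
#' influences which CA3 pattern is associated. The very first intrinsic
#' position is picked uniformly at random from the cycle.
#'
#' @param model A [build_hippocampus()] model.
#' @param ec_seq A [binary_sequence()] (or matrix) of EC patterns; at most
#'   `T_intr` long.
#' @param eta Learning rate for both plastic pathways; default
#'   [default_learning_rate()] of `n_ec`, i.e. 20/N.
#' @param seed Seed for the random starting position (used only when the
#'   model has not stored anything yet; later calls continue the cycle).
#' @param update_bias Passed to [hetero_step()]; `FALSE` gives the
#'   interference-free idealization used for orthogonal-code capacity
#'   demonstrations.
#' @return The updated model; `model$stored` holds the ground-truth EC
#'   patterns and their intrinsic positions for evaluation.
#' @export
store_sequence <- function(model, ec_seq, eta = NULL, seed = 1,
                           update_bias = TRUE) {
  X <- if (inherits(ec_seq, "binary_sequence")) as.matrix(ec_seq) else ec_seq
  T_s <- nrow(X)
  if (is.null(T_s) || T_s == 0L) return(model)
  T_intr <- length(model$intrinsic)
  if (T_s > T_intr)
    stop(sprintf(
      "store_sequence: sequence length %d exceeds intrinsic capacity %d",
      T_s, T_intr), call. = FALSE)
  if (ncol(X) != model$config$n_ec)
    stop_dims("store_sequence EC patterns", model$config$n_ec, ncol(X))
  if (is.null(eta)) eta <- default_learning_rate(model$config$n_ec)
  intr <- as.matrix(model$intrinsic)
  if (model$clock == 0L) {
    start <- with_seed(seed, sample.int(T_intr, 1L))
  } else {
    start <- next_pos(model$stored$positions[length(model$stored$positions)],
                      T_intr)
  }
  us_enc <- update_state(model$enc_plastic, eta = eta)
  us_dec <- update_state(model$dec_plastic, eta = eta)
  positions <- integer(T_s)
  pos <- start
  for (t in seq_len(T_s)) {
    positions[t] <- pos
    x_ec <- X[t, ]
    x_code <- encoder_input(model, x_ec)
    x_ca3 <- intr[pos, ]
    st <- hetero_step(model$enc_plastic, us_enc, x_code, x_ca3,
                      update_bias = update_bias)
    model$enc_plastic <- st$assoc
    us_enc <- st$us
    st <- hetero_step(model$dec_plastic, us_dec, x_ca3, x_ec,
                      update_bias = update_bias)
    model$dec_plastic <- st$assoc
    us_dec <- st$us
    pos <- next_pos(pos, T_intr)
  }
  model$stored <- list(
    ec = rbind(model$stored$ec, X),
    positions = c(model$stored$positions, positions))
  model$clock <- model$clock + T_s
  model
}

# Mean correlation of a run of CA3 states against the intrinsic sequence
# starting at position p0 (state i compared to position p0 + i).
align_score <- function(states, intr, p0, T_intr) {
  mean(vapply(seq_len(nrow(states)), function(i) {
    as.numeric(pearson(states[i, ],
                       intr[((p0 - 1 + i - 1) %% T_intr) + 1L, ]))
  }, numeric(1)))
}

# Classify a retrieval trajectory as correct / shifted / spurious: after a
# transient, the CA3 states must ride the intrinsic sequence at the cue's
# own positions (correct), at a wrong offset (shifted), or nowhere
# (spurious).
classify_relaxation <- function(states, intr, expected_pos, T_intr,
                                transient = 5, crit = 0.9) {
  n_states <- nrow(states)
  skip <- min(transient, n_states - 1L)
  tail_states <- states[(skip + 1L):n_states, , drop = FALSE]
  if (!is.null(expected_pos)) {
    p0 <- ((expected_pos - 1 + skip) %% T_intr) + 1L
    if (align_score(tail_states, intr, p0, T_intr) >= crit)
      return("correct")
  }
  scores <- vapply(seq_len(T_intr), function(p)
    align_score(tail_states, intr, p, T_intr), numeric(1))
  if (max(scores) >= crit) "shifted" else "spurious"
}

#' Cued retrieval of a stored sequence
#'
#' Retrieval proceeds in two phases. The cue is first propagated through the
#' encoding path (SI ->) EC -> DG -> CA3 while the intrinsic dynamics is
#' suppressed, triggering a CA3 state. The DG -> CA3 pathway is then
#' suppressed in turn and the recurrent CA3 dynamics reactivates the
#' intrinsic sequence from that state; each successive CA3 state is decoded
#' back to EC (and to SI if a sensory codec is attached). After the cue, the
#' plastic encoder plays no role: states evolve purely under the recurrent
#' pathway.
#'
#' @param model A stored [build_hippocampus()] model.
#' @param cue_ec Binary EC cue (possibly corrupted or novel).
#' @param n_transitions Number of intrinsic transitions after the cue.
#' @param cue_position Optional 1-based position of the cue in the stored
#'   sequence; enables ground-truth correlations and the
#'   correct/shifted/spurious relaxation classification (without it only
#'   shifted/spurious can be distinguished).
#' @param transient Transient length discarded before classifying
#'   (default 5 steps).
#' @return An object of class `recall_result`: retrieved CA3/EC (and SI)
#'   states, per-step correlations against ground truth where available,
#'   and the `relaxation` label.
#' @export
retrieve <- function(model, cue_ec, n_transitions = 0, cue_position = NULL,
                     transient = 5) {
  if (model$clock == 0L)
    stop("retrieve: model has not stored any pattern", call. = FALSE)
  stopifnot(n_transitions >= 0)
  intr <- as.matrix(model$intrinsic)
  T_intr <- length(model$intrinsic)
  n_steps <- n_transitions + 1L
  ca3 <- matrix(0, n_steps, model$config$n_ca3)
  ca3[1L, ] <- encode_cue(model, cue_ec)
  if (n_transitions > 0) {
    for (i in 2:n_steps)
      ca3[i, ] <- ca3_transition(model$ca3_recurrent, ca3[i - 1L, ])
  }
  ec <- binarize(activate(model$dec_plastic, ca3))
  si <- if (!is.null(model$sensory)) sensory_decode(model$sensory, ec)
  corr_ca3 <- rep(NA_real_, n_steps)
  corr_ec <- rep(NA_real_, n_steps)
  expected_pos <- NULL
  if (!is.null(cue_position)) {
    stopifnot(cue_position >= 1, cue_position <= model$clock)
    expected_pos <- model$stored$positions[cue_position]
    T_s <- model$clock
    for (i in seq_len(n_steps)) {
      p <- ((expected_pos - 1 + i - 1) %% T_intr) + 1L
      corr_ca3[i] <- as.numeric(pearson(ca3[i, ], intr[p, ]))
      s_idx <- cue_position + i - 1L
      if (T_s == T_intr) s_idx <- ((s_idx - 1L) %% T_s) + 1L
      if (s_idx <= T_s)
        corr_ec[i] <- as.numeric(pearson(ec[i, ], model$stored$ec[s_idx, ]))
    }
  }
  structure(list(
    cue_position = cue_position,
    retrieved_ca3 = ca3, retrieved_ec = ec, retrieved_si = si,
    per_step_corr_ca3 = corr_ca3, per_step_corr_ec = corr_ec,
    relaxation = classify_relaxation(ca3, intr, expected_pos, T_intr,
                                     transient = transient)
  ), class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("<recall_result> %d states, relaxation: %s\n",
              nrow(x$retrieved_ca3), x$relaxation))
  if (!all(is.na(x$per_step_corr_ec)))
    cat(sprintf("  EC correlation: first %.3f, last %.3f\n",
                x$per_step_corr_ec[1L],
                x$per_step_corr_ec[length(x$per_step_corr_ec)]))
  invisible(x)
}

#' Per-pattern recall correlation under intrinsic transitions
#'
#' For every stored position `t` independently: encode the ground-truth EC
#' pattern into CA3, run a fixed number of intrinsic transitions (0 for
#' direct encode-decode, `k`, or the full cycle of `T_intr` transitions
#' which arrives back at `t`), decode the final CA3 state, and report its
#' correlation against the ground-truth EC pattern at the arrival position.
#'
#' @param model A stored model.
#' @param mode `"direct"` (0 transitions), `"k_transitions"`, or
#'   `"full_cycle"`.
#' @param k Number of transitions for `mode = "k_transitions"`
#'   (non-negative).
#' @return A [correlation_curve()] over stored positions, with the
#'   mean-pattern baseline.
#' @export
full_intrinsic_recall <- function(model,
                                  mode = c("direct", "k_transitions",
                                           "full_cycle"),
                                  k = 0) {
  mode <- match.arg(mode)
  if (model$clock == 0L)
    stop("full_intrinsic_recall: nothing stored", call. = FALSE)
  if (k < 0) stop("full_intrinsic_recall: k must be >= 0", call. = FALSE)
  T_intr <- length(model$intrinsic)
  k <- switch(mode, direct = 0L, k_transitions = as.integer(k),
              full_cycle = T_intr)
  T_s <- model$clock
  gt <- model$stored$ec
  values <- rep(NA_real_, T_s)
  retrieved <- matrix(NA_real_, T_s, model$config$n_ec)
  for (t in seq_len(T_s)) {
    state <- encode_cue(model, gt[t, ])
    i <- 0L
    while (i < k) {
      state <- ca3_transition(model$ca3_recurrent, state)
      i <- i + 1L
    }
    arrival <- t + k
    if (T_s == T_intr) arrival <- ((arrival - 1L) %% T_s) + 1L
    if (arrival > T_s) next  # no ground truth beyond the stored range
    ec <- decode_ca3(model, state)
    retrieved[t, ] <- ec
    values[t] <- as.numeric(pearson(ec, gt[arrival, ]))
  }
  keep <- !is.na(values)
  correlation_curve(which(keep), values[keep],
                    baseline_curve(retrieved[keep, , drop = FALSE], gt))
}

#' Offline replay: self-improvement without external input
#'
#' Runs the model with no external input: looping over the stored part of
#' the intrinsic sequence (in sequential order, `n_loops` times), each
#' intrinsic CA3 pattern is decoded to a reconstructed EC pattern through
#' the decoder, and the direct EC -> CA3 encoder is then strengthened by
#' hetero-associating that reconstruction with the intrinsic pattern. The
#' decoder is not updated. Requires a model whose encoder maps EC directly
#' to CA3 (DG ablated); replay exists precisely to let that weaker direct
#' pathway catch up on correlated data.
#'
#' @param model A stored model without DG (see [ablate_dg()]).
#' @param n_loops Number of passes over the stored sequence (default 10).
#' @param eta Learning rate (default 20/N).
#' @param seed Unused source of randomness reserved for graded variants;
#'   replay itself is deterministic.
#' @return The updated model.
#' @export
replay <- function(model, n_loops = 10, eta = NULL, seed = 1) {
  if (!is.null(model$dg))
    stop("replay: requires the direct EC -> CA3 encoder (ablate DG first)",
         call. = FALSE)
  if (model$clock == 0L)
    stop("replay: nothing stored", call. = FALSE)
  if (n_loops == 0) return(model)
  if (is.null(eta)) eta <- default_learning_rate(model$config$n_ec)
  intr <- as.matrix(model$intrinsic)
  positions <- model$stored$positions
  us <- update_state(model$enc_plastic, eta = eta)
  for (loop in seq_len(n_loops)) {
    for (t in seq_along(positions)) {
      x_ca3 <- intr[positions[t], ]
      ec_recon <- decode_ca3(model, x_ca3)
      st <- hetero_step(model$enc_plastic, us, ec_recon, x_ca3)
      model$enc_plastic <- st$assoc
      us <- st$us
    }
  }
  model
}

#' Remove DG from the encoding path
#'
#' Returns a model whose plastic encoder maps EC to CA3 directly, with
#' fresh zero weights and input offsets equal to the EC activity; the
#' intrinsic sequence, recurrent pathway, decoder and sensory codec are
#' shared with the original. Used to probe how much pattern separation
#' contributes: without DG the encoder must hetero-associate raw
#' (possibly correlated) EC patterns.
#'
#' @param model A model built with DG.
#' @return A model with `use_dg = FALSE` and nothing stored yet.
#' @export
ablate_dg <- function(model) {
  if (is.null(model$dg))
    stop("ablate_dg: model has no DG", call. = FALSE)
  model$dg <- NULL
  model$enc_plastic <- centered_associator(
    model$config$n_ec, model$config$n_ca3,
    mu = model$config$ec_activity, mode = "hetero",
    act_fwd = activation_spec(model$config$plastic_act))
  model$config$use_dg <- FALSE
  model$stored <- NULL
  model$clock <- 0L
  model
}

#' Save / load a model bundle
#'
#' Writes the model as an RDS archive with a JSON sidecar
#' (`<path>.json`) holding the configuration and pre-training report for
#' human inspection.
#'
#' @param model A [build_hippocampus()] model.
#' @param path Output path for the RDS bundle.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(config = model$config,
                  clock = model$clock,
                  self_consistency = model$pretrain_report$self_consistency)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "hippocampus_model"))
  model
}
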
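# Reproducible experiment driver: validated configuration, seeded runs,
# bundle/report output. The functions here are what the command-line wrapper
# (inst/cli/hipposeq) calls.

#' Experiment configuration
#'
#' Validated container for everything a run needs: sizes, activity levels,
#' dataset choice, noise level, learning rate and four independent seed
#' streams (data / pretrain / storage / retrieval) so that each phase is
#' independently reproducible.
#'
#' @param n_ec EC size N.
#' @param n_ca3_factor,n_dg_factor Subregion size ratios (defaults 2.3 and
#'   10.9).
#' @param ec_activity,dg_activity,ca3_activity Activity levels (defaults
#'   0.35 / 0.03 / 0.25).
#' @param dataset One of `"rand"`, `"rand_corr"`, `"images"`, `"mnist"`.
#' @param T_len Stored sequence length (default `n_ec`).
#' @param T_intr Intrinsic sequence length (default `n_ec`).
#' @param noise_pct Cue noise level for retrieval (default 0).
#' @param eta_oneshot One-shot learning rate, or `"auto"` for 20/N.
#' @param seeds Named list with integer entries `data`, `pretrain`,
#'   `storage`, `retrieval`.
#' @param ablate_dg Drop DG from the encoding path.
#' @param replay_loops Number of replay passes after storage (0 = none).
#' @param recall_transitions Transition counts evaluated during recall
#'   (`0` = direct; `-1` codes for a full cycle).
#' @param mnist_images,mnist_labels IDX file paths (dataset `"mnist"`).
#' @param image_hw Height/width of synthetic images (dataset `"images"`).
#' @return A validated object of class `experiment_config`.
#' @export
experiment_config <- function(n_ec = 200, n_ca3_factor = 2.3,
                              n_dg_factor = 10.9, ec_activity = 0.35,
                              dg_activity = 0.03, ca3_activity = 0.25,
                              dataset = c("rand", "rand_corr", "images",
                                          "mnist"),
                              T_len = n_ec, T_intr = n_ec, noise_pct = 0,
                              eta_oneshot = "auto",
                              seeds = list(data = 1L, pretrain = 2L,
                                           storage = 3L, retrieval = 4L),
                              ablate_dg = FALSE, replay_loops = 0,
                              recall_transitions = c(0, -1),
                              mnist_images = NULL, mnist_labels = NULL,
                              image_hw = 16) {
  dataset <- match.arg(dataset)
  acts <- c(ec_activity, dg_activity, ca3_activity)
  if (any(acts <= 0) || any(acts >= 1))
    stop("experiment_config: activities must lie in (0,1)", call. = FALSE)
  if (n_ec < 1 || T_len < 1 || T_intr < 1 ||
      round(n_ca3_factor * n_ec) < 1 ||
      (!ablate_dg && round(n_dg_factor * n_ec) < 1))
    stop("experiment_config: all layer sizes must round to >= 1",
         call. = FALSE)
  if (!identical(eta_oneshot, "auto") &&
      (!is.numeric(eta_oneshot) || eta_oneshot <= 0))
    stop("experiment_config: eta_oneshot must be positive or \"auto\"",
         call. = FALSE)
  need <- c("data", "pretrain", "storage", "retrieval")
  if (!all(need %in% names(seeds)))
    stop("experiment_config: seeds must name data/pretrain/storage/retrieval",
         call. = FALSE)
  if (dataset == "mnist" && is.null(mnist_images))
    stop("experiment_config: dataset \"mnist\" needs mnist_images",
         call. = FALSE)
  structure(list(
    n_ec = n_ec, n_ca3_factor = n_ca3_factor, n_dg_factor = n_dg_factor,
    ec_activity = ec_activity, dg_activity = dg_activity,
    ca3_activity = ca3_activity, dataset = dataset, T_len = T_len,
    T_intr = T_intr, noise_pct = noise_pct, eta_oneshot = eta_oneshot,
    seeds = lapply(seeds[need], as.integer), ablate_dg = ablate_dg,
    replay_loops = replay_loops, recall_transitions = recall_transitions,
    mnist_images = mnist_images, mnist_labels = mnist_labels,
    image_hw = image_hw
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> N=%d, dataset=%s, T=%d, DG %s, replay=%d\n",
              x$n_ec, x$dataset, x$T_len,
              if (x$ablate_dg) "ablated" else "on", x$replay_loops))
  invisible(x)
}

#' Read an experiment configuration from a JSON file
#'
#' Fields not present fall back to the [experiment_config()] defaults; the
#' result is validated before anything is computed.
#'
#' @param path Path to a JSON file of configuration fields.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$seeds)) raw$seeds <- as.list(raw$seeds)
  do.call(experiment_config, raw)
}

config_hash <- function(config) {
  # Stable short fingerprint of the full configuration for run provenance.
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(json)) *
                        (seq_len(nchar(json)) %% 251 + 1)) %% .Machine$integer.max)
}

load_config_dataset <- function(config) {
  ds_seed <- config$seeds$data
  switch(config$dataset,
    rand = gen_rand(config$n_ec, config$T_len, config$ec_activity,
                    seed = ds_seed),
    rand_corr = gen_rand_corr(config$n_ec, config$T_len, config$ec_activity,
                              seed = ds_seed),
    images = ,
    mnist = {
      imgs <- if (config$dataset == "mnist") {
        load_mnist(config$mnist_images, config$mnist_labels)
      } else {
        gen_synthetic_images(config$T_len + 2000, config$image_hw,
                             config$image_hw, seed = ds_seed)
      }
      imgs
    })
}

#' Run the pre-training phase and save a model bundle
#'
#' Builds a model from a configuration (pre-training DG, CA3 and -- for
#' image datasets -- the sensory codec), writes the bundle to `out_path`
#' and a JSON report with the CA3 self-consistency and measured DG / EC
#' activities next to it.
#'
#' @param config An [experiment_config()].
#' @param out_path Path for the RDS bundle.
#' @return The report list, invisibly.
#' @export
run_pretrain <- function(config, out_path) {
  stopifnot(inherits(config, "experiment_config"))
  pre_seed <- config$seeds$pretrain
  sensory <- NULL
  if (config$dataset %in% c("images", "mnist")) {
    imgs <- load_config_dataset(config)
    d <- dim(imgs$images)
    train_idx <- seq_len(max(1L, d[1L] - config$T_len))
    train <- gray_image_set(imgs$images[train_idx, , , drop = FALSE])
    sensory <- pretrain_sensory(train, n_ec = config$n_ec,
                                ec_activity = config$ec_activity,
                                seed = child_seed(pre_seed, 31))
  }
  model <- build_hippocampus(
    n_ec = config$n_ec, n_ca3_factor = config$n_ca3_factor,
    n_dg_factor = config$n_dg_factor, ec_activity = config$ec_activity,
    dg_activity = config$dg_activity, ca3_activity = config$ca3_activity,
    T_intr = config$T_intr, use_dg = !config$ablate_dg, sensory = sensory,
    seed = pre_seed)
  save_model(model, out_path)
  report <- list(
    config_hash = config_hash(config),
    seeds = config$seeds,
    ca3_self_consistency = model$pretrain_report$self_consistency,
    dg_activity_measured = if (!is.null(model$dg)) {
      held <- as.matrix(gen_rand(config$n_ec, 200, config$ec_activity,
                                 seed = child_seed(pre_seed, 99)))
      mean(dg_encode(model$dg, held))
    },
    ec_activity_measured = if (!is.null(sensory)) {
      probe <- gen_synthetic_images(100, config$image_hw, config$image_hw,
                                    seed = child_seed(pre_seed, 98))
      mean(sensory_encode(sensory, probe))
    })
  jsonlite::write_json(report, paste0(out_path, ".report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run a storage / recall / replay experiment from a saved bundle
#'
#' Stores the configured sequence one-shot, evaluates recall at the
#' configured transition counts, optionally replays, and writes per-curve
#' CSV files, a JSON summary (mean correlations, capacity, relaxation
#' tallies, config hash and seeds) and a PNG figure per curve into
#' `out_dir`. Refuses to overwrite an existing non-empty `out_dir` unless
#' `force = TRUE`.
#'
#' @param config An [experiment_config()].
#' @param bundle_path Bundle written by [run_pretrain()].
#' @param out_dir Output directory.
#' @param force Overwrite existing outputs.
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(config, bundle_path, out_dir, force = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop(sprintf("run_experiment: %s exists and is not empty (use force)",
                 out_dir), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_model(bundle_path)
  ds <- load_config_dataset(config)
  ec_seq <- if (inherits(ds, "gray_image_set")) {
    d <- dim(ds$images)
    idx <- (d[1L] - config$T_len + 1L):d[1L]
    codes <- sensory_encode(model$sensory,
                            gray_image_set(ds$images[idx, , , drop = FALSE]))
    binary_sequence(codes, config$ec_activity, config$seeds$data)
  } else ds
  eta <- if (identical(config$eta_oneshot, "auto"))
    default_learning_rate(config$n_ec) else config$eta_oneshot
  model <- store_sequence(model, ec_seq, eta = eta,
                          seed = config$seeds$storage)
  if (config$replay_loops > 0)
    model <- replay(model, n_loops = config$replay_loops, eta = eta)

  summary <- list(config_hash = config_hash(config), seeds = config$seeds,
                  curves = list())
  for (k in config$recall_transitions) {
    curve <- if (k < 0) {
      full_intrinsic_recall(model, "full_cycle")
    } else if (k == 0) {
      full_intrinsic_recall(model, "direct")
    } else {
      full_intrinsic_recall(model, "k_transitions", k = k)
    }
    tag <- if (k < 0) "full_cycle" else paste0("k", k)
    utils::write.csv(as.data.frame(curve),
                     file.path(out_dir, paste0("curve_", tag, ".csv")),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, paste0("curve_", tag, ".png")),
                   width = 900, height = 500)
    plot(curve, main = paste("Recall,", tag))
    grDevices::dev.off()
    summary$curves[[tag]] <- list(
      mean = mean(curve$values),
      capacity = estimate_capacity(curve),
      trend_slope = unname(curve$trend[["slope"]]))
  }
  # Relaxation statistics from noisy cues at a spread of stored positions.
  probe_pos <- unique(round(seq(1, config$T_len, length.out = 10)))
  results <- lapply(seq_along(probe_pos), function(i) {
    cue <- as.matrix(ec_seq)[probe_pos[i], ]
    if (config$noise_pct > 0)
      cue <- add_binary_noise(cue, config$noise_pct,
                              seed = child_seed(config$seeds$retrieval, i))
    retrieve(model, cue, n_transitions = 15, cue_position = probe_pos[i])
  })
  summary$relaxation <- as.list(relaxation_stats(results))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line <- sprintf("[%s] run %s: dataset=%s N=%d T=%d dg=%s replay=%d",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      summary$config_hash, config$dataset, config$n_ec,
                      config$T_len, !config$ablate_dg, config$replay_loops)
  writeLines(log_line, file.path(out_dir, "run.log"))
  invisible(summary)
}
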
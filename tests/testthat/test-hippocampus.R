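# Model assembly, one-shot storage, cued retrieval, replay, DG ablation.

test_that("model assembly respects the anatomical size chain", {
  ms <- small_stored_model()
  m <- ms$model
  expect_equal(m$config$n_ca3, 230)
  expect_equal(m$config$n_dg, 1090)
  expect_equal(dim(m$enc_plastic$W), c(1090, 230))
  expect_equal(dim(m$dec_plastic$W), c(230, 100))
  expect_equal(length(m$intrinsic), 100)
})

test_that("storing an empty sequence leaves the model unchanged", {
  m <- build_hippocampus(40, use_dg = FALSE, pretrain_recurrent = FALSE,
                         seed = 1)
  m2 <- store_sequence(m, matrix(0, 0, 40))
  expect_identical(m2, m)
})

test_that("sequences longer than the intrinsic cycle are rejected", {
  m <- build_hippocampus(40, T_intr = 10, use_dg = FALSE,
                         pretrain_recurrent = FALSE, seed = 1)
  expect_error(store_sequence(m, gen_rand(40, 11, 0.35, seed = 1)),
               "capacity")
})

test_that("a single stored pair is retrieved with near-perfect correlation", {
  m <- build_hippocampus(200, use_dg = FALSE, T_intr = 10,
                         pretrain_recurrent = FALSE, seed = 4)
  s <- gen_rand(200, 1, 0.35, seed = 8)
  m <- store_sequence(m, s, seed = 9)
  r <- retrieve(m, as.matrix(s)[1, ], n_transitions = 0, cue_position = 1)
  expect_gte(r$per_step_corr_ec[1], 0.99)
})

test_that("retrieval is deterministic and post-cue states follow the recurrent dynamics only", {
  ms <- small_stored_model()
  cue <- as.matrix(ms$seq)[80, ]
  r1 <- retrieve(ms$model, cue, n_transitions = 8, cue_position = 80)
  r2 <- retrieve(ms$model, cue, n_transitions = 8, cue_position = 80)
  expect_identical(r1, r2)

  # the trajectory after step 0 is exactly the recurrent iteration: the
  # plastic encoder influences only the cue step
  st <- r1$retrieved_ca3[1, ]
  for (i in 2:9) {
    st <- ca3_transition(ms$model$ca3_recurrent, st)
    expect_identical(r1$retrieved_ca3[i, ], st)
  }
})

test_that("storage associates the clean intrinsic states regardless of encoder weights", {
  # theta-phase suppression: the DG -> CA3 input must not influence which
  # CA3 pattern gets associated, so corrupting the encoder beforehand
  # changes nothing about the stored decoder
  m <- build_hippocampus(50, use_dg = FALSE, T_intr = 20,
                         pretrain_recurrent = FALSE, seed = 3)
  m_perturbed <- m
  m_perturbed$enc_plastic$W <- m$enc_plastic$W + 5
  s <- gen_rand(50, 10, 0.36, seed = 5)
  a <- store_sequence(m, s, seed = 7)
  b <- store_sequence(m_perturbed, s, seed = 7)
  expect_identical(a$dec_plastic, b$dec_plastic)
  expect_identical(a$stored$positions, b$stored$positions)
})

test_that("cyclic index bookkeeping wraps exactly", {
  # storage positions continue around the cycle regardless of start
  m <- build_hippocampus(40, T_intr = 12, use_dg = FALSE,
                         pretrain_recurrent = FALSE, seed = 1)
  s <- gen_rand(40, 12, 0.35, seed = 2)
  m <- store_sequence(m, s, seed = 3)
  pos <- m$stored$positions
  expect_equal(sort(pos), 1:12) # every intrinsic position used exactly once
  expect_equal(pos[-1], (pos[-12] %% 12) + 1)

  # retrieval ground-truth comparison wraps with the same arithmetic
  r <- retrieve(m, as.matrix(s)[10, ], n_transitions = 6, cue_position = 10)
  intr <- as.matrix(m$intrinsic)
  for (i in 1:7) {
    p <- ((pos[10] - 1 + i - 1) %% 12) + 1
    expect_equal(r$per_step_corr_ca3[i],
                 as.numeric(pearson(r$retrieved_ca3[i, ], intr[p, ])))
    s_idx <- ((10 + i - 2) %% 12) + 1
    expect_equal(r$per_step_corr_ec[i],
                 as.numeric(pearson(r$retrieved_ec[i, ], as.matrix(s)[s_idx, ])))
  }

  # a full cycle of transitions arrives back at the cue's own position
  cv <- full_intrinsic_recall(m, "full_cycle")
  expect_equal(cv$positions, 1:12)
})

test_that("forgetting is graded: recent patterns recall better than old ones", {
  m <- build_hippocampus(100, T_intr = 200, pretrain_recurrent = FALSE,
                         seed = 5)
  s <- gen_rand_corr(100, 200, 0.35, 0.1, seed = 15)
  m <- store_sequence(m, s, seed = 25)
  cv <- full_intrinsic_recall(m, "direct")
  expect_gt(spearman(cv$positions, cv$values), 0)
  expect_gt(cv$trend[["slope"]], 0)
  # most recent clearly beats the oldest
  expect_gt(mean(tail(cv$values, 20)), mean(head(cv$values, 20)))
})

test_that("DG ablation rewires the encoder to EC and hurts correlated sequences", {
  ms <- small_stored_model()
  ab <- ablate_dg(ms$model)
  expect_null(ab$dg)
  expect_equal(nrow(ab$enc_plastic$W), 100)
  expect_equal(ab$clock, 0L)
  expect_error(ablate_dg(ab), "no DG")

  s <- ms$seq
  ab <- store_sequence(ab, s, seed = 31)
  intr <- as.matrix(ab$intrinsic)
  enc_corr <- function(model) {
    gt <- as.matrix(s)
    mean(vapply(seq_len(nrow(gt)), function(t) {
      as.numeric(pearson(hipposeq:::encode_cue(model, gt[t, ]),
                         intr[model$stored$positions[t], ]))
    }, numeric(1)))
  }
  # encoding through DG dominates direct EC -> CA3 on correlated patterns
  expect_gt(enc_corr(ms$model), enc_corr(ab) + 0.1)
})

test_that("without DG, uncorrelated sequences survive the full cycle but correlated ones sit at baseline", {
  run <- function(gen_seed, correlated) {
    m <- build_hippocampus(100, use_dg = FALSE, T_intr = 100, seed = 6)
    s <- if (correlated) gen_rand_corr(100, 100, 0.35, 0.1, seed = gen_seed)
         else gen_rand(100, 100, 0.35, seed = gen_seed)
    m <- store_sequence(m, s, seed = gen_seed + 1)
    cv <- full_intrinsic_recall(m, "full_cycle")
    c(mean(cv$values), mean(abs(cv$baseline)))
  }
  rand <- run(61, correlated = FALSE)
  corr <- run(62, correlated = TRUE)
  expect_gt(rand[1], rand[2] + 0.3)   # far above baseline
  expect_lt(corr[1], 0.35)            # near baseline for correlated input
  expect_gt(rand[1], corr[1])
})

test_that("replay improves recall without external input and leaves the decoder untouched", {
  m <- build_hippocampus(100, use_dg = FALSE, T_intr = 100, seed = 7)
  s <- gen_rand_corr(100, 100, 0.35, 0.1, seed = 71)
  m <- store_sequence(m, s, seed = 72)

  expect_identical(replay(m, n_loops = 0), m)

  # averaged over 5 seeds, recall is non-decreasing over replay loops 0->10
  curves <- vapply(1:5, function(sd0) {
    mi <- build_hippocampus(100, use_dg = FALSE, T_intr = 100, seed = sd0)
    si <- gen_rand_corr(100, 100, 0.35, 0.1, seed = 70 + sd0)
    mi <- store_sequence(mi, si, seed = 80 + sd0)
    out <- numeric(3)
    out[1] <- mean(full_intrinsic_recall(mi, "full_cycle")$values)
    for (i in 2:3) {
      mi <- replay(mi, n_loops = 5)
      out[i] <- mean(full_intrinsic_recall(mi, "full_cycle")$values)
    }
    out
  }, numeric(3))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > -0.01))  # non-decreasing on average
  expect_gt(avg[3], avg[1] + 0.1)      # and clearly better after 10 loops

  # the decoder itself is never updated by replay
  m2 <- replay(m, n_loops = 2)
  expect_identical(m2$dec_plastic, m$dec_plastic)

  expect_error(replay(small_stored_model()$model), "ablate DG")
})

test_that("relaxation outcomes: exact late cues are correct, garbage cues spurious", {
  ms <- small_stored_model()
  s <- as.matrix(ms$seq)
  late <- lapply(c(85, 90, 95), function(p)
    retrieve(ms$model, s[p, ], n_transitions = 15, cue_position = p))
  tally <- relaxation_stats(late)
  expect_gte(tally[["correct"]], 2)

  garbage <- lapply(1:3, function(i)
    retrieve(ms$model, as.matrix(gen_rand(100, 1, 0.35, seed = 900 + i))[1, ],
             n_transitions = 15))
  expect_gte(relaxation_stats(garbage)[["spurious"]], 2)

  # an all-zero cue is a legitimate failure input, not an error
  r0 <- retrieve(ms$model, numeric(100), n_transitions = 5)
  expect_true(r0$relaxation %in% c("shifted", "spurious"))
})

test_that("model bundles round-trip through disk with a JSON sidecar", {
  ms <- small_stored_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(ms$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$dec_plastic$W, ms$model$dec_plastic$W)
  expect_identical(back$config, ms$model$config)
})
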
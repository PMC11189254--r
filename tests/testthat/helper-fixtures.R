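# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Small full model (N = 100, with DG, trained recurrent dynamics) with a
# stored RAND-CORR sequence; reused by retrieval / relaxation tests.
small_stored_model <- function() {
  cached("small_stored", function() {
    m <- build_hippocampus(100, T_intr = 100, seed = 2)
    s <- gen_rand_corr(100, 100, 0.35, 0.1, seed = 21)
    list(model = store_sequence(m, s, seed = 31), seq = s)
  })
}

# Pre-trained DG at the reference size N = 200 (a few seconds; shared by
# pattern-separation tests).
dg200 <- function() cached("dg200", function() pretrain_dg(200, seed = 7))

# Sensory codec at the reference scale (2000 synthetic 16x16 images,
# n_ec = 200), with held-out images and the untrained (epochs = 0) control.
sensory200 <- function() {
  cached("sensory200", function() {
    imgs <- gen_synthetic_images(2200, 16, 16, seed = 9)
    train <- gray_image_set(imgs$images[1:2000, , ])
    held <- gray_image_set(imgs$images[2001:2200, , ])
    list(train = train, held = held,
         trained = pretrain_sensory(train, n_ec = 200, seed = 11),
         untrained = pretrain_sensory(train, n_ec = 200, epochs = 0,
                                      seed = 11))
  })
}

# Brute-force O(T^2) doppelganger profile used as an oracle.
max_corr_bruteforce <- function(m) {
  T_len <- nrow(m)
  out <- numeric(T_len)
  for (t in seq_len(T_len)) {
    best <- -Inf
    for (s in seq_len(T_len)) {
      if (s == t) next
      best <- max(best, as.numeric(pearson(m[t, ], m[s, ])))
    }
    out[t] <- best
  }
  out
}

spearman <- function(a, b) stats::cor(a, b, method = "spearman")
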
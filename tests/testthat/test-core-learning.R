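# Centered neuron layers and the Hebbian descent updates.

test_that("activation follows the centered neuron equation", {
  # zero weights and bias: sigmoid gives 0.5, step ties break to inactive
  a0 <- centered_associator(3, 2, mu = 0.5)
  expect_equal(activate(a0, c(1, 0, 1)), c(0.5, 0.5))
  a0s <- centered_associator(3, 2, mu = 0.5,
                             act_fwd = activation_spec("step"))
  expect_equal(activate(a0s, c(1, 0, 1)), c(0, 0))

  # hand evaluation: a = 0.5*2 + (-0.5)*(-2) + 0.5 = 2.5
  a <- centered_associator(2, 1, mu = c(0.5, 0.5))
  a$W <- matrix(c(2, -2), 2, 1)
  a$b <- 0.5
  expect_equal(activate(a, c(1, 0)), plogis(2.5))

  expect_error(activate(a, c(1, 0, 0)), "dim")
  expect_error(activate(a, c(1, NA)), "finite")
})

test_that("reconstruction uses the tied transposed weights", {
  a <- centered_associator(2, 3, mu = 0.5, mode = "auto", lam = 0.4)
  expect_equal(reconstruct(a, c(0.1, 0.9, 0.5)), c(0.5, 0.5))
  # h equal to lam everywhere: centered hidden input vanishes
  expect_equal(reconstruct(a, rep(0.4, 3)), c(0.5, 0.5))

  # hand case: z_i = sigmoid(sum_j (h_j - lam_j) w_ij + c_i)
  a$W <- matrix(1:6 / 10, 2, 3)
  a$c <- c(0.2, -0.1)
  h <- c(0.9, 0.1, 0.6)
  z_hand <- plogis(drop(a$W %*% (h - 0.4)) + a$c)
  expect_equal(reconstruct(a, h), z_hand)

  het <- centered_associator(2, 3, mu = 0.5, mode = "hetero")
  expect_error(reconstruct(het, c(1, 0, 0)), "auto-associative")
})

test_that("hetero step matches the hand-derived update", {
  # single pair, 1x1: x=1, mu=0.25, t=1, eta=0.1 -> dw = 0.0375, db = 0.05
  a <- centered_associator(1, 1, mu = 0.25)
  us <- update_state(a, eta = 0.1)
  st <- hetero_step(a, us, 1, 1)
  expect_equal(st$assoc$W[1, 1], 0.0375)
  expect_equal(st$assoc$b, 0.05)

  expect_error(hetero_step(a, us, 1, 2), "targets")
})

test_that("already-correct pairs are an exact fixed point", {
  set.seed(2)
  a <- centered_associator(4, 3, mu = 0.5)
  a$W <- matrix(rnorm(12), 4, 3)
  a$b <- rnorm(3)
  X <- matrix(rbinom(8, 1, 0.5), 2, 4)
  Tg <- activate(a, X) # targets equal to current outputs
  st <- hetero_step(a, update_state(a, eta = 5), X, Tg)
  expect_identical(st$assoc$W, a$W)
  expect_identical(st$assoc$b, a$b)
})

test_that("inputs at the offset update the bias but not the weights", {
  a <- centered_associator(3, 2, mu = 0.4)
  X <- matrix(0.4, 1, 3)
  st <- hetero_step(a, update_state(a, eta = 1), X, matrix(c(1, 0), 1, 2))
  expect_equal(st$assoc$W, matrix(0, 3, 2))
  expect_false(all(st$assoc$b == 0))
})

test_that("centering with the empirical mean gives mean-free inputs", {
  set.seed(5)
  X <- matrix(rbinom(200, 1, 0.3), 20, 10)
  mu <- colMeans(X)
  expect_lt(max(abs(colMeans(sweep(X, 2, mu)))), 1e-12)
})

test_that("auto step matches the tied-weight equations by hand", {
  a <- centered_associator(2, 2, mu = 0.5, mode = "auto",
                           lam = 0.3, lam_tilde = 0.3)
  a$W <- matrix(c(0.5, -0.2, 0.1, 0.4), 2, 2)
  a$c <- c(0.1, -0.3)
  x <- c(1, 0)
  h <- plogis(drop((x - 0.5) %*% a$W))
  z <- plogis(drop(a$W %*% (h - 0.3)) + a$c)
  eta <- 0.5
  dW_hand <- -eta * outer(z - x, h - 0.3)
  dc_hand <- -eta * (z - x)
  db_hand <- -eta * (h - 0.3)
  st <- auto_step(a, update_state(a, eta = eta), x,
                  update_output_bias = TRUE)
  expect_equal(st$assoc$W, a$W + dW_hand)
  expect_equal(st$assoc$c, a$c + dc_hand)
  expect_equal(st$assoc$b, a$b + db_hand)

  # perfect reconstruction: no weight or visible-bias change
  a2 <- centered_associator(2, 2, mu = 0.5, mode = "auto", lam = 0.5)
  st2 <- auto_step(a2, update_state(a2, eta = 1), c(0.5, 0.5))
  expect_equal(st2$assoc$W, a2$W)
  expect_equal(st2$assoc$c, a2$c)

  expect_error(auto_step(centered_associator(2, 2, mode = "hetero"),
                         update_state(a2, eta = 1), c(1, 0)),
               "auto-associative")
})

test_that("tied weights are one shared matrix, not two", {
  a <- centered_associator(3, 2, mu = 0.5, mode = "auto", lam = 0.5,
                           init_sd = 0.1, init_seed = 4)
  st <- auto_step(a, update_state(a, eta = 2), c(1, 0, 1))
  # reconstruction after the update must reflect the updated forward W
  z_probe <- reconstruct(st$assoc, c(0.9, 0.2))
  z_manual <- plogis(drop(st$assoc$W %*% (c(0.9, 0.2) - 0.5)) + st$assoc$c)
  expect_equal(z_probe, z_manual)
})

test_that("momentum accumulates classically and off reproduces plain descent", {
  a <- centered_associator(3, 2, mu = 0.4)
  set.seed(1)
  X <- matrix(rbinom(6, 1, 0.5), 2, 3)
  Tg <- matrix(rbinom(4, 1, 0.5), 2, 2)

  plain1 <- hetero_step(a, update_state(a, eta = 0.3), X, Tg)
  zero_m <- hetero_step(a, update_state(a, eta = 0.3, momentum = 0), X, Tg)
  expect_identical(plain1$assoc$W, zero_m$assoc$W)
  expect_identical(plain1$assoc$b, zero_m$assoc$b)

  # second step with momentum: update = delta + momentum * previous
  us <- update_state(a, eta = 0.3, momentum = 0.9)
  s1 <- hetero_step(a, us, X, Tg)
  s2 <- hetero_step(s1$assoc, s1$us, X, Tg)
  H2 <- activate(s1$assoc, X)
  delta2 <- -(0.3 / 2) * crossprod(sweep(X, 2, a$mu), H2 - Tg)
  expect_equal(s2$assoc$W - s1$assoc$W, delta2 + 0.9 * s1$us$prev_dW)
})

test_that("one-shot storage of orthogonal one-hot codes is exact", {
  # Interference-free idealization: step error, no bias accumulation.
  for (n in c(8, 16, 32)) {
    set.seed(n)
    Tg <- matrix(rbinom(n * n, 1, 0.4) + 0, n, n)
    a <- centered_associator(n, n, mu = 1 / n,
                             act_fwd = activation_spec("step"))
    us <- update_state(a, eta = 1)
    for (k in seq_len(n)) {
      x <- numeric(n)
      x[k] <- 1
      st <- hetero_step(a, us, x, Tg[k, ], update_bias = FALSE)
      a <- st$assoc
      us <- st$us
    }
    for (k in seq_len(n)) {
      x <- numeric(n)
      x[k] <- 1
      expect_identical(binarize(activate(a, x)), Tg[k, ])
    }
  }
})

test_that("learning rate law and binarization behave as specified", {
  expect_equal(default_learning_rate(200), 0.1)
  expect_equal(default_learning_rate(20), 1)
  expect_equal(default_learning_rate(2000), 0.01)
  expect_error(default_learning_rate(0))

  expect_equal(binarize(c(0.5, 0.50001, 0.2)), c(0, 1, 0))
  expect_equal(binarize(numeric(4)), numeric(4))
  # sigmoid output above 0.5 iff membrane positive
  a_vals <- c(-2, -1e-9, 0, 1e-9, 3)
  expect_equal(binarize(plogis(a_vals)), (a_vals > 0) + 0)
})
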
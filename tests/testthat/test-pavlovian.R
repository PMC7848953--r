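test_that("trial traces have the prescribed windows and magnitudes", {
  tr <- make_trial(1, 1)  # strong reward
  expect_equal(tr$cue, c(rep(0, 5), rep(1, 5), rep(0, 10)))
  expect_equal(tr$reward, c(rep(0, 13), rep(1, 5), rep(0, 2)))
  expect_equal(tr$motivation, rep(1, 20))

  wp <- make_trial(-1, 0.5)  # weak punishment
  expect_equal(wp$cue[6:10], rep(-0.5, 5))
  expect_equal(wp$reward[14:18], rep(-0.5, 5))
  expect_equal(wp$motivation, rep(-1, 20))

  # zero-magnitude reward and punishment trials differ only in motivation
  zr <- make_trial(1, 0); zp <- make_trial(-1, 0)
  expect_identical(zr$cue, zp$cue)
  expect_identical(zr$reward, zp$reward)
  expect_false(identical(zr$motivation, zp$motivation))

  expect_equal(nrow(trial_types()), 6L)
})

test_that("v_star is the discounted reward sum and satisfies Bellman exactly", {
  gam <- 0.9
  tr <- make_trial(1, 1)
  v <- v_star(tr, gam)
  expect_equal(v_star(make_trial(1, 0), gam), rep(0, 20))
  expect_equal(v[18], 1)  # last reward step: no future, r = 1
  expect_equal(v[13], gam + gam^2 + gam^3 + gam^4 + gam^5)
  # Bellman identity at every step (v_21 := 0)
  for (t in 1:20) {
    vn <- if (t == 20) 0 else v[t + 1]
    expect_equal(v[t], tr$reward[t] + gam * vn, tolerance = 1e-14)
  }
})

test_that("the recurrent unroll matches a hand computation", {
  w_in <- matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2)
  w_rec <- matrix(c(0.4, -0.2, 0.1, 0.3), 2, 2)
  w_out <- matrix(c(1, -1), 1, 2)
  p <- structure(list(w_in = w_in, w_rec = w_rec, w_out = w_out),
                 class = "rnn")
  tr <- make_trial(1, 1)
  out <- rnn_forward(p, tr)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- c(0, 0)
  for (t in 1:3) {
    h <- sig(w_in %*% c(tr$cue[t], tr$motivation[t]) + w_rec %*% h)
    expect_equal(out$hidden[, t], as.numeric(h), tolerance = 1e-12)
    expect_equal(out$v[t], as.numeric(w_out %*% h), tolerance = 1e-12)
  }
  expect_true(all(out$hidden > 0 & out$hidden < 1))

  # all-zero weights: hidden pinned at 0.5, readout at 0
  pz <- structure(list(w_in = w_in * 0, w_rec = w_rec * 0, w_out = w_out * 0),
                  class = "rnn")
  oz <- rnn_forward(pz, tr)
  expect_equal(oz$hidden, matrix(0.5, 2, 20))
  expect_equal(oz$v, rep(0, 20))
})

test_that("training approaches the partially observable TD fixed point", {
  fit <- trained_rnn()
  # pre-cue steps of a block are observationally aliased, so the reachable
  # fixed point averages the block's trial types there; elsewhere v = v_star
  types <- trial_types()
  vs <- sapply(1:6, function(i)
    v_star(make_trial(types$valence[i], types$magnitude[i])))
  vfix <- vs
  for (blk in list(1:3, 4:6)) {
    for (t in 5:1) vfix[t, blk] <- 0.9 * mean(vfix[t + 1, blk])
  }
  floor_mse <- mean((vfix - vs)^2)
  mse <- rnn_value_mse(fit$params)
  expect_lt(mse, floor_mse + 0.05)
  # smoothed loss decreases over training
  ls <- fit$loss$mse
  expect_lt(mean(tail(ls, 5)), mean(head(ls, 5)))
  # frozen input weights are untouched by training
  set.seed(9001)
  p0 <- init_rnn()
  expect_identical(fit$params$w_in, p0$w_in)
})

test_that("motivation separates the zero-magnitude trials; a blinded control cannot", {
  fit <- trained_rnn()
  vz_r <- rnn_forward(fit$params, make_trial(1, 0))$v
  vz_p <- rnn_forward(fit$params, make_trial(-1, 0))$v
  # baseline reward expectation carries the block sign
  expect_gt(mean(vz_r[1:5]), 0)
  expect_lt(mean(vz_p[1:5]), 0)

  set.seed(9002)
  ctrl <- train_rnn(train_schedule(2000, 1e-2, 1e-3, gamma = 0.9),
                    motivation_input = "zero", loss_every = 1000L)
  cz_r <- rnn_forward(ctrl$params, make_trial(1, 0), "zero")$v
  cz_p <- rnn_forward(ctrl$params, make_trial(-1, 0), "zero")$v
  expect_identical(cz_r, cz_p)
})

test_that("divergent training raises an informative error", {
  set.seed(9003)
  expect_error(
    train_rnn(train_schedule(2000, 50, 50, gamma = 0.9), loss_every = 1e6),
    "diverged")
})

test_that("trial traces export with their reference values", {
  fit <- trained_rnn()
  df <- trial_trace(fit$params, "strong_reward")
  expect_named(df, c("step", "cue", "motivation", "reward", "v", "v_star"))
  expect_equal(nrow(df), 20L)
  expect_equal(df$v_star, v_star(make_trial(1, 1)))
  expect_error(trial_trace(fit$params, "mild_reward"))
})
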
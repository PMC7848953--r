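test_that("initialization is reproducible, bounded, and Xavier-scaled", {
  set.seed(101)
  p1 <- init_mlp(c(36, 100, 5), c("sigmoid", "linear"))
  set.seed(101)
  p2 <- init_mlp(c(36, 100, 5), c("sigmoid", "linear"))
  expect_identical(p1$W, p2$W)

  set.seed(102)
  pu <- init_mlp(c(10, 10), "linear", init = c(-1e-5, 1e-5))
  expect_true(all(abs(pu$W[[1]]) <= 1e-5))

  # empirical variance of Xavier draws vs 2 / (fan_in + fan_out)
  set.seed(103)
  vars <- replicate(10, {
    p <- init_mlp(c(36, 100), "sigmoid")
    var(as.numeric(p$W[[1]]))
  })
  expect_lt(abs(mean(vars) - 2 / 136) / (2 / 136), 0.2)

  expect_error(init_mlp(c(3), "linear"))
})

test_that("forward pass matches hand computation and activation definitions", {
  p <- init_mlp(c(2, 2, 1), c("sigmoid", "linear"), init = c(0, 0))
  p$W[[1]] <- matrix(c(1, -1, 0.5, 2), 2, 2)
  p$b[[1]] <- c(0.1, -0.2)
  p$W[[2]] <- matrix(c(3, -2), 1, 2)
  p$b[[2]] <- 0.5
  x <- c(0.3, -0.7)
  h <- 1 / (1 + exp(-(p$W[[1]] %*% x + p$b[[1]])))
  expect_equal(forward(p, x)$output, as.numeric(p$W[[2]] %*% h + p$b[[2]]),
               tolerance = 1e-12)

  # sigmoid(0) = 0.5 through zero weights
  pz <- init_mlp(c(4, 3, 2), c("sigmoid", "linear"), init = c(0, 0))
  out <- forward(pz, rnorm(4))
  expect_equal(out$activations[[2]], rep(0.5, 3))

  # leaky ReLU slope on the negative side
  pl <- init_mlp(c(1, 1), "leaky_relu", init = c(0, 0), alpha = 0.2)
  pl$W[[1]][1, 1] <- 1
  expect_equal(mlp_output(pl, -1), -0.2)
  expect_error(forward(pz, rnorm(5)))
})

test_that("td_error implements the Bellman mismatch", {
  expect_equal(td_error(1, 0.9, 2, 1), 1.8)
  expect_equal(td_error(0.7, 0.9, 2, 0.7 + 0.9 * 2), 0)
  expect_equal(td_error(5, 0.9, 0, 5), 0)  # terminal bootstrap
})

test_that("selected-output update matches finite differences; others untouched", {
  set.seed(104)
  p <- init_mlp(c(3, 4, 5), c("sigmoid", "linear"))
  x <- rnorm(3)
  k <- 2L
  before <- mlp_clone(p)
  update_selected(p, forward(p, x), k, delta = 1, lr = 1)
  # analytic gradient = parameter change at delta = lr = 1
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in sample(length(p$W[[l]]), 6)) {
      pp <- mlp_clone(before); pp$W[[l]][idx] <- pp$W[[l]][idx] + eps
      pm <- mlp_clone(before); pm$W[[l]][idx] <- pm$W[[l]][idx] - eps
      g_num <- (mlp_output(pp, x)[k] - mlp_output(pm, x)[k]) / (2 * eps)
      expect_equal(p$W[[l]][idx] - before$W[[l]][idx], g_num,
                   tolerance = 1e-6)
    }
  }
  # non-selected output rows identical
  expect_identical(p$W[[2]][-k, ], before$W[[2]][-k, ])
  expect_identical(p$b[[2]][-k], before$b[[2]][-k])

  # delta = 0 leaves everything unchanged
  p2 <- mlp_clone(before)
  update_selected(p2, forward(p2, x), k, delta = 0, lr = 0.1)
  expect_identical(p2$W, before$W)
})

test_that("a small update shrinks the TD error on a frozen transition", {
  set.seed(105)
  for (rep in 1:5) {
    p <- init_mlp(c(4, 6, 3), c("sigmoid", "linear"))
    x <- rnorm(4); x2 <- rnorm(4); r <- rnorm(1)
    k <- sample(3, 1)
    d0 <- td_error(r, 0.9, max(mlp_output(p, x2)), mlp_output(p, x)[k])
    update_selected(p, forward(p, x), k, d0, lr = 0.01)
    d1 <- td_error(r, 0.9, max(mlp_output(p, x2)), mlp_output(p, x)[k])
    expect_lt(abs(d1), abs(d0))
  }
})

test_that("a tabular-equivalent net converges to the analytic chain-MDP values", {
  # 3-state chain, move left/right, reward 1 on reaching the terminal state 3
  set.seed(106)
  p <- init_mlp(c(3, 2), "linear", init = c(0, 0))
  gam <- 0.9
  eye <- diag(3)
  for (it in 1:15000) {
    s <- sample(1:2, 1)
    cache <- forward(p, eye[s, ])
    a <- sample(1:2, 1)
    s2 <- if (a == 1) max(1, s - 1) else s + 1
    r <- as.numeric(s2 == 3)
    qnb <- if (s2 == 3) 0 else max(mlp_output(p, eye[s2, ]))
    update_selected(p, cache, a, td_error(r, gam, qnb, cache$output[a]), 0.05)
  }
  q1 <- mlp_output(p, eye[1, ]); q2 <- mlp_output(p, eye[2, ])
  expect_equal(q2[2], 1, tolerance = 1e-2)       # step into terminal
  expect_equal(q1[2], gam, tolerance = 1e-2)     # one step from it
  expect_equal(q1[1], gam^2, tolerance = 1e-2)   # bounce off the left wall
  expect_equal(q2[1], gam^2, tolerance = 1e-2)
})

test_that("action selection respects masks and policy definitions", {
  q <- c(0.1, 0.9, 0.3, 0.2)
  # epsilon = 0: always the available argmax
  expect_identical(
    unique(replicate(50, select_action(q, list(kind = "epsilon_greedy",
                                               epsilon = 0)))), 2L)
  expect_identical(
    unique(replicate(50, select_action(
      q, list(kind = "epsilon_greedy", epsilon = 0),
      c(TRUE, FALSE, TRUE, TRUE)))), 3L)

  # epsilon = 1: uniform over available (chi-squared sanity)
  set.seed(107)
  mask <- c(TRUE, FALSE, TRUE, TRUE)
  draws <- replicate(1e4, select_action(q, list(kind = "epsilon_greedy",
                                                epsilon = 1), mask))
  expect_true(all(draws %in% c(1L, 3L, 4L)))
  cs <- chisq.test(table(draws))
  expect_gt(cs$p.value, 1e-4)

  # large-beta softmax concentrates on the argmax
  set.seed(108)
  draws <- replicate(2000, select_action(q, list(kind = "softmax",
                                                 beta = 1e3)))
  expect_gt(mean(draws == 2L), 0.999)

  # masks always respected, over random masks and q-values
  set.seed(109)
  for (i in 1:200) {
    qq <- rnorm(5)
    m <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    if (!any(m)) m[sample(5, 1)] <- TRUE
    pol <- list(kind = sample(c("epsilon_greedy", "softmax"), 1),
                epsilon = runif(1), beta = runif(1, 0, 5))
    expect_true(m[select_action(qq, pol, m)])
  }
  expect_error(select_action(q, list(kind = "softmax", beta = 1),
                             rep(FALSE, 4)))
})

test_that("annealing is geometric between its endpoints", {
  expect_equal(anneal(3e-3, 3e-5, 0, 10), 3e-3)
  expect_equal(anneal(3e-3, 3e-5, 10, 10), 3e-5)
  expect_equal(anneal(3e-3, 3e-5, 5, 10), 3e-4)
})

test_that("network parameters round-trip through serialization", {
  set.seed(110)
  p <- init_mlp(c(4, 7, 3), c("leaky_relu", "linear"), alpha = 0.2,
                input_spec = list(mean = 0.5, sd = 2))
  path <- tempfile(fileext = ".json")
  write_mlp(p, path)
  q <- read_mlp(path)
  expect_equal(q$W, p$W, tolerance = 1e-15)
  expect_equal(q$b, p$b, tolerance = 1e-15)
  expect_identical(q$act, p$act)
  expect_equal(mlp_output(q, c(1, 2, 3, 4)), mlp_output(p, c(1, 2, 3, 4)))
})
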
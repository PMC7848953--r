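test_that("Delaunay road networks are planar, connected, and correct on a square", {
  # unit square: 4 sides plus one diagonal
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  tris <- motivrl:::delaunay_triangles(sq)
  edges <- unique(do.call(rbind, apply(tris, 1, function(tr)
    rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)])),
    simplify = FALSE)))
  expect_equal(nrow(edges), 5L)

  set.seed(301)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    w <- sample_world(n)
    expect_true(igraph::is_connected(w$graph))
    expect_lte(nrow(w$edges), 3 * n - 6)
    expect_true(all(w$lengths > 0))
    # shortest distances between adjacent cities equal the road lengths
    for (e in seq_len(nrow(w$edges)))
      expect_equal(w$dist[w$edges[e, 1], w$edges[e, 2]], w$lengths[e])
  }
})

test_that("shortest tours match exhaustive enumeration on small worlds", {
  set.seed(302)
  for (i in 1:6) {
    w <- sample_world(sample(6:8, 1))
    for (j in 1:4) {
      ts <- sample_test_sets(w, 1)[[1]]
      st <- shortest_tour(w, ts$start, ts$targets)
      expect_equal(st$length,
                   exhaustive_tour_length(w, ts$start, ts$targets),
                   tolerance = 1e-9)
      expect_equal(st$route[1], ts$start)
      # the tour is invariant under permutations of the target set
      st2 <- shortest_tour(w, ts$start, rev(ts$targets))
      expect_equal(st2$length, st$length)
      expect_identical(st2$route, st$route)
    }
  }
  # single target degenerates to the point-to-point shortest path
  set.seed(303)
  w <- sample_world(7)
  expect_equal(shortest_tour(w, 1, 5)$length, w$dist[1, 5])
})

test_that("environment steps pay 5 minus distance and terminate correctly", {
  set.seed(304)
  w <- sample_world(10)
  nb <- w$adj[[1]][1]
  d <- w$dist[1, nb]
  st <- transport_initial_state(1, targets = nb, n_cities = 10)
  s <- transport_step(w, st, nb)
  expect_equal(s$reward, 5 - d)
  expect_equal(s$state$mu[nb], 0)
  expect_true(s$done)  # last nonzero component cleared

  st2 <- transport_initial_state(1, targets = setdiff(1:10, c(1, nb))[1:3], 10)
  s2 <- transport_step(w, st2, nb)
  expect_equal(s2$reward, -d)
  expect_false(s2$done)
  far <- setdiff(1:10, c(1, w$adj[[1]]))[1]
  expect_error(transport_step(w, st, far))
})

test_that("total positive reward per episode is 5 per initial target", {
  set.seed(305)
  w <- sample_world(8)
  params <- init_mlp(c(16, 20, 8), "leaky_relu", alpha = 0.2)
  for (i in 1:5) {
    ts <- sample_test_sets(w, 1, m = 3)[[1]]
    ep <- motivrl:::transport_episode(w, params, ts$start, ts$targets,
                                      beta = 0.5, max_steps = 500)
    expect_true(ep$done)  # random-ish walk on a connected graph terminates
    # each of the 3 targets pays +5 exactly once: reward + distance == 5
    d_step <- w$dist[cbind(ep$route[-length(ep$route)], ep$route[-1])]
    expect_equal(sum(abs(ep$rewards + d_step - 5) < 1e-9), 3L)
    # episode return = 15 - traveled length
    expect_equal(sum(ep$rewards), 15 - ep$traveled, tolerance = 1e-9)
  }
})

test_that("training improves returns over an untrained network", {
  set.seed(306)
  w <- sample_world(10)
  untrained <- init_mlp(c(20, 200, 10), "leaky_relu", alpha = 0.2)
  trained <- train_transport(w, train_schedule(6000, 1e-2, 1e-4, gamma = 0.9))
  ts <- sample_test_sets(w, 40)
  seeds <- sample.int(1e6, 40)
  ret <- function(params) {
    r <- numeric(length(ts))
    for (i in seq_along(ts)) {
      set.seed(seeds[i])
      ep <- motivrl:::transport_episode(w, params, ts[[i]]$start,
                                        ts[[i]]$targets, beta = 10)
      r[i] <- sum(ep$rewards)
    }
    r
  }
  expect_gt(mean(ret(trained)), mean(ret(untrained)))
  # trained agent completes test episodes promptly
  ev <- evaluate_transport(w, trained, ts)
  expect_gt(mean(ev$pairs$done), 0.95)
  expect_true(all(ev$pairs$L >= ev$pairs$L_star - 1e-9))
})

test_that("an oracle-replaying policy scores as exactly optimal", {
  set.seed(307)
  w <- sample_world(9)
  ts <- sample_test_sets(w, 10)
  L <- numeric(10); Ls <- numeric(10)
  for (i in seq_along(ts)) {
    tour <- shortest_tour(w, ts[[i]]$start, ts[[i]]$targets)
    Ls[i] <- tour$length
    L[i] <- sum(w$dist[cbind(tour$route[-length(tour$route)],
                             tour$route[-1])])
  }
  expect_equal(L, Ls, tolerance = 1e-12)
})

test_that("worlds serialize and round-trip through JSON", {
  set.seed(308)
  w <- sample_world(7)
  path <- tempfile(fileext = ".json")
  write_world(w, path)
  w2 <- read_world(path)
  expect_equal(w2$coords, w$coords, tolerance = 1e-12)
  expect_equal(w2$dist, w$dist, tolerance = 1e-12)
})
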
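#' Delaunay triangulation of planar points
#'
#' Incremental Bowyer-Watson construction. Points must be in (near) general
#' position; exactly cocircular quadruples are resolved deterministically by
#' insertion order. Intended for the small city sets of the transport task.
#'
#' @param coords Numeric n x 2 matrix of point coordinates, n >= 3.
#' @return Integer matrix of triangles (rows of 3 vertex indices).
#' @keywords internal
delaunay_triangles <- function(coords) {
  n <- nrow(coords)
  stopifnot(n >= 3L)
  # super-triangle comfortably enclosing all points
  cx <- mean(range(coords[, 1L])); cy <- mean(range(coords[, 2L]))
  r <- max(1e-6, max(abs(coords[, 1L] - cx), abs(coords[, 2L] - cy))) * 20
  pts <- rbind(coords,
               c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  sup <- n + 1:3
  circum <- function(tri) {
    p <- pts[tri, , drop = FALSE]
    ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
    cx2 <- p[3, 1]; cy2 <- p[3, 2]
    d <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    if (abs(d) < 1e-14) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  tris <- list(sup)
  ccs <- list(circum(sup))
  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- vapply(ccs, function(cc) {
      (p[1L] - cc[1L])^2 + (p[2L] - cc[2L])^2 < cc[3L] * (1 - 1e-12)
    }, logical(1L))
    # boundary polygon of the cavity: edges of bad triangles not shared twice
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[!bad]
    ccs <- ccs[!bad]
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, ], ip)
      tris <- c(tris, list(tr))
      ccs <- c(ccs, list(circum(tr)))
    }
  }
  keep <- vapply(tris, function(tr) !any(tr %in% sup), logical(1L))
  out <- do.call(rbind, tris[keep])
  if (is.null(out) || nrow(out) == 0L) stop("degenerate point configuration")
  out
}

#' Sample a random transport world
#'
#' Draws city coordinates from the standard normal distribution, connects
#' them by the edges of their Delaunay triangulation (the road network),
#' assigns Euclidean edge lengths, and precomputes all-pairs shortest-path
#' distances on the road graph.
#'
#' @param n_cities Number of cities (default 10).
#' @param max_resample Resampling attempts on degenerate geometry.
#' @return A list of class `transport_world` with `coords`, `edges` (two-
#'   column index matrix), `lengths`, `adj` (adjacency list), `graph`
#'   (igraph object), and `dist` (all-pairs shortest distances).
#' @export
sample_world <- function(n_cities = 10L, max_resample = 20L) {
  stopifnot(n_cities >= 3L)
  for (try in seq_len(max_resample)) {
    coords <- cbind(rnorm(n_cities), rnorm(n_cities))
    tris <- tryCatch(delaunay_triangles(coords), error = function(e) NULL)
    if (is.null(tris)) next
    edges <- unique(do.call(rbind, apply(tris, 1L, function(tr) {
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }, simplify = FALSE)))
    w <- make_world(coords, edges)
    if (igraph::is_connected(w$graph)) return(w)
  }
  stop("could not sample a non-degenerate connected world")
}

#' Assemble a transport world from coordinates and an edge list
#'
#' @param coords n x 2 coordinate matrix.
#' @param edges Two-column matrix of undirected edges (vertex indices).
#' @return A `transport_world` (see [sample_world()]).
#' @export
make_world <- function(coords, edges) {
  lengths <- sqrt(rowSums((coords[edges[, 1L], , drop = FALSE] -
                             coords[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::make_graph(t(edges), n = nrow(coords), directed = FALSE)
  igraph::E(g)$weight <- lengths
  adj <- lapply(seq_len(nrow(coords)), function(i) {
    sort(unique(c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L])))
  })
  structure(list(coords = coords, edges = edges, lengths = lengths,
                 adj = adj, graph = g,
                 dist = igraph::distances(g, algorithm = "dijkstra")),
            class = "transport_world")
}

#' @export
print.transport_world <- function(x, ...) {
  cat("<transport_world> ", nrow(x$coords), " cities, ",
      nrow(x$edges), " roads\n", sep = "")
  invisible(x)
}

#' Shortest open tour through a set of target cities
#'
#' Minimizes, over all orderings of the targets, the chained shortest-path
#' distance start -> t1 -> ... -> tm (no return to the origin), and expands
#' the winning ordering into the full city-by-city route. Ties in length are
#' broken by lexicographic order of the expanded route.
#'
#' @param world A `transport_world`.
#' @param start Start city index.
#' @param targets Vector of distinct target city indices.
#' @return List with `length` and `route` (city sequence starting at
#'   `start`).
#' @export
shortest_tour <- function(world, start, targets) {
  targets <- unique(as.integer(targets))
  perms <- .permutations(targets)
  best_len <- Inf
  best_route <- NULL
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    len <- world$dist[start, ord[1L]]
    if (length(ord) > 1L)
      for (j in seq_len(length(ord) - 1L))
        len <- len + world$dist[ord[j], ord[j + 1L]]
    if (len > best_len + 1e-12) next
    route <- start
    from <- start
    for (tgt in ord) {
      sp <- igraph::shortest_paths(world$graph, from, tgt,
                                   algorithm = "dijkstra")$vpath[[1L]]
      route <- c(route, as.integer(sp[-1L]))
      from <- tgt
    }
    if (is.null(best_route) || len < best_len - 1e-12 ||
        (abs(len - best_len) <= 1e-12 && .lex_less(route, best_route))) {
      best_len <- len
      best_route <- route
    }
  }
  list(length = best_len, route = best_route)
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Initial transport state
#' @param city Start city.
#' @param targets Target city indices (their binary drives start at 1).
#' @param n_cities World size.
#' @return List with `city` and binary `mu`.
#' @export
transport_initial_state <- function(city, targets, n_cities = 10L) {
  mu <- numeric(n_cities)
  mu[targets] <- 1
  list(city = as.integer(city), mu = mu)
}

#' One step in the transport network
#'
#' Moving along a road to `action_city` pays 5 if that city's binary drive
#' is on (then resets it), minus the road length. The episode terminates
#' when every drive component is zero.
#'
#' @param world A `transport_world`.
#' @param state State from [transport_initial_state()] or a previous step.
#' @param action_city Adjacent city to move to.
#' @return List with `state`, `reward`, `done`.
#' @export
transport_step <- function(world, state, action_city) {
  if (!(action_city %in% world$adj[[state$city]]))
    stop("city ", action_city, " is not adjacent to ", state$city)
  d <- world$dist[state$city, action_city]
  # adjacent cities: the direct road is the shortest path between them
  mu <- state$mu
  reward <- 5 * (mu[action_city] > 0) - d
  mu[action_city] <- 0
  list(state = list(city = as.integer(action_city), mu = mu),
       reward = reward, done = all(mu == 0))
}

.encode_transport <- function(state, n_cities) {
  pos <- numeric(n_cities)
  pos[state$city] <- 1
  c(pos, state$mu)
}

#' Train a motivated Q-agent on the transport task
#'
#' A one-hidden-layer network (20-200-10, leaky ReLU with slope 0.2
#' throughout) maps the one-hot position plus the binary motivation vector
#' to Q-values for moving to each city. Non-adjacent cities are masked both
#' at action selection and in the TD target's max. Behavior during training
#' follows a softmax policy (beta = 0.5); each episode starts at a uniform
#' random city with a fresh random 3-target set (targets distinct from the
#' start city) and runs until all targets are cleared.
#'
#' @param world A `transport_world`.
#' @param schedule A [train_schedule()] counted in episodes; defaults to
#'   1e5 episodes, lr 1e-2 to 1e-4, gamma 0.9.
#' @param m Number of targets per episode.
#' @param beta Softmax inverse temperature of the behavior policy.
#' @param n_hidden Hidden-layer width.
#' @return Trained `mlp` Q-network.
#' @export
train_transport <- function(world,
                            schedule = train_schedule(1e5, 1e-2, 1e-4,
                                                      gamma = 0.9),
                            m = 3L, beta = 0.5, n_hidden = 200L) {
  n <- nrow(world$coords)
  params <- init_mlp(c(2L * n, n_hidden, n), "leaky_relu", alpha = 0.2)
  train_transport_loop_cpp(params$W, params$b, params$act, params$alpha,
                           world$adj, world$dist,
                           as.integer(schedule$n_steps), as.integer(m),
                           schedule$gamma, beta, schedule$lr_start,
                           schedule$lr_end)
  params
}

#' Roll out one transport episode under a fixed motivation supplier
#'
#' Shared harness for the flat agent and the manager-driven hierarchy: the
#' `supplier` closure updates the agent's motivation estimate before each
#' agent move, so the flat agent, an oracle manager, and a learned manager
#' consume identical RNG draws and are directly comparable.
#'
#' @param world A `transport_world`.
#' @param params Trained agent network.
#' @param start,targets Episode specification.
#' @param beta Agent softmax inverse temperature.
#' @param supplier `NULL` for the true dynamics, or
#'   `function(position, mu_est) -> mu_est` applied before each agent step.
#' @param max_steps Step cap.
#' @return List with `traveled`, `route`, `done`, `rewards`.
#' @keywords internal
transport_episode <- function(world, params, start, targets, beta = 10,
                              supplier = NULL, max_steps = 200L) {
  n <- nrow(world$coords)
  state <- transport_initial_state(start, targets, n)
  mu_est <- state$mu
  policy <- list(kind = "softmax", beta = beta)
  traveled <- 0
  route <- state$city
  rewards <- numeric(0)
  done <- FALSE
  for (t in seq_len(max_steps)) {
    if (!is.null(supplier)) mu_est <- supplier(state$city, mu_est)
    else mu_est <- state$mu
    q <- mlp_output(params, .encode_transport(
      list(city = state$city, mu = mu_est), n))
    mask <- seq_len(n) %in% world$adj[[state$city]]
    a <- select_action(q, policy, mask)
    stp <- transport_step(world, state, a)
    traveled <- traveled + world$dist[state$city, a]
    route <- c(route, a)
    rewards <- c(rewards, stp$reward)
    state <- stp$state
    if (stp$done) { done <- TRUE; break }
  }
  list(traveled = traveled, route = route, done = done, rewards = rewards)
}

#' Sample held-out test sets
#' @param world A `transport_world`.
#' @param n_sets Number of episodes.
#' @param m Targets per episode.
#' @return List of `list(start, targets)`.
#' @export
sample_test_sets <- function(world, n_sets = 100L, m = 3L) {
  n <- nrow(world$coords)
  lapply(seq_len(n_sets), function(i) {
    start <- sample.int(n, 1L)
    list(start = start, targets = sample(setdiff(seq_len(n), start), m))
  })
}

#' Evaluate a transport agent against the shortest-tour oracle
#'
#' Runs near-greedy (softmax, default beta = 10) episodes on each test set
#' and compares the traveled length to the optimal open-tour length.
#'
#' @param world A `transport_world`.
#' @param params Trained agent.
#' @param test_sets From [sample_test_sets()].
#' @param beta Evaluation inverse temperature.
#' @param supplier Optional motivation supplier (see `transport_episode`).
#' @return List with `fraction_optimal` (lengths equal within 1e-9
#'   relative), `mean_excess_pct` (`100 * mean((L - L*) / L*)`), and a
#'   data.frame `pairs` of `(L, L_star, done)`.
#' @export
evaluate_transport <- function(world, params, test_sets, beta = 10,
                               supplier = NULL) {
  L <- numeric(length(test_sets))
  Ls <- numeric(length(test_sets))
  done <- logical(length(test_sets))
  for (i in seq_along(test_sets)) {
    ts <- test_sets[[i]]
    ep <- transport_episode(world, params, ts$start, ts$targets, beta,
                            supplier = supplier)
    L[i] <- ep$traveled
    Ls[i] <- shortest_tour(world, ts$start, ts$targets)$length
    done[i] <- ep$done
  }
  list(fraction_optimal = mean(done & (L - Ls) <= 1e-9 * pmax(Ls, 1)),
       mean_excess_pct = 100 * mean((L - Ls) / Ls),
       pairs = data.frame(L = L, L_star = Ls, done = done))
}

#' Exhaustive shortest-tour oracle by route enumeration
#'
#' Independent check of [shortest_tour()]: depth-first enumeration of all
#' walks from the start that visit every target, pruned at `max_len` edges,
#' returning the minimum traveled length. Only intended for small worlds.
#'
#' @param world A `transport_world`.
#' @param start,targets Episode specification.
#' @param max_len Walk-length cap in edges.
#' @return Minimal traveled length.
#' @export
exhaustive_tour_length <- function(world, start, targets, max_len = 12L) {
  best <- Inf
  n <- nrow(world$coords)
  recurse <- function(city, remaining, len, depth) {
    if (len >= best) return()
    if (length(remaining) == 0L) { best <<- min(best, len); return() }
    if (depth >= max_len) return()
    for (nb in world$adj[[city]]) {
      recurse(nb, setdiff(remaining, nb),
              len + world$dist[city, nb], depth + 1L)
    }
  }
  recurse(start, setdiff(targets, start), 0, 0L)
  best
}

#' Serialize a world to JSON
#' @param world A `transport_world`.
#' @param path Output path.
#' @export
write_world <- function(world, path) {
  jsonlite::write_json(list(coords = world$coords, edges = world$edges,
                            lengths = world$lengths),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a world written by [write_world()]
#' @param path File path.
#' @return A `transport_world`.
#' @export
read_world <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_world(matrix(unlist(obj$coords), ncol = 2L),
             matrix(as.integer(unlist(obj$edges)), ncol = 2L))
}
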
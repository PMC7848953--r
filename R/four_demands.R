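#' Configuration of the Four Demands grid world
#'
#' A 6 x 6 grid split into four 3 x 3 rooms (quadrants), each dispensing one
#' resource (water, food, sleep, play). The agent's drive toward resource
#' `n` grows by 1 per step while unconsumed, saturating at `theta[n]`;
#' occupying room `n` pays the subjective reward `mu[n]` and resets that
#' drive to zero. Room boundaries are open; only the outer wall blocks
#' movement.
#'
#' Input normalization constants for the motivation block of the network
#' encoding are estimated here from a random-walk rollout at the configured
#' saturation caps (so creating a config consumes RNG draws; seed first for
#' reproducibility).
#'
#' @param theta Saturation cap(s): scalar or length-4 vector, each >= 1.
#' @param gamma Discount factor.
#' @param theta_as_input If `TRUE` the network receives the current cap as an
#'   extra (41st) input channel, enabling a single network to serve several
#'   motivational schedules.
#' @param norm_steps Random-walk steps used to estimate motivation moments.
#' @return A list of class `fd_config`.
#' @export
fd_config <- function(theta, gamma = 0.9, theta_as_input = FALSE,
                      norm_steps = 10000L) {
  if (length(theta) == 1L) theta <- rep(theta, 4L)
  stopifnot(length(theta) == 4L, all(theta >= 1))
  cfg <- structure(list(theta = as.numeric(theta), gamma = gamma,
                        theta_as_input = theta_as_input,
                        mu_mean = rep(0, 4), mu_sd = rep(1, 4),
                        theta_norm = c(mean = 5.5, sd = sd(1:10))),
                   class = "fd_config")
  mus <- .fd_random_walk_mu(cfg, norm_steps)
  cfg$mu_mean <- colMeans(mus)
  cfg$mu_sd <- pmax(apply(mus, 2L, sd), 1e-8)
  cfg
}

.fd_random_walk_mu <- function(config, n_steps) {
  state <- fd_initial_state()
  mus <- matrix(0, n_steps, 4L)
  for (t in seq_len(n_steps)) {
    step <- fd_step(config, state, sample.int(5L, 1L))
    state <- step$state
    mus[t, ] <- state$mu
  }
  mus
}

#' Initial state of the grid world
#' @param position Length-2 integer `(row, col)`, 1-based; default top-left.
#' @param mu Initial 4-component motivation; default all zero.
#' @return A list with `position` and `mu`.
#' @export
fd_initial_state <- function(position = c(1L, 1L), mu = rep(0, 4L)) {
  list(position = as.integer(position), mu = as.numeric(mu))
}

#' Room (quadrant) of a grid cell
#'
#' Rooms are numbered row-major: 1 = NW, 2 = NE, 3 = SW, 4 = SE.
#' @param position Length-2 integer `(row, col)` with entries in 1..6.
#' @return Room index in 1..4.
#' @export
room_of <- function(position) {
  r <- position[1L]; c <- position[2L]
  if (r < 1 || r > 6 || c < 1 || c > 6) stop("position outside the 6x6 grid")
  2L * ((r - 1L) %/% 3L) + ((c - 1L) %/% 3L) + 1L
}

.fd_moves <- rbind(up = c(-1L, 0L), down = c(1L, 0L), left = c(0L, -1L),
                   right = c(0L, 1L), stay = c(0L, 0L))

#' Names of the five grid-world actions
#' @export
fd_actions <- function() rownames(.fd_moves)

#' One environment step of the Four Demands task
#'
#' Applies the movement (position unchanged if it would cross the outer
#' wall), reads out the subjective reward `mu[room]` at the new position,
#' then updates the drives: the consumed component (if its reward was
#' nonzero) resets to zero, and every component that delivered no reward
#' this step grows by one up to its cap.
#'
#' @param config An [fd_config()].
#' @param state State as returned by [fd_initial_state()] or a previous step.
#' @param action Action index 1..5 (up, down, left, right, stay).
#' @return A list with `state` (next state) and `reward`.
#' @export
fd_step <- function(config, state, action) {
  mv <- .fd_moves[action, ]
  pos <- state$position + mv
  if (pos[1L] < 1L || pos[1L] > 6L || pos[2L] < 1L || pos[2L] > 6L)
    pos <- state$position
  room <- room_of(pos)
  mu <- state$mu
  reward <- mu[room]
  if (reward > 0) {
    mu[room] <- 0
    grow <- setdiff(1:4, room)
  } else {
    grow <- 1:4
  }
  mu[grow] <- pmin(mu[grow] + 1, config$theta[grow])
  list(state = list(position = pos, mu = mu), reward = reward)
}

#' Encode a grid-world state as a network input vector
#'
#' Concatenates a centered one-hot position block scaled so that the
#' block's total variance is 1 (under uniform random positions), the
#' motivation block standardized to total variance 9, and, when
#' `theta_as_input`, one standardized cap channel. Keeping the position
#' channels individually small while the four motivation channels carry
#' most of the input variance is what preserves the motivated/blinded
#' contrast: controls without a motivation signal then rarely discover
#' position-only room cycles (see the package vignette for the
#' alternative reading of the block scaling and why it was rejected).
#'
#' @param state Grid-world state.
#' @param config An [fd_config()].
#' @param theta_input Cap value for the extra channel (defaults to the
#'   config's first cap).
#' @return Numeric vector of length 40 (or 41 with the cap channel).
#' @export
encode_fd <- function(state, config, theta_input = config$theta[1L]) {
  pos <- numeric(36L)
  pos[(state$position[1L] - 1L) * 6L + state$position[2L]] <- 1
  pos <- (pos - 1 / 36) * sqrt(36 / 35)
  mu <- (state$mu - config$mu_mean) / config$mu_sd * sqrt(9 / 4)
  out <- c(pos, mu)
  if (config$theta_as_input) {
    tn <- config$theta_norm
    out <- c(out, (theta_input - tn[["mean"]]) / tn[["sd"]])
  }
  out
}

#' Train a Q-network on the Four Demands task
#'
#' A 40(41)-100-100-100-5 network (three sigmoid hidden layers, linear
#' Q-value outputs) trained by semi-gradient Q-learning on a continuing
#' stream of environment steps. The learning rate and the epsilon-greedy
#' exploration rate both anneal geometrically over the run.
#'
#' @param config An [fd_config()].
#' @param schedule A [train_schedule()]; defaults reproduce the standard run
#'   (4e5 steps, lr 3e-3 to 3e-5, epsilon 0.5 to 0.05, gamma from `config`).
#' @param motivation_input `"true"` feeds the real drive vector to the
#'   network; `"zero"` trains a motivation-blinded control whose reward is
#'   still driven by the true drives.
#' @param theta_set Cap values cycled through in minibatches of
#'   `minibatch` steps when `config$theta_as_input` is set.
#' @param minibatch Steps spent at each cap before switching.
#' @param eval_steps,burn_in Length of the greedy post-training rollout used
#'   for strategy classification and its discarded prefix.
#' @return A list with `params`, `rollout` (positions, rooms, rewards of the
#'   greedy evaluation), `strategy` (a [classify_strategy()] label), and
#'   `rate` (mean subjective reward per step after burn-in).
#' @export
train_fd_agent <- function(config,
                           schedule = train_schedule(4e5, 3e-3, 3e-5,
                                                     0.5, 0.05,
                                                     gamma = config$gamma),
                           motivation_input = c("true", "zero"),
                           theta_set = 1:10, minibatch = 10L,
                           eval_steps = 500L, burn_in = 100L) {
  motivation_input <- match.arg(motivation_input)
  n_in <- if (config$theta_as_input) 41L else 40L
  params <- init_mlp(c(n_in, 100L, 100L, 100L, 5L),
                     c("sigmoid", "sigmoid", "sigmoid", "linear"))
  gamma <- schedule$gamma
  n <- schedule$n_steps
  state <- fd_initial_state(position = c(sample.int(6L, 1L),
                                         sample.int(6L, 1L)))
  theta_cur <- config$theta[1L]
  cfg_cur <- config
  enc <- function(s) {
    s_in <- s
    if (motivation_input == "zero") s_in$mu <- rep(0, 4L)
    encode_fd(s_in, config, theta_input = theta_cur)
  }
  x <- enc(state)
  for (t in seq_len(n)) {
    if (config$theta_as_input && (t - 1L) %% minibatch == 0L) {
      theta_cur <- theta_set[((t - 1L) %/% minibatch) %% length(theta_set) + 1L]
      cfg_cur$theta <- rep(theta_cur, 4L)
    }
    eps <- anneal(schedule$eps_start, schedule$eps_end, t - 1L, n)
    lr <- anneal(schedule$lr_start, schedule$lr_end, t - 1L, n)
    cache <- mlp_forward_cpp(params$W, params$b, params$act, params$alpha, x)
    q <- cache[[length(cache)]]
    a <- select_action(q, list(kind = "epsilon_greedy", epsilon = eps))
    step <- fd_step(cfg_cur, state, a)
    x_next <- enc(step$state)
    q_next <- mlp_output(params, x_next)
    delta <- td_error(step$reward, gamma, max(q_next), q[a])
    mlp_update_selected_cpp(params$W, params$b, params$act, params$alpha,
                            cache, a, delta, lr)
    state <- step$state
    x <- x_next
  }
  res <- fd_rollout(params, config, steps = eval_steps, burn_in = burn_in,
                    motivation_input = motivation_input,
                    theta_input = theta_cur)
  list(params = params, rollout = res,
       strategy = classify_strategy(res$rooms, res$rewards),
       rate = res$rate)
}

#' Greedy evaluation rollout in the Four Demands task
#'
#' @param params Trained `mlp`.
#' @param config An [fd_config()]; for a cap-as-input network set
#'   `config$theta` (and `theta_input`) to the cap under evaluation.
#' @param steps,burn_in Rollout length and discarded prefix.
#' @param motivation_input As in [train_fd_agent()].
#' @param theta_input Cap channel value for cap-as-input networks.
#' @return List with `positions` (steps x 2), `rooms`, `rewards` (after
#'   burn-in), and `rate`.
#' @export
fd_rollout <- function(params, config, steps = 500L, burn_in = 100L,
                       motivation_input = "true",
                       theta_input = config$theta[1L]) {
  state <- fd_initial_state(position = c(sample.int(6L, 1L),
                                         sample.int(6L, 1L)))
  positions <- matrix(0L, steps, 2L)
  rooms <- integer(steps)
  rewards <- numeric(steps)
  for (t in seq_len(steps)) {
    s_in <- state
    if (motivation_input == "zero") s_in$mu <- rep(0, 4L)
    q <- mlp_output(params, encode_fd(s_in, config, theta_input))
    a <- which.max(q)
    stp <- fd_step(config, state, a)
    state <- stp$state
    positions[t, ] <- state$position
    rooms[t] <- room_of(state$position)
    rewards[t] <- stp$reward
  }
  keep <- (burn_in + 1L):steps
  list(positions = positions[keep, , drop = FALSE], rooms = rooms[keep],
       rewards = rewards[keep], rate = mean(rewards[keep]))
}

#' Analytic mean subjective reward per step of the canonical strategies
#'
#' Closed forms for the periodic policies of the Four Demands task:
#' one-room binge 1/2; two-room binge `min(theta, 1)`; delayed two-room
#' binge `2 min(theta, 2) / 3`; migration `(min(theta, 9) + 1) / 3` (10/3
#' once the cap reaches 9, 2/3 at cap 1); delayed migration
#' `(3 (min(theta, 11) + 1) + min(theta, 9) + 2) / 14` (47/14 at cap 15).
#'
#' @param strategy_name One of `"one_room_binge"`, `"two_room_binge"`,
#'   `"delayed_two_room_binge"`, `"migration"`, `"delayed_migration"`.
#' @param theta Saturation cap, >= 1.
#' @return Mean subjective reward per step.
#' @export
strategy_rate <- function(strategy_name, theta) {
  stopifnot(theta >= 1)
  switch(strategy_name,
    one_room_binge = 1 / 2,
    two_room_binge = min(theta, 1),
    delayed_two_room_binge = 2 * min(theta, 2) / 3,
    migration = (min(theta, 9) + 1) / 3,
    delayed_migration = (3 * (min(theta, 11) + 1) + min(theta, 9) + 2) / 14,
    stop("unknown strategy: ", strategy_name)
  )
}

#' Canonical periodic trajectories of the named strategies
#'
#' Returns a representative position/action cycle that realizes the strategy
#' on the grid, for replaying through [fd_step()] (simulation-versus-formula
#' checks, fixtures, and reward read-outs).
#'
#' @param strategy_name As in [strategy_rate()].
#' @return List with `start` (position preceding the cycle), `actions`
#'   (one period of action indices), and `period`.
#' @export
canonical_trajectory <- function(strategy_name) {
  a <- function(...) match(c(...), fd_actions())
  switch(strategy_name,
    one_room_binge = list(start = c(1L, 1L), actions = a("stay", "stay"),
                          period = 2L),
    two_room_binge = list(start = c(1L, 3L), actions = a("right", "left"),
                          period = 2L),
    delayed_two_room_binge = list(start = c(1L, 3L),
                                  actions = a("right", "stay", "left"),
                                  period = 3L),
    migration = list(
      start = c(3L, 2L),
      actions = a("up", "right", "right", "right", "down", "down",
                  "down", "left", "left", "left", "up", "up"),
      period = 12L),
    delayed_migration = list(
      start = c(3L, 2L),
      actions = a("up", "stay", "stay", "right", "right", "right", "down",
                  "down", "down", "left", "left", "left", "up", "up"),
      period = 14L),
    stop("unknown strategy: ", strategy_name)
  )
}

#' Replay a canonical strategy through the environment
#'
#' Runs the cycle for `warmup` periods to reach the steady state, then one
#' further period, returning the steady-state per-step rewards.
#'
#' @param strategy_name As in [strategy_rate()].
#' @param theta Saturation cap.
#' @param warmup Number of periods run before measuring.
#' @return List with `rewards` (one steady-state period), `rooms`, and
#'   `rate` (their mean).
#' @export
replay_strategy <- function(strategy_name, theta, warmup = 4L) {
  traj <- canonical_trajectory(strategy_name)
  config <- structure(list(theta = rep(theta, 4L), gamma = 0.9,
                           theta_as_input = FALSE), class = "fd_config")
  state <- fd_initial_state(position = traj$start)
  for (i in seq_len(warmup * traj$period)) {
    state <- fd_step(config, state,
                     traj$actions[(i - 1L) %% traj$period + 1L])$state
  }
  rewards <- numeric(traj$period)
  rooms <- integer(traj$period)
  for (i in seq_len(traj$period)) {
    stp <- fd_step(config, state, traj$actions[i])
    state <- stp$state
    rewards[i] <- stp$reward
    rooms[i] <- room_of(state$position)
  }
  list(rewards = rewards, rooms = rooms, rate = mean(rewards))
}

.cyclic_runs <- function(cycle) {
  # run-length encoding of one period, merging the wrap-around run
  r <- rle(cycle)
  if (length(r$values) > 1L && r$values[1L] == r$values[length(r$values)]) {
    r$lengths[1L] <- r$lengths[1L] + r$lengths[length(r$lengths)]
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  r
}

.is_periodic <- function(x, p) {
  n <- length(x)
  if (n < 2L * p) return(FALSE)
  all(x[seq_len(n - p)] == x[seq_len(n - p) + p])
}

#' Classify a room-visit sequence into a canonical strategy
#'
#' Detects the periodic room pattern of each named strategy (checking
#' periods in increasing order) on the tail of the sequence; anything
#' aperiodic or unrecognized is labeled `"other"`.
#'
#' @param rooms Integer room sequence (>= 28 steps).
#' @param rewards Optional per-step subjective rewards from the same rollout,
#'   used for the empirical rate.
#' @return List with `name` and `empirical_rate` (NA if no rewards given).
#' @export
classify_strategy <- function(rooms, rewards = NULL) {
  if (length(rooms) < 28L) stop("sequence too short to classify (need >= 28)")
  rate <- if (is.null(rewards)) NA_real_ else mean(rewards)
  lab <- function(name) list(name = name, empirical_rate = rate)
  for (p in c(1L, 2L, 3L, 12L, 14L)) {
    if (!.is_periodic(rooms, p)) next
    cycle <- tail(rooms, p)
    runs <- .cyclic_runs(cycle)
    k <- length(runs$values)
    distinct <- length(unique(runs$values)) == k
    if (p == 1L) return(lab("one_room_binge"))
    if (p == 2L && k == 2L) return(lab("two_room_binge"))
    if (p == 3L && k == 2L && distinct &&
        setequal(runs$lengths, c(1L, 2L)))
      return(lab("delayed_two_room_binge"))
    if (p == 12L && k == 4L && distinct && all(runs$lengths == 3L))
      return(lab("migration"))
    if (p == 14L && k == 4L && distinct &&
        sum(runs$lengths == 3L) == 3L && sum(runs$lengths == 5L) == 1L)
      return(lab("delayed_migration"))
    break
  }
  lab("other")
}

#' Configuration for the addiction variant
#'
#' Three ordinary rooms with caps of 1 and a "smoking" room whose drive may
#' grow to 10. The excursion structure of the learned policy depends on the
#' discount factor: myopic agents (small gamma) re-enter the smoking room
#' almost immediately, far-sighted ones wait for the drive to build up.
#'
#' @param gamma Discount factor in (0, 1).
#' @return An [fd_config()] with caps `(1, 1, 1, 10)`.
#' @export
make_addiction_config <- function(gamma) {
  stopifnot(gamma > 0, gamma < 1)
  fd_config(theta = c(1, 1, 1, 10), gamma = gamma)
}

#' Inter-consumption intervals for one room
#'
#' Gaps (in steps) between successive nonzero-reward visits to the given
#' room, from a rollout's room and reward sequences. Summarizes excursion
#' length in the addiction variant.
#'
#' @param rooms,rewards Aligned sequences from a rollout.
#' @param room Room index (default 4, the high-cap room).
#' @return Integer vector of intervals (possibly empty).
#' @export
consumption_intervals <- function(rooms, rewards, room = 4L) {
  hits <- which(rooms == room & rewards > 0)
  if (length(hits) < 2L) return(integer(0))
  diff(hits)
}

#' Sweep the saturation cap and record the learned strategy
#'
#' Trains one agent per cap value and tabulates the classified strategy and
#' empirical subjective-reward rate, reproducing the phase-diagram analysis
#' of behavior against the cap.
#'
#' @param thetas Cap values; default 41 geometrically spaced points on
#'   `[1, 100]`.
#' @param schedule Training schedule passed to each run.
#' @param motivation_input As in [train_fd_agent()].
#' @return A data.frame with columns `theta`, `strategy`, `rate`.
#' @export
fd_sweep <- function(thetas = exp(seq(log(1), log(100), length.out = 41L)),
                     schedule = NULL, motivation_input = "true") {
  rows <- lapply(thetas, function(th) {
    config <- fd_config(theta = th)
    sch <- if (is.null(schedule))
      train_schedule(4e5, 3e-3, 3e-5, 0.5, 0.05, gamma = config$gamma)
    else schedule
    fit <- train_fd_agent(config, sch, motivation_input = motivation_input)
    data.frame(theta = th, strategy = fit$strategy$name, rate = fit$rate)
  })
  do.call(rbind, rows)
}
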
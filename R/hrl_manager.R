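#' Apply a manager action to an estimated motivation vector
#'
#' The manager's action space has 11 actions: `set_zero(i)` for each of the
#' 10 components (actions 1..10), and `do_nothing` (action 11). All actions
#' are idempotent and can only clear components, so the estimate is binary
#' and non-increasing within an episode.
#'
#' @param mu_est Binary motivation estimate (length 10).
#' @param action Action index 1..11.
#' @return Updated estimate.
#' @export
apply_manager_action <- function(mu_est, action) {
  n <- length(mu_est)
  stopifnot(action >= 1L, action <= n + 1L)
  if (action <= n) mu_est[action] <- 0
  mu_est
}

#' Manager reward schedules
#'
#' In supervised mode the manager is scored against the recorded true
#' motivation transition: +2 when applying its action to the pre-transition
#' vector reproduces the post-transition vector, otherwise -2, softened to
#' -1 when the wrong action was `do_nothing` (to discourage spurious edits
#' without over-penalizing caution). In unsupervised mode only the sign of
#' the agent's reward is propagated: +5 on a positive agent reward (larger
#' than the penalty because positive steps are rarer), otherwise -2,
#' softened to -1 after `do_nothing`.
#'
#' @param mode `"supervised"` or `"unsupervised"`.
#' @return List with `mode` and the reward constants.
#' @export
manager_schedule <- function(mode = c("supervised", "unsupervised")) {
  mode <- match.arg(mode)
  if (mode == "supervised")
    list(mode = mode, r_correct = 2, r_incorrect = -2, r_incorrect_nothing = -1)
  else
    list(mode = mode, r_positive = 5, r_negative = -2, r_negative_nothing = -1)
}

#' Manager reward for one step
#'
#' @param schedule A [manager_schedule()].
#' @param action Manager action index (11 = do nothing).
#' @param mu_true_before,mu_true_after True motivation around the agent's
#'   step (supervised mode only).
#' @param agent_reward_sign Sign of the agent's step reward (unsupervised
#'   mode only).
#' @return Scalar reward.
#' @export
manager_reward <- function(schedule, action, mu_true_before = NULL,
                           mu_true_after = NULL, agent_reward_sign = NULL) {
  nothing <- if (is.null(mu_true_before)) action == 11L
             else action == length(mu_true_before) + 1L
  if (schedule$mode == "supervised") {
    stopifnot(!is.null(mu_true_before), !is.null(mu_true_after))
    correct <- all(apply_manager_action(mu_true_before, action) ==
                     mu_true_after)
    if (correct) return(schedule$r_correct)
    if (nothing) return(schedule$r_incorrect_nothing)
    return(schedule$r_incorrect)
  }
  stopifnot(!is.null(agent_reward_sign))
  if (agent_reward_sign > 0) return(schedule$r_positive)
  if (nothing) return(schedule$r_negative_nothing)
  schedule$r_negative
}

.encode_manager <- function(city, mu_est, n_cities) {
  pos <- numeric(n_cities)
  pos[city] <- 1
  c(pos, mu_est)
}

#' Record episodes of the trained agent under the true dynamics
#'
#' Produces the (position, motivation-before, motivation-after) transition
#' stream that the supervised manager trains on. Episodes start at random
#' cities with random targets; the behavior policy is the agent's training
#' softmax so state coverage stays broad.
#'
#' @param world A `transport_world`.
#' @param agent_params Trained agent network.
#' @param n_episodes Number of recorded episodes.
#' @param beta Agent softmax inverse temperature while recording.
#' @param m Targets per episode.
#' @param max_steps Per-episode step cap while recording.
#' @return List of episodes; each has matrices `mu_before`, `mu_after` and
#'   vector `position` (the city just entered at each step).
#' @export
record_agent_episodes <- function(world, agent_params, n_episodes,
                                  beta = 0.5, m = 3L, max_steps = 50L) {
  n <- nrow(world$coords)
  lapply(seq_len(n_episodes), function(ep) {
    start <- sample.int(n, 1L)
    targets <- sample(setdiff(seq_len(n), start), m)
    state <- transport_initial_state(start, targets, n)
    pos <- integer(0)
    before <- NULL; after <- NULL
    for (t in seq_len(max_steps)) {
      q <- mlp_output(agent_params, .encode_transport(state, n))
      mask <- seq_len(n) %in% world$adj[[state$city]]
      a <- select_action(q, list(kind = "softmax", beta = beta), mask)
      stp <- transport_step(world, state, a)
      # the motivation transition caused by entering city `a`
      pos <- c(pos, a)
      before <- rbind(before, state$mu)
      after <- rbind(after, stp$state$mu)
      state <- stp$state
      if (stp$done) break
    }
    list(position = pos, mu_before = before, mu_after = after)
  })
}

.manager_net <- function(n_cities) {
  init_mlp(c(2L * n_cities, 200L, 200L, 200L, n_cities + 1L),
           "leaky_relu", alpha = 0.2)
}

#' Train the manager network
#'
#' The manager is a 20-200-200-200-11 leaky-ReLU Q-network over its own
#' action space (zero one of the 10 estimated-motivation components, or do
#' nothing), trained by semi-gradient Q-learning with an epsilon-greedy
#' behavior policy (epsilon = 0.1, gamma = 0.9). It observes the agent's
#' position (the city just entered) and the current motivation estimate.
#'
#' In supervised mode it replays prerecorded true-motivation transitions of
#' the trained agent. In unsupervised mode it runs in closed loop: the
#' manager edits the estimate, the agent acts on the edited estimate, and
#' only the sign of the agent's reward comes back; episodes are capped at
#' 50 manager steps and semi-gradients are accumulated over minibatches of
#' 50 steps before each weight update, with the annealed learning rate
#' clipped from above at 1e-3.
#'
#' @param mode `"supervised"` or `"unsupervised"`.
#' @param world A `transport_world`.
#' @param agent_params Trained agent network.
#' @param n_episodes Training episodes (full-scale default: 2e5).
#' @param epsilon Exploration rate.
#' @param gamma Discount factor.
#' @param agent_beta Agent softmax inverse temperature in the closed loop.
#' @param minibatch Minibatch size (manager steps) in unsupervised mode.
#' @param episodes Prerecorded episodes for supervised mode (recorded on the
#'   fly when `NULL`).
#' @param m Targets per episode.
#' @return Trained manager `mlp`.
#' @export
train_manager <- function(mode = c("supervised", "unsupervised"), world,
                          agent_params, n_episodes = 2e5, epsilon = 0.1,
                          gamma = 0.9, agent_beta = 10, minibatch = 50L,
                          episodes = NULL, m = 3L) {
  mode <- match.arg(mode)
  n <- nrow(world$coords)
  params <- .manager_net(n)
  sched <- manager_schedule(mode)
  policy <- list(kind = "epsilon_greedy", epsilon = epsilon)

  if (mode == "supervised") {
    if (is.null(episodes)) {
      # compiled path: the agent runs under the true dynamics and the
      # manager is scored on each transition as it is generated (same
      # distribution as replaying prerecorded episodes)
      train_manager_supervised_cpp(params$W, params$b, params$act,
                                   params$alpha, agent_params$W,
                                   agent_params$b, agent_params$act,
                                   agent_params$alpha, world$adj,
                                   world$dist, as.integer(n_episodes),
                                   as.integer(m), gamma, epsilon, 0.5, 50L,
                                   1e-3, 1e-6)
      return(params)
    }
    n_ep <- length(episodes)
    for (ep in seq_len(n_ep)) {
      lr <- anneal(1e-3, 1e-6, ep - 1L, n_ep)
      e <- episodes[[ep]]
      n_steps <- length(e$position)
      for (t in seq_len(n_steps)) {
        x <- .encode_manager(e$position[t], e$mu_before[t, ], n)
        cache <- mlp_forward_cpp(params$W, params$b, params$act,
                                 params$alpha, x)
        q <- cache[[length(cache)]]
        a <- select_action(q, policy)
        r <- manager_reward(sched, a, e$mu_before[t, ], e$mu_after[t, ])
        q_next_best <- if (t == n_steps) 0 else {
          x_next <- .encode_manager(e$position[t + 1L], e$mu_after[t, ], n)
          max(mlp_output(params, x_next))
        }
        delta <- td_error(r, gamma, q_next_best, q[a])
        mlp_update_selected_cpp(params$W, params$b, params$act,
                                params$alpha, cache, a, delta, lr)
      }
    }
    return(params)
  }

  # unsupervised closed loop (compiled; mutates params in place)
  train_manager_loop_cpp(params$W, params$b, params$act, params$alpha,
                         agent_params$W, agent_params$b, agent_params$act,
                         agent_params$alpha, world$adj, world$dist,
                         as.integer(n_episodes), as.integer(m), gamma,
                         epsilon, agent_beta, 50L, 1e-2, 1e-5, 1e-3,
                         as.integer(minibatch))
  params
}

#' Held-out accuracy of the supervised manager's learned dynamics
#'
#' Fraction of recorded transitions on which the manager's greedy action
#' reproduces the true motivation change.
#'
#' @param manager_params Trained manager.
#' @param episodes Held-out episodes from [record_agent_episodes()].
#' @param n_cities World size.
#' @return Accuracy in `[0, 1]`.
#' @export
manager_accuracy <- function(manager_params, episodes, n_cities = 10L) {
  correct <- 0L; total <- 0L
  for (e in episodes) {
    for (t in seq_along(e$position)) {
      q <- mlp_output(manager_params,
                      .encode_manager(e$position[t], e$mu_before[t, ],
                                      n_cities))
      a <- which.max(q)
      pred <- apply_manager_action(e$mu_before[t, ], a)
      correct <- correct + all(pred == e$mu_after[t, ])
      total <- total + 1L
    }
  }
  correct / total
}

#' Motivation suppliers for the closed-loop evaluation harness
#'
#' `oracle_supplier` replaces the manager with the true dynamics (zero the
#' component of the city just entered), which makes the hierarchy
#' behaviorally identical to the flat agent. `manager_supplier` wraps a
#' trained manager acting greedily (epsilon = 0).
#'
#' @param manager_params Trained manager network.
#' @param n_cities World size.
#' @return A `function(position, mu_est) -> mu_est`.
#' @export
manager_supplier <- function(manager_params, n_cities = 10L) {
  function(position, mu_est) {
    q <- mlp_output(manager_params,
                    .encode_manager(position, mu_est, n_cities))
    apply_manager_action(mu_est, which.max(q))
  }
}

#' @rdname manager_supplier
#' @export
oracle_supplier <- function() {
  function(position, mu_est) { mu_est[position] <- 0; mu_est }
}

#' Evaluate the manager-agent hierarchy
#'
#' Closed-loop rollouts (manager greedy, agent softmax beta = 10) on the
#' same test harness as [evaluate_transport()]; the motivation estimate is
#' initialized to the episode's true target set and thereafter maintained
#' by the manager.
#'
#' @param world A `transport_world`.
#' @param agent_params Trained agent.
#' @param manager_params Trained manager, or `NULL` with
#'   `supplier = oracle_supplier()`.
#' @param test_sets From [sample_test_sets()].
#' @param beta Agent inverse temperature.
#' @param supplier Optional explicit supplier overriding `manager_params`.
#' @return As [evaluate_transport()].
#' @export
evaluate_hierarchy <- function(world, agent_params, manager_params,
                               test_sets, beta = 10, supplier = NULL) {
  if (is.null(supplier))
    supplier <- manager_supplier(manager_params, nrow(world$coords))
  evaluate_transport(world, agent_params, test_sets, beta,
                     supplier = supplier)
}
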
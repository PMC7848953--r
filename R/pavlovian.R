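#' Trial specifications of the conditioning task
#'
#' Six trial types: strong/weak/zero reward (valence +1) and strong/weak/
#' zero punishment (valence -1), with cue and outcome magnitudes 1, 0.5, 0.
#' The two zero-magnitude types have identical cue and reward traces and
#' differ only in the motivation input, mirroring the identical no-reward /
#' no-punishment trials of the reward and punishment blocks.
#'
#' @return A data.frame of the six `(name, valence, magnitude)` specs.
#' @export
trial_types <- function() {
  data.frame(
    name = c("strong_reward", "weak_reward", "zero_reward",
             "zero_punishment", "weak_punishment", "strong_punishment"),
    valence = c(1, 1, 1, -1, -1, -1),
    magnitude = c(1, 0.5, 0, 0, 0.5, 1)
  )
}

#' Build the 20-step traces of one conditioning trial
#'
#' The cue (conditioned stimulus) is `valence * magnitude` on steps 6-10
#' and 0 elsewhere; the subjective reward (unconditioned stimulus,
#' numerically equal to the cue value) arrives on steps 14-18; the
#' motivation trace is the constant block sign (+1 reward block, -1
#' punishment block).
#'
#' @param valence +1 or -1.
#' @param magnitude 0, 0.5, or 1.
#' @return List of class `trial` with `cue`, `motivation`, `reward`
#'   (each length 20), `valence`, `magnitude`.
#' @export
make_trial <- function(valence, magnitude) {
  stopifnot(valence %in% c(-1, 1), magnitude >= 0)
  cue <- numeric(20L)
  cue[6:10] <- valence * magnitude
  reward <- numeric(20L)
  reward[14:18] <- valence * magnitude
  structure(list(cue = cue, motivation = rep(valence, 20L), reward = reward,
                 valence = valence, magnitude = magnitude), class = "trial")
}

#' Exact discounted value trace of a trial
#'
#' `V*_t = sum_{tau >= 0} gamma^tau * r_{t + tau}` within the trial (the
#' current step's reward is included), the fixed point that TD(0) learning
#' converges to here.
#'
#' @param trial A [make_trial()] object.
#' @param gamma Discount factor.
#' @return Numeric length-20 value trace.
#' @export
v_star <- function(trial, gamma = 0.9) {
  r <- trial$reward
  v <- numeric(20L)
  v[20L] <- r[20L]
  for (t in 19:1) v[t] <- r[t] + gamma * v[t + 1L]
  v
}

#' Initialize the recurrent value network
#'
#' 40 sigmoid recurrent units driven by the 2-channel input (cue,
#' motivation) through frozen Xavier input weights; the recurrent matrix
#' and the linear readout are trainable and start near zero (uniform on
#' +/- 1e-5).
#'
#' @param n_hidden Recurrent layer width.
#' @param w_scale Half-width of the uniform initialization of the trained
#'   weights.
#' @return List of class `rnn` with `w_in` (n_hidden x 2), `w_rec`
#'   (n_hidden x n_hidden), `w_out` (1 x n_hidden).
#' @export
init_rnn <- function(n_hidden = 40L, w_scale = 1e-5) {
  w_in <- matrix(rnorm(n_hidden * 2L, sd = sqrt(2 / (2 + n_hidden))),
                 n_hidden, 2L)
  w_rec <- matrix(runif(n_hidden^2, -w_scale, w_scale), n_hidden, n_hidden)
  w_out <- matrix(runif(n_hidden, -w_scale, w_scale), 1L, n_hidden)
  structure(list(w_in = w_in, w_rec = w_rec, w_out = w_out), class = "rnn")
}

#' Unroll the recurrent network over one trial
#'
#' `h_t = sigmoid(w_in [cue_t, motivation_t] + w_rec h_{t-1})` with
#' `h_0 = 0`, and `v_t = w_out h_t` (linear readout).
#'
#' @param params An `rnn` object.
#' @param trial A [make_trial()] object.
#' @param motivation_input `"true"` or `"zero"` (motivation-blinded
#'   control).
#' @return List with `hidden` (n_hidden x 20) and `v` (length 20).
#' @export
rnn_forward <- function(params, trial, motivation_input = "true") {
  n_hidden <- nrow(params$w_rec)
  mot <- if (motivation_input == "zero") rep(0, 20L) else trial$motivation
  h <- numeric(n_hidden)
  H <- matrix(0, n_hidden, 20L)
  for (t in 1:20) {
    z <- params$w_in %*% c(trial$cue[t], mot[t]) + params$w_rec %*% h
    h <- 1 / (1 + exp(-z))
    H[, t] <- h
  }
  list(hidden = H, v = as.numeric(params$w_out %*% H))
}

#' Train the recurrent value network by TD(0)
#'
#' Per-step TD errors `delta_t = r_t + gamma v_{t+1} - v_t` (with
#' `v_21 = 0`) are backpropagated through the readout and the recurrent
#' weights. Each error is held constant in the gradient (semi-gradient) and
#' credited through the stored activations of the preceding time steps by
#' backpropagation through time within the trial; `truncate` limits how
#' many steps back the credit flows (default: the whole trial, which is
#' required for the recurrent weights to learn the cue-outcome bridge —
#' with one-step credit they never leave their near-zero initialization).
#' The input weights stay frozen. Each batch holds 20 trials drawn
#' uniformly from the six types; gradients are averaged over the batch and
#' the learning rate decays geometrically.
#'
#' @param schedule A [train_schedule()] counted in batches; the full-scale
#'   run is 3e5 batches, lr 1e-2 to 1e-4, gamma 0.9.
#' @param params Optional pre-initialized `rnn`.
#' @param batch_size Trials per batch.
#' @param motivation_input `"true"` or `"zero"` control.
#' @param truncate Steps of backpropagation through time (>= 1; `Inf` or 20
#'   for the full trial).
#' @param anneal_horizon Batch count over which the learning rate is
#'   annealed (defaults to `schedule$n_steps`). Setting it larger than the
#'   number of batches runs a prefix of the longer schedule, the
#'   recommended way to scale training down: convergence requires the
#'   learning rate still to be high when the recurrent weights escape
#'   their initial plateau, so compressing the decay fails where
#'   truncating it succeeds.
#' @param loss_every Record the running MSE against [v_star()] every this
#'   many batches.
#' @return List with `params`, `loss` (data.frame batch/mse), and
#'   `motivation_input`.
#' @export
train_rnn <- function(schedule = train_schedule(3e5, 1e-2, 1e-4, gamma = 0.9),
                      params = init_rnn(), batch_size = 20L,
                      motivation_input = "true", truncate = Inf,
                      anneal_horizon = schedule$n_steps,
                      loss_every = 500L) {
  types <- trial_types()
  trials <- lapply(seq_len(nrow(types)),
                   function(i) make_trial(types$valence[i],
                                          types$magnitude[i]))
  cue_by_type <- vapply(trials, `[[`, numeric(20L), "cue")
  mot_by_type <- vapply(trials, `[[`, numeric(20L), "motivation")
  rew_by_type <- vapply(trials, `[[`, numeric(20L), "reward")
  n_hidden <- nrow(params$w_rec)
  gamma <- schedule$gamma
  n_batches <- schedule$n_steps
  w_in_frozen <- params$w_in + 0
  loss_batch <- integer(0); loss_mse <- numeric(0)
  for (b in seq_len(n_batches)) {
    lr <- anneal(schedule$lr_start, schedule$lr_end, b - 1L,
                 anneal_horizon)
    kinds <- sample.int(6L, batch_size, replace = TRUE)
    cues <- cue_by_type[, kinds, drop = FALSE]
    mots <- mot_by_type[, kinds, drop = FALSE]
    rews <- rew_by_type[, kinds, drop = FALSE]
    if (motivation_input == "zero") mots <- mots * 0
    g <- rnn_td_batch_cpp(params$w_in, params$w_rec, params$w_out,
                          cues, mots, rews, gamma, truncate)
    params$w_out <- params$w_out + lr * g$dW_out / batch_size
    params$w_rec <- params$w_rec + lr * g$dW_rec / batch_size
    if (!all(is.finite(params$w_out)) || !all(is.finite(params$w_rec)))
      stop("RNN training diverged at batch ", b,
           " (non-finite weights); reduce the learning rate")
    if (b %% loss_every == 0L || b == n_batches) {
      mse <- rnn_value_mse(params, gamma = gamma,
                           motivation_input = motivation_input)
      loss_batch <- c(loss_batch, b); loss_mse <- c(loss_mse, mse)
    }
  }
  params$w_in <- w_in_frozen
  list(params = params,
       loss = data.frame(batch = loss_batch, mse = loss_mse),
       motivation_input = motivation_input)
}

#' Mean squared error of the value trace against the exact values
#'
#' Averages `(v - V*)^2` over all 20 steps of all six trial types.
#'
#' @param params An `rnn`.
#' @param gamma Discount factor.
#' @param motivation_input Input mode used at evaluation.
#' @return Scalar MSE.
#' @export
rnn_value_mse <- function(params, gamma = 0.9, motivation_input = "true") {
  types <- trial_types()
  errs <- vapply(seq_len(nrow(types)), function(i) {
    tr <- make_trial(types$valence[i], types$magnitude[i])
    v <- rnn_forward(params, tr, motivation_input)$v
    mean((v - v_star(tr, gamma))^2)
  }, numeric(1L))
  mean(errs)
}

#' Hidden-unit activity in the strong reward and punishment trials
#'
#' The model-side analogue of per-neuron firing-rate traces: a units x
#' timesteps x condition array for the population analysis.
#'
#' @param params An `rnn`.
#' @param motivation_input Input mode.
#' @return 3-d array `[units, 20, 2]` with conditions `strong_reward`,
#'   `strong_punishment`.
#' @export
rnn_activity <- function(params, motivation_input = "true") {
  hr <- rnn_forward(params, make_trial(1, 1), motivation_input)$hidden
  hp <- rnn_forward(params, make_trial(-1, 1), motivation_input)$hidden
  arr <- array(0, dim = c(nrow(hr), 20L, 2L),
               dimnames = list(NULL, NULL,
                               c("strong_reward", "strong_punishment")))
  arr[, , 1L] <- hr
  arr[, , 2L] <- hp
  arr
}

#' Export the traces of one trial as a table
#'
#' @param params Trained `rnn`.
#' @param trial_name One of the names in [trial_types()].
#' @param gamma Discount factor for the reference values.
#' @return data.frame with columns step, cue, motivation, reward, v,
#'   v_star.
#' @export
trial_trace <- function(params, trial_name, gamma = 0.9) {
  types <- trial_types()
  i <- match(trial_name, types$name)
  if (is.na(i)) stop("unknown trial type: ", trial_name)
  tr <- make_trial(types$valence[i], types$magnitude[i])
  data.frame(step = 1:20, cue = tr$cue, motivation = tr$motivation,
             reward = tr$reward, v = rnn_forward(params, tr)$v,
             v_star = v_star(tr, gamma))
}
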
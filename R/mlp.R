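#' @useDynLib motivrl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd prcomp hclust cutree dist cor
#' @importFrom utils write.csv read.csv head tail
NULL

.act_codes <- c(linear = 0L, sigmoid = 1L, leaky_relu = 2L)

#' Create a small feedforward network for Q- or value-function approximation
#'
#' Builds the weight/bias stack of a fully connected multilayer perceptron.
#' Weights are drawn either by the Xavier (Glorot) rule, normal with variance
#' `2 / (fan_in + fan_out)`, or uniformly on `(lo, hi)`; biases start at zero.
#' Randomness comes from R's global RNG stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param layer_sizes Integer vector of layer widths, input first, output last.
#' @param activations Character vector, one per weight layer, each one of
#'   `"linear"`, `"sigmoid"`, `"leaky_relu"`.
#' @param init Either `"xavier"` or a numeric length-2 vector `c(lo, hi)` for
#'   uniform initialization.
#' @param alpha Leak slope used by any `"leaky_relu"` layer.
#' @param input_spec Optional list of input normalization constants carried
#'   along with the network (used by the encoders; not interpreted here).
#' @return An object of class `mlp`: a list with elements `W` (list of
#'   out-by-in matrices), `b` (list of bias vectors), `act`, `alpha`, and
#'   `input_spec`.
#' @export
init_mlp <- function(layer_sizes, activations, init = "xavier", alpha = 0.2,
                     input_spec = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stop("need at least an input and output layer")
  n_layers <- length(layer_sizes) - 1L
  if (length(activations) == 1L) activations <- rep(activations, n_layers)
  if (length(activations) != n_layers)
    stop("need one activation per weight layer")
  codes <- .act_codes[activations]
  if (anyNA(codes)) stop("unknown activation: ", activations[is.na(codes)][1L])
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- layer_sizes[l]
    fan_out <- layer_sizes[l + 1L]
    if (identical(init, "xavier")) {
      w <- rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out)))
    } else if (is.numeric(init) && length(init) == 2L) {
      w <- runif(fan_in * fan_out, init[1L], init[2L])
    } else stop("init must be \"xavier\" or c(lo, hi)")
    W[[l]] <- matrix(w, nrow = fan_out, ncol = fan_in)
    b[[l]] <- numeric(fan_out)
  }
  structure(list(W = W, b = b, act = unname(codes),
                 alpha = rep(alpha, n_layers), input_spec = input_spec),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  sizes <- c(ncol(x$W[[1L]]), vapply(x$W, nrow, 0L))
  acts <- names(.act_codes)[x$act + 1L]
  cat("<mlp> ", paste(sizes, collapse = "-"), " [",
      paste(acts, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Deep-copy a network
#'
#' The TD update functions modify weights in place for speed (reference
#' semantics, as the training loops discard the previous parameters anyway).
#' Use `mlp_clone()` when a before-update snapshot is needed.
#' @param params An `mlp` object.
#' @return An independent copy.
#' @export
mlp_clone <- function(params) {
  params$W <- lapply(params$W, function(m) m + 0)
  params$b <- lapply(params$b, function(v) v + 0)
  params
}

#' Forward pass with activation cache
#'
#' @param params An `mlp` object.
#' @param x Numeric input vector matching the first layer's width.
#' @return A list with `activations` (per-layer post-activation values,
#'   element 1 being the input itself) and `output` (last layer's values).
#' @export
forward <- function(params, x) {
  cache <- mlp_forward_cpp(params$W, params$b, params$act, params$alpha,
                           as.numeric(x))
  list(activations = cache, output = cache[[length(cache)]])
}

#' Network output without keeping the cache
#' @inheritParams forward
#' @return Numeric vector of output-layer values.
#' @export
mlp_output <- function(params, x) {
  mlp_output_cpp(params$W, params$b, params$act, params$alpha, as.numeric(x))
}

#' Temporal-difference error
#'
#' `delta = r + gamma * q_next_best - q_selected`, the mismatch between the
#' two sides of the Bellman equation. For terminal transitions pass
#' `q_next_best = 0` (no bootstrap beyond the end of an episode).
#'
#' @param r Subjective reward collected on the transition.
#' @param gamma Discount factor in (0, 1].
#' @param q_next_best Best available Q-value in the successor state.
#' @param q_selected Q-value of the action actually taken.
#' @return The scalar TD error.
#' @export
td_error <- function(r, gamma, q_next_best, q_selected) {
  stopifnot(gamma > 0, gamma <= 1)
  r + gamma * q_next_best - q_selected
}

#' Semi-gradient TD update through one output unit
#'
#' Backpropagates the TD error only through the output unit corresponding to
#' the selected action, holding the error constant (semi-gradient):
#' `w <- w + lr * delta * dQ_k/dw`. Output-layer weight rows of non-selected
#' units are untouched. The update modifies `params` in place and also
#' returns it.
#'
#' @param params An `mlp` object.
#' @param cache Activation cache from [forward()] on the state being updated.
#' @param k Selected output index (1-based).
#' @param delta TD error.
#' @param lr Learning rate.
#' @return `params`, invisibly the same object, updated.
#' @export
update_selected <- function(params, cache, k, delta, lr) {
  if (is.list(cache) && !is.null(cache$activations)) cache <- cache$activations
  mlp_update_selected_cpp(params$W, params$b, params$act, params$alpha,
                          cache, as.integer(k), delta, lr)
  invisible(params)
}

#' Action selection under a behavioral policy
#'
#' Supports epsilon-greedy, softmax (sampling probability proportional to
#' `exp(beta * q)` over available actions), and deterministic argmax.
#' Unavailable actions (masked out) are never chosen. Ties in argmax are
#' broken by the lowest index, for reproducibility.
#'
#' @param q_values Numeric vector of action values.
#' @param policy A list like `list(kind = "epsilon_greedy", epsilon = 0.1)`,
#'   `list(kind = "softmax", beta = 0.5)`, or `list(kind = "deterministic")`.
#' @param available_mask Logical vector of available actions (default: all).
#' @return The selected action index (1-based).
#' @export
select_action <- function(q_values, policy, available_mask = NULL) {
  n <- length(q_values)
  if (is.null(available_mask)) available_mask <- rep(TRUE, n)
  avail <- which(available_mask)
  if (length(avail) == 0L) stop("no available actions")
  q <- q_values[avail]
  kind <- policy$kind
  if (kind == "deterministic") {
    return(avail[which.max(q)])
  }
  if (kind == "epsilon_greedy") {
    eps <- policy$epsilon
    if (runif(1) < eps) {
      return(avail[[sample.int(length(avail), 1L)]])
    }
    return(avail[which.max(q)])
  }
  if (kind == "softmax") {
    z <- policy$beta * q
    p <- exp(z - max(z))
    return(avail[[sample.int(length(avail), 1L, prob = p)]])
  }
  stop("unknown policy kind: ", kind)
}

#' Geometric annealing schedule
#'
#' Interpolates exponentially from `start` at `t = 0` to `end` at `t = T`:
#' `start * (end / start)^(t / T)`. Used for both learning rates and the
#' exploration rate.
#'
#' @param start,end Positive endpoints.
#' @param t Current step (0-based).
#' @param T_total Total number of steps.
#' @return The annealed value.
#' @export
anneal <- function(start, end, t, T_total) {
  stopifnot(start > 0, end > 0, T_total > 0)
  start * (end / start)^(t / T_total)
}

#' Training schedule container
#'
#' @param n_steps Total training steps (or episodes/batches, per task).
#' @param lr_start,lr_end Learning-rate endpoints of the geometric decay.
#' @param eps_start,eps_end Optional epsilon-greedy exploration endpoints.
#' @param gamma Discount factor.
#' @return A list of class `train_schedule`.
#' @export
train_schedule <- function(n_steps, lr_start, lr_end,
                           eps_start = NULL, eps_end = NULL, gamma = 0.9) {
  stopifnot(lr_start >= lr_end, lr_end > 0, gamma > 0, gamma <= 1,
            n_steps >= 1)
  if (!is.null(eps_start))
    stopifnot(eps_start >= 0, eps_start <= 1, eps_end >= 0, eps_end <= 1)
  structure(list(n_steps = as.integer(n_steps), lr_start = lr_start,
                 lr_end = lr_end, eps_start = eps_start, eps_end = eps_end,
                 gamma = gamma), class = "train_schedule")
}

#' Serialize network parameters to JSON
#'
#' Writes one named entry per layer weight/bias plus the layer activation
#' specs and any input normalization constants, so a network round-trips
#' losslessly through the file.
#'
#' @param params An `mlp` object.
#' @param path Output file path.
#' @export
write_mlp <- function(params, path) {
  obj <- list(
    layer_sizes = c(ncol(params$W[[1L]]), vapply(params$W, nrow, 0L)),
    activations = names(.act_codes)[params$act + 1L],
    alpha = params$alpha,
    input_spec = params$input_spec,
    W = lapply(params$W, function(m) unclass(m)),
    b = params$b
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read network parameters written by [write_mlp()]
#' @param path File path.
#' @return An `mlp` object.
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$W
  if (is.matrix(W)) W <- list(W)  # single-layer nets simplify to a matrix
  W <- lapply(W, function(m) matrix(unlist(m), nrow = NROW(m)))
  b <- obj$b
  if (!is.list(b)) b <- list(b)
  structure(list(W = W, b = lapply(b, as.numeric),
                 act = unname(.act_codes[obj$activations]),
                 alpha = as.numeric(obj$alpha),
                 input_spec = obj$input_spec),
            class = "mlp")
}
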
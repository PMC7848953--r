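#' Cluster units by their condition-evoked activity
#'
#' The population pipeline used for both recorded neurons and model units:
#' each unit's traces in the strong-reward and strong-punishment conditions
#' are concatenated and z-scored, the population is reduced to its first
#' three principal components, and the units are grouped by agglomerative
#' hierarchical clustering (Euclidean distance, complete linkage) cut at
#' `n_clusters`. Constant-rate units (zero variance) are excluded with a
#' warning and labeled `NA`.
#'
#' @param activity Units x timesteps x condition array (see
#'   [rnn_activity()]), or a units x (timesteps * conditions) matrix.
#' @param n_clusters Number of clusters to cut the tree into (default 3:
#'   positive, negative, and mixed tuning).
#' @return List of class `cluster_assignment` with `labels` (per unit, 1-
#'   based, `NA` for excluded units), `linkage` (the `hclust` tree),
#'   `n_clusters`, `scores` (PCA scores), and `zscored`.
#' @export
cluster_units <- function(activity, n_clusters = 3L) {
  if (is.array(activity) && length(dim(activity)) == 3L) {
    activity <- do.call(cbind, lapply(seq_len(dim(activity)[3L]),
                                      function(k) activity[, , k]))
  }
  stopifnot(is.matrix(activity), nrow(activity) >= 2L)
  sds <- apply(activity, 1L, sd)
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " constant-rate unit(s) excluded from clustering")
  if (sum(ok) < n_clusters) stop("fewer variable units than clusters")
  z <- t(scale(t(activity[ok, , drop = FALSE])))
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(3L, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  tree <- hclust(dist(scores, method = "euclidean"), method = "complete")
  lab_ok <- cutree(tree, k = n_clusters)
  labels <- rep(NA_integer_, nrow(activity))
  labels[ok] <- lab_ok
  structure(list(labels = labels, linkage = tree, n_clusters = n_clusters,
                 scores = scores, zscored = z),
            class = "cluster_assignment")
}

#' Mean activity difference between conditions per cluster
#'
#' For each cluster, the mean over member units of (mean strong-reward
#' activity minus mean strong-punishment activity). Opposite signs in the
#' two largest clusters identify the positive- and negative-valence
#' populations.
#'
#' @param activity Units x timesteps x 2 array.
#' @param labels Cluster labels from [cluster_units()].
#' @return Named numeric vector, one entry per cluster.
#' @export
cluster_condition_difference <- function(activity, labels) {
  d_unit <- rowMeans(activity[, , 1L]) - rowMeans(activity[, , 2L])
  tapply(d_unit, labels, mean)
}

#' The two largest clusters (the valence populations)
#' @param labels Cluster labels.
#' @return Integer vector of the two most populous cluster ids.
#' @export
largest_two_clusters <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  as.integer(names(tab)[1:2])
}

#' Weight-based correlation and 2-D embedding of recurrent units
#'
#' Correlates units by the vectors of their postsynaptic (outgoing)
#' recurrent weights - with `w_rec[i, j]` the weight from unit j onto unit
#' i, unit j's outgoing vector is column j - and lays the units out in two
#' dimensions with a stochastic-neighbor embedding of the correlation
#' distance. The embedding is for visualization only.
#'
#' @param params An `rnn` (or any list with a square `w_rec`).
#' @param perplexity t-SNE perplexity.
#' @param direction `"outgoing"` (postsynaptic weight vectors) or
#'   `"incoming"`.
#' @param n_iter Embedding gradient-descent iterations.
#' @return List with `correlation` (units x units matrix) and `coords`
#'   (units x 2).
#' @export
weight_embedding <- function(params, perplexity = 30, direction = "outgoing",
                             n_iter = 300L) {
  w <- params$w_rec
  stopifnot(nrow(w) == ncol(w), nrow(w) >= 3L)
  vecs <- if (direction == "outgoing") w else t(w)  # unit i -> column i
  cmat <- cor(vecs)
  d2 <- (1 - cmat)
  coords <- .tsne(d2, perplexity = perplexity, n_iter = n_iter)
  list(correlation = cmat, coords = coords)
}

# Minimal exact t-SNE on a precomputed squared-distance-like matrix.
# Deterministic given the RNG state; adequate for a few dozen units.
.tsne <- function(d2, perplexity = 30, n_iter = 300L, lr = 50) {
  n <- nrow(d2)
  perplexity <- min(perplexity, (n - 1) / 1.05)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    di <- d2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { beta <- beta / 2; next }
      p <- p / sp
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(h - target) < 1e-5) break
      if (h > target) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * 2L, sd = 1e-4), n, 2L)
  inc <- matrix(0, n, 2L)
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100L) 4 else 1  # early exaggeration
    sq <- as.matrix(dist(Y))^2
    Qn <- 1 / (1 + sq); diag(Qn) <- 0
    Q <- pmax(Qn / sum(Qn), 1e-12)
    G <- 4 * ((ex * P - Q) * Qn)
    grad <- (diag(rowSums(G)) - G) %*% Y
    inc <- 0.8 * inc - lr * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Within- versus between-cluster recurrent connectivity (push-pull summary)
#'
#' Mean and standard error of the recurrent weights within each of the two
#' valence clusters (pooled, diagonal excluded) and between them (both
#' directions pooled). A push-pull circuit shows within-cluster excitation
#' and between-cluster inhibition: `mean_within > 0 > mean_between`.
#'
#' @param w_rec Square recurrent weight matrix.
#' @param labels Cluster labels; the two largest clusters are used.
#' @return List of class `connectivity_summary` with `mean_within`,
#'   `sem_within`, `mean_between`, `sem_between`, and `clusters`.
#' @export
push_pull_summary <- function(w_rec, labels) {
  cl <- largest_two_clusters(labels)
  i1 <- which(labels == cl[1L]); i2 <- which(labels == cl[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each valence cluster needs at least 2 units")
  offdiag <- function(m) m[row(m) != col(m)]
  within <- c(offdiag(w_rec[i1, i1, drop = FALSE]),
              offdiag(w_rec[i2, i2, drop = FALSE]))
  between <- c(as.numeric(w_rec[i1, i2]), as.numeric(w_rec[i2, i1]))
  sem <- function(x) sd(x) / sqrt(length(x))
  structure(list(mean_within = mean(within), sem_within = sem(within),
                 mean_between = mean(between), sem_between = sem(between),
                 clusters = cl),
            class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat(sprintf("within:  %+0.4f +/- %0.4f\nbetween: %+0.4f +/- %0.4f\n",
              x$mean_within, x$sem_within, x$mean_between, x$sem_between))
  invisible(x)
}

#' Agreement between activity-based and weight-based groupings
#'
#' Mean weight-vector correlation within activity clusters versus between
#' them (two largest clusters, diagonal excluded).
#'
#' @param correlation Weight-correlation matrix from [weight_embedding()].
#' @param labels Activity-cluster labels.
#' @return List with `within`, `between` mean correlations.
#' @export
weight_activity_agreement <- function(correlation, labels) {
  cl <- largest_two_clusters(labels)
  i1 <- which(labels == cl[1L]); i2 <- which(labels == cl[2L])
  offdiag <- function(m) m[row(m) != col(m)]
  list(within = mean(c(offdiag(correlation[i1, i1, drop = FALSE]),
                       offdiag(correlation[i2, i2, drop = FALSE]))),
       between = mean(correlation[i1, i2]))
}
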
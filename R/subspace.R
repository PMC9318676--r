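# Adaptive-subspace few-shot classifier: class subspaces from support
# features, residual-distance classification, Grassmannian-regularized
# episode loss, and episode sampling.
#
# A class c with K support feature vectors is represented by the offset
# mu_c (support mean) and an orthonormal basis P_c of the r-dimensional
# principal subspace of the centered support features.  A query feature f
# is scored by d_c(f) = -|| (I - P_c P_c^T)(f - mu_c) ||^2, the negated
# squared residual after projection, and class probabilities are the
# softmax of the distances.  During training the cross-entropy of the
# query probabilities is regularized by lambda * sum_{i != j}
# ||P_i^T P_j||_F^2, which pushes class subspaces apart in the
# Grassmannian projection metric.

#' Few-shot training configuration
#'
#' Defaults follow the episodic protocol used throughout: 5-way, 5-shot,
#' 5-query, 100 episodes per epoch, 10 epochs, Adam with learning rate
#' 1e-3, lambda 0.03.  Each default episode therefore contains 25 support
#' and 25 query items.
#'
#' @param n_way Classes per episode.
#' @param k_shot Support items per class.
#' @param m_query Query items per class.
#' @param episodes_per_epoch,epochs Episodic training schedule.
#' @param learning_rate Adam learning rate.
#' @param lambda_reg Weight of the subspace-overlap regularizer (the
#'   sum runs over ordered pairs, so each unordered pair counts twice).
#' @param subspace_rank Subspace dimension `r`; centering K vectors
#'   leaves at most `k_shot - 1` dimensions, the default.
#' @param seed Integer seed controlling all training randomness.
#' @param augment Apply [coarse_dropout_augment()] to support and query
#'   items during training.
#' @return Object of class `few_shot_config`.
#' @export
few_shot_config <- function(n_way = 5L, k_shot = 5L, m_query = 5L,
                            episodes_per_epoch = 100L, epochs = 10L,
                            learning_rate = 1e-3, lambda_reg = 0.03,
                            subspace_rank = k_shot - 1L, seed = 1L,
                            augment = FALSE) {
  stopifnot(n_way >= 2, k_shot >= 2, m_query >= 1,
            episodes_per_epoch >= 1, epochs >= 1, learning_rate > 0,
            lambda_reg >= 0,
            subspace_rank >= 1, subspace_rank <= k_shot - 1)
  structure(list(n_way = as.integer(n_way), k_shot = as.integer(k_shot),
                 m_query = as.integer(m_query),
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, lambda_reg = lambda_reg,
                 subspace_rank = as.integer(subspace_rank),
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "few_shot_config")
}

item_conditions <- function(items)
  vapply(items, `[[`, "", "condition")

#' Sample a few-shot episode
#'
#' Per class, a uniform random permutation assigns the first `k_shot`
#' items to the support set and the next `m_query` to the query set
#' (disjoint by construction).  Uses the current global RNG stream, so
#' the result is deterministic after `set.seed()`.
#'
#' @param items List of labeled [thickness_image()] objects.
#' @param config A [few_shot_config()].
#' @return List with `support`, `support_class`, `query`, `query_class`
#'   (class indices 1..n_way into `classes`) and `classes`.
#' @export
sample_episode <- function(items, config) {
  conds <- item_conditions(items)
  classes <- sort(unique(conds))
  if (length(classes) < config$n_way)
    stop("dataset has ", length(classes), " classes; n_way = ",
         config$n_way)
  if (length(classes) > config$n_way)
    classes <- sort(sample(classes, config$n_way))
  support_idx <- integer(0); query_idx <- integer(0)
  support_class <- integer(0); query_class <- integer(0)
  need <- config$k_shot + config$m_query
  for (ci in seq_along(classes)) {
    idx <- which(conds == classes[ci])
    if (length(idx) < need)
      stop("class ", classes[ci], " has ", length(idx),
           " items; needs at least ", need)
    perm <- sample(idx)
    support_idx <- c(support_idx, perm[seq_len(config$k_shot)])
    query_idx <- c(query_idx, perm[config$k_shot + seq_len(config$m_query)])
    support_class <- c(support_class, rep(ci, config$k_shot))
    query_class <- c(query_class, rep(ci, config$m_query))
  }
  list(support = items[support_idx], support_class = support_class,
       query = items[query_idx], query_class = query_class,
       classes = classes, support_idx = support_idx,
       query_idx = query_idx)
}

#' Build a class subspace from support features
#'
#' `mean` is the support mean and `basis` holds the first `rank` left
#' singular vectors of the centered support feature matrix.  If `rank`
#' exceeds the numerical rank of the centered matrix, the basis is
#' truncated to the numerical rank with a warning (never padded).
#'
#' @param features `k_shot x D` matrix of support features (rows =
#'   shots).
#' @param rank Requested subspace dimension (`<= k_shot - 1`).
#' @param class_id Optional class identifier stored in the result.
#' @return Object of class `class_subspace` with fields `mean`
#'   (D-vector), `basis` (`D x r` orthonormal columns), `rank`, `class_id`.
#' @export
build_class_subspace <- function(features, rank, class_id = NA) {
  stopifnot(is.matrix(features), nrow(features) >= 2,
            rank >= 1, rank <= nrow(features) - 1)
  mu <- colMeans(features)
  a <- t(features) - mu # D x K, centered columns
  sv <- svd(a, nu = min(dim(a)), nv = 0)
  tol <- max(dim(a)) * .Machine$double.eps * max(sv$d, 0)
  num_rank <- sum(sv$d > tol)
  r_eff <- min(rank, num_rank)
  if (r_eff < rank)
    warning("requested rank ", rank, " exceeds numerical rank ", num_rank,
            " of the centered support features; basis truncated to ",
            r_eff)
  structure(list(mean = mu,
                 basis = sv$u[, seq_len(r_eff), drop = FALSE],
                 rank = r_eff, class_id = class_id),
            class = "class_subspace")
}

#' Residual distance of a query to a class subspace
#'
#' `-||(I - P P^T)(f - mu)||^2`, computed from the basis alone (the
#' `D x D` projection matrix is never materialized).  Always `<= 0`; 0
#' iff the centered query lies in the subspace.
#'
#' @param query_feature Feature D-vector.
#' @param subspace A [build_class_subspace()] result.
#' @return Scalar `<= 0`.
#' @export
subspace_distance <- function(query_feature, subspace) {
  stopifnot(inherits(subspace, "class_subspace"))
  if (length(query_feature) != length(subspace$mean))
    stop("feature dimension ", length(query_feature),
         " does not match subspace dimension ", length(subspace$mean))
  z <- as.numeric(query_feature) - subspace$mean
  proj <- if (ncol(subspace$basis) == 0) 0
          else sum(as.numeric(crossprod(subspace$basis, z))^2)
  -(sum(z^2) - proj)
}

#' Softmax class probabilities from distances
#'
#' `p_c = exp(d_c) / sum_c' exp(d_c')`, computed shift-invariantly.
#'
#' @param distances Numeric vector (or `n x n_way` matrix) of per-class
#'   distances.
#' @return Simplex vector (or row-stochastic matrix) of the same shape.
#' @export
class_probabilities <- function(distances) {
  if (is.matrix(distances)) {
    e <- exp(distances - apply(distances, 1, max))
    e / rowSums(e)
  } else {
    e <- exp(distances - max(distances))
    e / sum(e)
  }
}

#' Overlap between two class subspaces
#'
#' Returns `||P_i^T P_j||_F^2`.  The Grassmannian projection metric
#' `delta^2 = ||P_i P_i^T - P_j P_j^T||_F^2 = 2 r - 2 overlap` is exposed
#' as [grassmann_projection_metric()].
#'
#' @param a,b [build_class_subspace()] results of equal rank.
#' @return Scalar overlap in `[0, r]`.
#' @export
subspace_overlap <- function(a, b) {
  stopifnot(inherits(a, "class_subspace"), inherits(b, "class_subspace"))
  if (a$rank != b$rank)
    stop("subspace ranks differ: ", a$rank, " vs ", b$rank)
  sum(crossprod(a$basis, b$basis)^2)
}

#' @rdname subspace_overlap
#' @export
grassmann_projection_metric <- function(a, b)
  2 * a$rank - 2 * subspace_overlap(a, b)

#' Episode loss
#'
#' Mean negative log-probability of the true class over all queries plus
#' `lambda_reg` times the sum of pairwise subspace overlaps over ordered
#' pairs `i != j` (each unordered pair counted twice, so the regularizer
#' is symmetric and `lambda_reg` has a fixed interpretation).
#'
#' @param probabilities `n_query x n_way` row-stochastic matrix.
#' @param true_labels Integer class indices (1..n_way) per query.
#' @param subspaces List of `n_way` [build_class_subspace()] results.
#' @param lambda_reg Regularization weight.
#' @return Scalar loss.
#' @export
episode_loss <- function(probabilities, true_labels, subspaces,
                         lambda_reg = 0.03) {
  stopifnot(is.matrix(probabilities),
            length(true_labels) == nrow(probabilities))
  ce <- -mean(log(probabilities[cbind(seq_along(true_labels),
                                      true_labels)]))
  reg <- 0
  n <- length(subspaces)
  if (lambda_reg > 0 && n > 1) {
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        reg <- reg + 2 * subspace_overlap(subspaces[[i]], subspaces[[j]])
  }
  ce + lambda_reg * reg
}

#' Coarse-dropout augmentation
#'
#' Zeroes a uniformly drawn count of 4-8 pixel positions across all
#' channels; the input is untouched.  Uses the global RNG stream.
#'
#' @param image A [thickness_image()].
#' @return A new augmented [thickness_image()].
#' @export
coarse_dropout_augment <- function(image) {
  stopifnot(inherits(image, "thickness_image"))
  d <- dim(image$pixels)
  count <- sample(4:8, 1)
  pos <- sample(d[1] * d[2], min(count, d[1] * d[2]))
  px <- image$pixels
  for (k in seq_len(d[3])) {
    ch <- px[, , k]
    ch[pos] <- 0L
    px[, , k] <- ch
  }
  thickness_image(image$patient_id, px, image$condition)
}
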
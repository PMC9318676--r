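# Episodic training of the encoder through the subspace head.
#
# The training-time head recomputes, differentiably, what the inference
# ops in subspace.R compute: the rank-r principal subspace of the
# centered support features of each class.  For D-dimensional features
# and K shots the left singular subspace is obtained through the K x K
# Gram matrix S = A^T A (A = centered support, D x K): if S = V L V^T,
# then P = A V_r L_r^{-1/2} holds the top-r left singular vectors.  The
# backward pass uses the standard symmetric-eigendecomposition adjoint
# (1/(lambda_j - lambda_i) cross terms) on the K x K problem, which is
# far cheaper than an SVD adjoint on the D x K matrix and is verified
# against finite differences in the tests.  A tiny seeded jitter
# (sd 1e-8) is added to A during training to keep eigenvalue gaps away
# from zero.

head_forward <- function(f_support, f_query, support_class, query_class,
                         n_way, rank, lambda_reg, jitter = TRUE) {
  nq <- nrow(f_query)
  dists <- matrix(0, nq, n_way)
  cls <- vector("list", n_way)
  zq <- t(f_query) # D x NQ
  for (c in seq_len(n_way)) {
    xc <- f_support[support_class == c, , drop = FALSE] # K x D
    k <- nrow(xc)
    mu <- colMeans(xc)
    a <- t(xc) - mu
    if (jitter) a <- a + matrix(stats::rnorm(length(a), sd = 1e-8),
                                nrow(a), ncol(a))
    s <- crossprod(a)
    eg <- eigen(s, symmetric = TRUE) # decreasing eigenvalues
    lam <- pmax(eg$values[seq_len(rank)], 1e-12)
    v <- eg$vectors[, seq_len(rank), drop = FALSE]
    p <- a %*% sweep(v, 2, sqrt(lam), `/`)
    zc <- zq - mu
    u <- crossprod(p, zc) # r x NQ
    dists[, c] <- -(colSums(zc^2) - colSums(u^2))
    cls[[c]] <- list(mu = mu, a = a, eg = eg, lam = lam, v = v, p = p,
                     zc = zc, u = u, k = k, rows = which(support_class == c))
  }
  probs <- class_probabilities(dists)
  ce <- -mean(log(pmax(probs[cbind(seq_len(nq), query_class)], 1e-300)))
  reg <- 0
  if (lambda_reg > 0) {
    for (i in seq_len(n_way - 1))
      for (j in (i + 1):n_way)
        reg <- reg + 2 * sum(crossprod(cls[[i]]$p, cls[[j]]$p)^2)
  }
  pred <- max.col(dists, ties.method = "first")
  list(loss = ce + lambda_reg * reg, ce = ce, reg = reg,
       probs = probs, dists = dists, pred = pred, cls = cls,
       accuracy = mean(pred == query_class))
}

# Adjoint of the symmetric eigendecomposition S = V diag(lam) V^T,
# given gradients w.r.t. the first r eigenvectors/values.
eigh_backward <- function(eg, dv_r, dlam_r) {
  k <- length(eg$values)
  r <- ncol(dv_r)
  dv <- matrix(0, k, k); dv[, seq_len(r)] <- dv_r
  dlam <- numeric(k); dlam[seq_len(r)] <- dlam_r
  vt_dv <- crossprod(eg$vectors, dv)
  gap <- outer(eg$values, eg$values, function(a, b) b - a) # [i,j] = l_j - l_i
  f <- ifelse(abs(gap) < 1e-12, 0, 1 / gap)
  diag(f) <- 0
  eg$vectors %*% (f * vt_dv + diag(dlam, k)) %*% t(eg$vectors)
}

head_backward <- function(hf, f_support, f_query, query_class, n_way,
                          rank, lambda_reg) {
  nq <- nrow(f_query)
  d_dists <- hf$probs
  d_dists[cbind(seq_len(nq), query_class)] <-
    d_dists[cbind(seq_len(nq), query_class)] - 1
  d_dists <- d_dists / nq
  df_query <- matrix(0, nq, ncol(f_query))
  df_support <- matrix(0, nrow(f_support), ncol(f_support))
  for (c in seq_len(n_way)) {
    cl <- hf$cls[[c]]
    g <- d_dists[, c]
    # distance gradients: d = -(||z||^2 - ||P^T z||^2)
    w_q <- -2 * cl$zc + 2 * (cl$p %*% cl$u) # D x NQ, per-query d d/d f_q
    df_query <- df_query + t(w_q) * g
    g_mu <- -as.numeric(w_q %*% g)
    g_p <- 2 * (cl$zc %*% (g * t(cl$u))) # D x r
    # regularizer gradient
    if (lambda_reg > 0) {
      for (j in seq_len(n_way)) {
        if (j == c) next
        pj <- hf$cls[[j]]$p
        cij <- crossprod(cl$p, pj) # r x r
        g_p <- g_p + lambda_reg * 4 * pj %*% t(cij)
      }
    }
    # back through P = A V_r lam_r^{-1/2}
    inv_sqrt <- 1 / sqrt(cl$lam)
    da <- g_p %*% (t(cl$v) * inv_sqrt)
    av <- cl$a %*% cl$v # D x r
    dv_r <- crossprod(cl$a, g_p) * rep(inv_sqrt, each = cl$k)
    dlam_r <- colSums(g_p * av) * (-0.5) * cl$lam^(-1.5)
    ds <- eigh_backward(cl$eg, dv_r, dlam_r)
    da <- da + cl$a %*% (ds + t(ds))
    # A = t(Xc) - mu 1^T, mu = rowMeans of t(Xc)
    dxc <- t(da - rowMeans(da) + g_mu / cl$k)
    df_support[cl$rows, ] <- df_support[cl$rows, ] + dxc
    # mu also enters the query offsets z = f - mu
    # (already in g_mu above); nothing further
  }
  list(df_support = df_support, df_query = df_query)
}

adam_init <- function(params)
  list(t = 0, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

#' Train the few-shot model episodically
#'
#' Per epoch, `episodes_per_epoch` episodes are sampled and one Adam
#' step is taken per episode on the episode loss (query cross-entropy
#' plus the subspace-overlap regularizer).  Fully reproducible from
#' `config$seed`.
#'
#' @param items List of labeled [thickness_image()]s.
#' @param config A [few_shot_config()].
#' @param encoder Optional [conv4_encoder()]; initialized from the
#'   config seed when `NULL`.
#' @param encoder_args Arguments for [conv4_encoder()] when building the
#'   default encoder (e.g. `filters`, `dropout`, `input_pool`).
#' @param verbose Print per-epoch progress.
#' @return Object of class `fewshot_model`: `encoder`, `config`,
#'   `classes`, and `history` (per-epoch mean loss and query accuracy).
#' @export
train_fewshot <- function(items, config = few_shot_config(),
                          encoder = NULL, encoder_args = list(),
                          verbose = FALSE) {
  set.seed(config$seed)
  if (is.null(encoder)) {
    d <- dim(items[[1]]$pixels)
    encoder <- do.call(conv4_encoder,
                       c(list(input_shape = d), encoder_args))
  }
  classes <- sort(unique(item_conditions(items)))
  # without augmentation the encoder input of each item never changes, so
  # scaling and input pooling are done once up front
  pre <- if (!config$augment)
    lapply(items, function(im)
      preprocess_pixels(im$pixels, encoder$cfg$input_pool))
  opt <- adam_init(encoder$params)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        query_accuracy = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    losses <- numeric(config$episodes_per_epoch)
    accs <- numeric(config$episodes_per_epoch)
    for (e in seq_len(config$episodes_per_epoch)) {
      ep <- sample_episode(items, config)
      if (config$augment) {
        im <- lapply(c(ep$support, ep$query), coarse_dropout_augment)
        x <- images_to_batch(im)
      } else {
        x <- batch_from_cache(pre, c(ep$support_idx, ep$query_idx))
      }
      fw <- encoder_forward(encoder, x, train = TRUE, keep_cache = TRUE)
      encoder$state <- fw$state
      ns <- length(ep$support)
      f_s <- fw$features[seq_len(ns), , drop = FALSE]
      f_q <- fw$features[ns + seq_along(ep$query), , drop = FALSE]
      hf <- head_forward(f_s, f_q, ep$support_class, ep$query_class,
                         config$n_way, config$subspace_rank,
                         config$lambda_reg, jitter = TRUE)
      hb <- head_backward(hf, f_s, f_q, ep$query_class, config$n_way,
                          config$subspace_rank, config$lambda_reg)
      grads <- encoder_backward(encoder, fw$cache,
                                rbind(hb$df_support, hb$df_query))
      upd <- adam_step(encoder$params, grads, opt, config$learning_rate)
      encoder$params <- upd$params
      opt <- upd$state
      losses[e] <- hf$loss
      accs[e] <- hf$accuracy
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, mean_loss = mean(losses),
                                query_accuracy = mean(accs)))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  acc %.3f", epoch,
                      config$epochs, mean(losses), mean(accs)))
  }
  structure(list(encoder = encoder, config = config, classes = classes,
                 history = history), class = "fewshot_model")
}

#' @export
print.fewshot_model <- function(x, ...) {
  cat("<fewshot_model>", x$config$n_way, "way /", x$config$k_shot,
      "shot | classes:", paste(x$classes, collapse = ", "), "\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat("  trained", nrow(x$history), "epochs; final loss",
        sprintf("%.4f", last$mean_loss), "query acc",
        sprintf("%.3f", last$query_accuracy), "\n")
  }
  invisible(x)
}

classify_features <- function(feat_query, subspaces) {
  dists <- vapply(subspaces, function(s)
    apply(feat_query, 1, subspace_distance, subspace = s),
    numeric(nrow(feat_query)))
  if (!is.matrix(dists)) dists <- matrix(dists, nrow = 1)
  max.col(dists, ties.method = "first")
}

#' Predict per-patient labels by majority voting over episodes
#'
#' Over `n_episodes` evaluation episodes a fresh support sample
#' (`k_shot` per class) is drawn from `support_items`, class subspaces
#' are rebuilt, and a random selection of `queries_per_episode` query
#' images is classified by residual distance.  Each patient's label is
#' the modal prediction over all episodes, ties broken toward the lowest
#' class index.  Patients left unsampled by chance are classified in
#' additional sweeps so every patient receives at least one vote.
#'
#' @param model A [train_fewshot()] result.
#' @param support_items Labeled [thickness_image()]s covering every class
#'   with at least `k_shot` items.
#' @param query_items [thickness_image()]s to classify (one per patient;
#'   labels, if present, are ignored).
#' @param n_episodes Number of evaluation episodes.
#' @param queries_per_episode Queries sampled per episode (default 25).
#' @return `data.frame` with `patient_id`, `predicted_class`, `votes`,
#'   `total_votes`; the full patient-by-class vote matrix is attached as
#'   attribute `"vote_matrix"`.
#' @export
predict_majority_vote <- function(model, support_items, query_items,
                                  n_episodes = 100L,
                                  queries_per_episode = 25L) {
  stopifnot(inherits(model, "fewshot_model"))
  cfg <- model$config
  classes <- model$classes
  sup_cond <- item_conditions(support_items)
  for (cl in classes)
    if (sum(sup_cond == cl) < cfg$k_shot)
      stop("support set has fewer than ", cfg$k_shot, " items of class ", cl)
  ids <- vapply(query_items, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stop("duplicated patient IDs in query set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  f_sup <- encoder_forward(model$encoder, support_items)$features
  f_qry <- encoder_forward(model$encoder, query_items)$features
  votes <- matrix(0L, length(query_items), length(classes),
                  dimnames = list(ids, classes))
  run_episode <- function(q_idx) {
    subspaces <- lapply(seq_along(classes), function(ci) {
      pool <- which(sup_cond == classes[ci])
      pick <- pool[sample(length(pool), cfg$k_shot)]
      build_class_subspace(f_sup[pick, , drop = FALSE],
                           cfg$subspace_rank, class_id = classes[ci])
    })
    pred <- classify_features(f_qry[q_idx, , drop = FALSE], subspaces)
    for (i in seq_along(q_idx))
      votes[q_idx[i], pred[i]] <<- votes[q_idx[i], pred[i]] + 1L
  }
  nq <- length(query_items)
  for (e in seq_len(n_episodes))
    run_episode(sample(nq, min(queries_per_episode, nq)))
  unvoted <- which(rowSums(votes) == 0)
  while (length(unvoted) > 0) {
    run_episode(unvoted)
    unvoted <- which(rowSums(votes) == 0)
  }
  pred_idx <- max.col(votes, ties.method = "first")
  out <- data.frame(patient_id = ids,
                    predicted_class = classes[pred_idx],
                    votes = votes[cbind(seq_len(nq), pred_idx)],
                    total_votes = rowSums(votes),
                    stringsAsFactors = FALSE)
  attr(out, "vote_matrix") <- votes
  out
}

#' Ensemble per-patient labels across runs
#'
#' Per patient, the modal label across runs; ties broken toward the
#' lowest class index.  All runs must cover the same patients.
#'
#' @param per_run_labels List of `data.frame`s with `patient_id` and
#'   `predicted_class` (one per trained run).
#' @param classes Class ordering used for tie-breaking (default
#'   [condition_classes()]).
#' @return `data.frame` with `patient_id`, `predicted_class`.
#' @export
ensemble_predict <- function(per_run_labels,
                             classes = condition_classes()) {
  stopifnot(is.list(per_run_labels), length(per_run_labels) >= 1)
  ref <- sort(per_run_labels[[1]]$patient_id)
  for (r in per_run_labels)
    if (!identical(sort(r$patient_id), ref))
      stop("runs cover different patient sets")
  ids <- per_run_labels[[1]]$patient_id
  lab <- vapply(per_run_labels, function(r)
    r$predicted_class[match(ids, r$patient_id)], character(length(ids)))
  lab <- matrix(lab, nrow = length(ids))
  pick <- apply(lab, 1, function(v) {
    v <- factor(v, levels = union(classes, v))
    names(which.max(table(v)))
  })
  data.frame(patient_id = ids, predicted_class = pick,
             stringsAsFactors = FALSE)
}

#' Accuracy and confusion matrix of predictions
#'
#' @param predictions `data.frame` with `patient_id`, `predicted_class`.
#' @param labels `data.frame` with `patient_id`, `condition`.
#' @return List with `accuracy` and `confusion` (true class in rows).
#' @export
evaluate_predictions <- function(predictions, labels) {
  m <- merge(predictions, labels, by = "patient_id")
  if (nrow(m) < nrow(predictions))
    stop("labels missing for ",
         paste(setdiff(predictions$patient_id, labels$patient_id),
               collapse = ", "))
  lv <- sort(union(m$condition, m$predicted_class))
  conf <- table(factor(m$condition, lv), factor(m$predicted_class, lv))
  names(dimnames(conf)) <- c("true", "predicted")
  list(accuracy = mean(m$condition == m$predicted_class),
       confusion = conf)
}

#' Save / load a trained model checkpoint
#'
#' Versioned JSON container holding the config, class order, encoder
#' configuration, parameters and batch-norm state at full precision.
#'
#' @param model A [train_fewshot()] result.
#' @param path Checkpoint file path (JSON).
#' @return `save_checkpoint`: `path`, invisibly.  `load_checkpoint`: the
#'   restored `fewshot_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fewshot_model"))
  enc <- model$encoder
  payload <- list(
    format = "thickshot-checkpoint", version = 1L,
    config = unclass(model$config), classes = model$classes,
    encoder = list(cfg = enc$cfg, dim = enc$dim,
                   params = lapply(enc$params, function(p)
                     list(dim = dim(p) %||% length(p), data = as.numeric(p))),
                   state = enc$state),
    history = model$history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "thickshot-checkpoint"))
    stop("not a thickshot checkpoint: ", path)
  params <- lapply(j$encoder$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  enc <- structure(list(cfg = list(
    input_shape = as.integer(j$encoder$cfg$input_shape),
    filters = as.integer(j$encoder$cfg$filters),
    dropout = j$encoder$cfg$dropout,
    input_pool = as.integer(j$encoder$cfg$input_pool)),
    params = params,
    state = lapply(j$encoder$state, as.numeric),
    dim = as.integer(j$encoder$dim)), class = "conv4_encoder")
  cfg <- do.call(few_shot_config, j$config[setdiff(names(j$config), NULL)])
  structure(list(encoder = enc, config = cfg, classes = j$classes,
                 history = as.data.frame(j$history)),
            class = "fewshot_model")
}
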
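# Conv4 feature encoder in base R with an analytic backward pass.
#
# Internal batch layout is (H, W, B, C): the first three axes are
# contiguous, so an (H*W*B) x C matrix view needs no copy and 3x3 "same"
# convolution reduces to nine contiguous slice extractions plus one BLAS
# matrix multiply (im2col).  Each block is convolution -> batch norm ->
# ReLU -> 2x2 max pool; the last feature map is flattened to a D-vector,
# with optional dropout before the output.  All gradients are exercised
# against central finite differences in the test suite.

conv_pad <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2, d[2] + 2, d[3], d[4]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), , ] <- x
  xp
}

# offsets in column order j = 1..9: (dh, dw), dh fastest
CONV_OFFSETS <- as.matrix(expand.grid(dh = -1:1, dw = -1:1))

im2col <- function(xp, h, w) {
  b <- dim(xp)[3]; cc <- dim(xp)[4]
  n <- h * w * b
  pm <- matrix(0, n, 9 * cc)
  for (j in 1:9) {
    dh <- CONV_OFFSETS[j, 1]; dw <- CONV_OFFSETS[j, 2]
    s <- xp[(2 + dh):(h + 1 + dh), (2 + dw):(w + 1 + dw), , , drop = FALSE]
    dim(s) <- c(n, cc)
    pm[, (j - 1) * cc + seq_len(cc)] <- s
  }
  pm
}

conv_forward <- function(x, wmat, bias) {
  d <- dim(x)
  pm <- im2col(conv_pad(x), d[1], d[2])
  y <- pm %*% wmat
  y <- y + rep(bias, each = nrow(pm))
  list(y = array(y, c(d[1], d[2], d[3], ncol(wmat))), pm = pm)
}

conv_backward <- function(dy, pm, wmat, in_dim, need_dx = TRUE) {
  h <- in_dim[1]; w <- in_dim[2]; b <- in_dim[3]; cc <- in_dim[4]
  n <- h * w * b
  dym <- dy; dim(dym) <- c(n, ncol(wmat))
  dw <- crossprod(pm, dym)
  db <- colSums(dym)
  if (!need_dx) return(list(dx = NULL, dw = dw, db = db))
  dpm <- dym %*% t(wmat)
  dxp <- array(0, c(h + 2, w + 2, b, cc))
  for (j in 1:9) {
    dh <- CONV_OFFSETS[j, 1]; dw_ <- CONV_OFFSETS[j, 2]
    blk <- dpm[, (j - 1) * cc + seq_len(cc)]
    dim(blk) <- c(h, w, b, cc)
    dxp[(2 + dh):(h + 1 + dh), (2 + dw_):(w + 1 + dw_), , ] <-
      dxp[(2 + dh):(h + 1 + dh), (2 + dw_):(w + 1 + dw_), , ] + blk
  }
  list(dx = dxp[2:(h + 1), 2:(w + 1), , , drop = FALSE], dw = dw, db = db)
}

BN_EPS <- 1e-5

bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- x; dim(xm) <- c(n, d[4])
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    va <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean; va <- run_var
    xc <- xm - rep(mu, each = n)
  }
  ivstd <- 1 / sqrt(va + BN_EPS)
  xhat <- xc * rep(ivstd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(y) <- d
  list(y = y, xhat = xhat, ivstd = ivstd, run_mean = run_mean,
       run_var = run_var, train = train)
}

bn_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- prod(d[1:3])
  dym <- dy; dim(dym) <- c(n, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = n)
  if (cache$train) {
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
      rep(cache$ivstd, each = n)
  } else {
    dx <- dxhat * rep(cache$ivstd, each = n)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
  oi <- seq(1, 2 * h2, by = 2); oj <- seq(1, 2 * w2, by = 2)
  n <- h2 * w2 * d[3] * d[4]
  m <- cbind(as.vector(x[oi, oj, , , drop = FALSE]),
             as.vector(x[oi + 1, oj, , , drop = FALSE]),
             as.vector(x[oi, oj + 1, , , drop = FALSE]),
             as.vector(x[oi + 1, oj + 1, , , drop = FALSE]))
  arg <- max.col(m, ties.method = "first")
  y <- m[cbind(seq_len(n), arg)]
  dim(y) <- c(h2, w2, d[3], d[4])
  list(y = y, arg = arg, in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
  n <- h2 * w2 * d[3] * d[4]
  dm <- matrix(0, n, 4)
  dm[cbind(seq_len(n), cache$arg)] <- as.vector(dy)
  dx <- array(0, d)
  oi <- seq(1, 2 * h2, by = 2); oj <- seq(1, 2 * w2, by = 2)
  dx[oi, oj, , ] <- array(dm[, 1], c(h2, w2, d[3], d[4]))
  dx[oi + 1, oj, , ] <- array(dm[, 2], c(h2, w2, d[3], d[4]))
  dx[oi, oj + 1, , ] <- array(dm[, 3], c(h2, w2, d[3], d[4]))
  dx[oi + 1, oj + 1, , ] <- array(dm[, 4], c(h2, w2, d[3], d[4]))
  dx
}

avgpool2 <- function(x) {
  d <- dim(x)
  oi <- seq(1, d[1] - 1, by = 2); oj <- seq(1, d[2] - 1, by = 2)
  (x[oi, oj, , , drop = FALSE] + x[oi + 1, oj, , , drop = FALSE] +
     x[oi, oj + 1, , , drop = FALSE] + x[oi + 1, oj + 1, , , drop = FALSE]) / 4
}

#' Conv4 feature encoder
#'
#' Four blocks of (3x3 same convolution, batch normalization, ReLU,
#' 2x2 max pool), flattened to a fixed-length feature vector, with
#' optional dropout before the output.  `input_pool` average-pools the
#' input by that factor first — a cheap way to train on reduced image
#' resolution without changing the thickness-image contract.
#'
#' @param input_shape `(rows, cols, channels)` of the input images;
#'   `rows/input_pool` and `cols/input_pool` must be divisible by 16.
#' @param filters Four filter counts, one per block.
#' @param dropout Dropout rate in `[0, 1)` applied before the output in
#'   training mode (0 disables).
#' @param input_pool Input average-pooling factor (power of 2).
#' @param seed Optional seed for weight initialization (He normal).
#' @return Object of class `conv4_encoder` with fields `cfg`, `params`,
#'   `state` and feature dimension `dim`.
#' @export
conv4_encoder <- function(input_shape = c(128L, 64L, 3L),
                          filters = c(16L, 32L, 64L, 64L),
                          dropout = 0, input_pool = 1L, seed = NULL) {
  stopifnot(length(input_shape) == 3, length(filters) == 4,
            dropout >= 0, dropout < 1, input_pool >= 1,
            bitwAnd(as.integer(input_pool), as.integer(input_pool) - 1L) == 0)
  hw <- input_shape[1:2] / input_pool
  if (any(hw != floor(hw)) || any(hw %% 16 != 0))
    stop("input shape ", paste(input_shape[1:2], collapse = "x"),
         " with input_pool ", input_pool,
         " must leave sides divisible by 16")
  with_seed(seed, {
    chans <- c(input_shape[3], filters)
    params <- list(); state <- list()
    for (l in 1:4) {
      fan_in <- 9 * chans[l]
      params[[paste0("w", l)]] <- matrix(
        stats::rnorm(fan_in * chans[l + 1], sd = sqrt(2 / fan_in)),
        fan_in, chans[l + 1])
      params[[paste0("b", l)]] <- numeric(chans[l + 1])
      params[[paste0("gamma", l)]] <- rep(1, chans[l + 1])
      params[[paste0("beta", l)]] <- numeric(chans[l + 1])
      state[[paste0("mean", l)]] <- numeric(chans[l + 1])
      state[[paste0("var", l)]] <- rep(1, chans[l + 1])
    }
    d <- as.integer(prod(hw / 16) * filters[4])
    structure(list(cfg = list(input_shape = as.integer(input_shape),
                              filters = as.integer(filters),
                              dropout = dropout,
                              input_pool = as.integer(input_pool)),
                   params = params, state = state, dim = d),
              class = "conv4_encoder")
  })
}

#' @export
print.conv4_encoder <- function(x, ...) {
  cat("<conv4_encoder>", paste(x$cfg$input_shape, collapse = "x"),
      "-> D =", x$dim, "| filters", paste(x$cfg$filters, collapse = "/"),
      "| dropout", x$cfg$dropout, "| input_pool", x$cfg$input_pool, "\n")
  invisible(x)
}

# Stack thickness images into an (H, W, B, C) batch scaled to [0, 1].
images_to_batch <- function(images) {
  d <- dim(images[[1]]$pixels)
  x <- array(0, c(d[1], d[2], length(images), d[3]))
  for (i in seq_along(images))
    x[, , i, ] <- images[[i]]$pixels / 255
  x
}

# Scale to [0, 1] and apply the encoder's input pooling to one image;
# used to cache preprocessed inputs across episodes.
preprocess_pixels <- function(pixels, input_pool) {
  d <- dim(pixels)
  x <- array(0, c(d[1], d[2], 1, d[3]))
  x[, , 1, ] <- pixels / 255
  f <- input_pool
  while (f > 1) { x <- avgpool2(x); f <- f / 2 }
  array(x[, , 1, ], dim(x)[c(1, 2, 4)])
}

batch_from_cache <- function(pre, idx) {
  d <- dim(pre[[1]])
  x <- array(0, c(d[1], d[2], length(idx), d[3]))
  for (b in seq_along(idx)) x[, , b, ] <- pre[[idx[b]]]
  x
}

#' Encoder forward pass
#'
#' @param encoder A [conv4_encoder()].
#' @param x `(H, W, B, C)` batch array (see `images_to_batch`) or a list
#'   of [thickness_image()]s.
#' @param train Training mode: batch-norm uses batch statistics (and
#'   updates the running averages in the returned `state`) and dropout is
#'   active.  In evaluation mode the pass is deterministic.
#' @param keep_cache Keep intermediates for [encoder_backward()].
#' @return List with `features` (`B x D` matrix), updated `state`, and
#'   (if requested) `cache`.
#' @export
encoder_forward <- function(encoder, x, train = FALSE, keep_cache = FALSE) {
  if (is.list(x) && !is.array(x)) x <- images_to_batch(x)
  cfg <- encoder$cfg; p <- encoder$params; st <- encoder$state
  if (dim(x)[1] == cfg$input_shape[1]) {
    f <- cfg$input_pool
    while (f > 1) { x <- avgpool2(x); f <- f / 2 }
  } else if (dim(x)[1] != cfg$input_shape[1] / cfg$input_pool) {
    stop("batch height ", dim(x)[1], " matches neither the input shape ",
         "nor its pooled size")
  }
  cache <- list()
  for (l in 1:4) {
    cv <- conv_forward(x, p[[paste0("w", l)]], p[[paste0("b", l)]])
    bn <- bn_forward(cv$y, p[[paste0("gamma", l)]], p[[paste0("beta", l)]],
                     st[[paste0("mean", l)]], st[[paste0("var", l)]], train)
    st[[paste0("mean", l)]] <- bn$run_mean
    st[[paste0("var", l)]] <- bn$run_var
    relu_mask <- bn$y > 0
    act <- bn$y * relu_mask
    mp <- maxpool_forward(act)
    if (keep_cache)
      cache[[l]] <- list(in_dim = dim(x), pm = cv$pm, bn = bn,
                         relu_mask = relu_mask, mp = mp)
    x <- mp$y
  }
  d <- dim(x) # (h, w, B, C)
  feat <- aperm(x, c(1, 2, 4, 3)) # (h, w, C, B): per-image vector contiguous
  dim(feat) <- c(d[1] * d[2] * d[4], d[3])
  features <- t(feat)
  drop_mask <- NULL
  if (train && cfg$dropout > 0) {
    drop_mask <- matrix(stats::runif(length(features)) >= cfg$dropout,
                        nrow(features), ncol(features))
    features <- features * drop_mask / (1 - cfg$dropout)
  }
  out <- list(features = features, state = st)
  if (keep_cache)
    out$cache <- list(layers = cache, out_dim = d, drop_mask = drop_mask,
                      dropout = cfg$dropout)
  out
}

#' Encoder backward pass
#'
#' @param encoder A [conv4_encoder()].
#' @param cache `cache` from [encoder_forward()] with `keep_cache = TRUE`.
#' @param dfeatures Gradient of the loss w.r.t. the `B x D` features.
#' @return Named list of parameter gradients matching `encoder$params`.
#' @export
encoder_backward <- function(encoder, cache, dfeatures) {
  p <- encoder$params
  if (!is.null(cache$drop_mask))
    dfeatures <- dfeatures * cache$drop_mask / (1 - cache$dropout)
  d <- cache$out_dim
  dx <- t(dfeatures)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(dx, c(1, 2, 4, 3))
  grads <- list()
  for (l in 4:1) {
    ly <- cache$layers[[l]]
    dact <- maxpool_backward(dx, ly$mp)
    dbn_out <- dact * ly$relu_mask
    bnb <- bn_backward(dbn_out, ly$bn, p[[paste0("gamma", l)]])
    cvb <- conv_backward(bnb$dx, ly$pm, p[[paste0("w", l)]], ly$in_dim,
                         need_dx = l > 1)
    grads[[paste0("w", l)]] <- cvb$dw
    grads[[paste0("b", l)]] <- cvb$db
    grads[[paste0("gamma", l)]] <- bnb$dgamma
    grads[[paste0("beta", l)]] <- bnb$dbeta
    dx <- cvb$dx
  }
  grads
}
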
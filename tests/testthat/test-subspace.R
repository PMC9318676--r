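test_that("sample_episode partitions classes per the episodic protocol", {
  items <- dummy_items(20)
  cfg <- few_shot_config()
  withr::with_seed(9, {
    ep <- sample_episode(items, cfg)
    expect_length(ep$support, 25) # 25 support + 25 query at defaults
    expect_length(ep$query, 25)
    expect_identical(ep$support_class, rep(1:5, each = 5))
    # support and query are disjoint per class
    expect_length(intersect(ep$support_idx, ep$query_idx), 0)
  })
  e1 <- withr::with_seed(10, sample_episode(items, cfg))
  e2 <- withr::with_seed(10, sample_episode(items, cfg))
  expect_identical(e1, e2)
  expect_error(sample_episode(dummy_items(6), cfg), "needs at least")
})

test_that("build_class_subspace recovers spans and stays orthonormal", {
  set.seed(21)
  for (trial in 1:10) {
    k <- sample(3:6, 1); d <- sample(6:12, 1)
    f <- matrix(rnorm(k * d), k, d)
    r <- k - 1
    s <- build_class_subspace(f, r)
    expect_equal(crossprod(s$basis), diag(r), tolerance = 1e-6)
    expect_equal(s$mean, colMeans(f))
  }

  # features spanning a known 2-plane: principal angles ~ 0
  d <- 8
  plane <- random_basis(d, 2)
  coords <- matrix(rnorm(10), 5, 2)
  f <- coords %*% t(plane)
  s <- build_class_subspace(f, 2)
  sv <- svd(crossprod(s$basis, plane))$d
  expect_true(all(abs(sv - 1) < 1e-6)) # cos(principal angles) = 1

  # degenerate support: identical features -> rank-0 basis with warning
  same <- matrix(1, 4, 6)
  expect_warning(s0 <- build_class_subspace(same, 2), "numerical rank")
  expect_equal(ncol(s0$basis), 0)
  q <- rnorm(6)
  expect_equal(subspace_distance(q, s0), -sum((q - 1)^2))
})

test_that("subspace_distance matches the explicit projection-matrix oracle", {
  set.seed(33)
  for (trial in 1:100) {
    d <- 6; k <- 4; r <- sample(1:3, 1)
    f <- matrix(rnorm(k * d), k, d)
    s <- build_class_subspace(f, r)
    q <- rnorm(d)
    m_explicit <- s$basis %*% t(s$basis)
    z <- q - s$mean
    oracle <- -sum(((diag(d) - m_explicit) %*% z)^2)
    expect_equal(subspace_distance(q, s), oracle, tolerance = 1e-8)
  }
  # trivial limits
  f <- matrix(rnorm(20), 4, 5)
  s <- build_class_subspace(f, 2)
  expect_equal(subspace_distance(s$mean, s), 0)
  in_plane <- s$mean + s$basis %*% c(2, -1)
  expect_equal(subspace_distance(as.numeric(in_plane), s), 0,
               tolerance = 1e-12)
  expect_error(subspace_distance(rnorm(4), s), "dimension")
})

test_that("class_probabilities is a shift-invariant simplex map", {
  p <- class_probabilities(rep(-3, 5))
  expect_equal(p, rep(0.2, 5))
  p2 <- class_probabilities(c(0, -1e6, -1e6))
  expect_gt(p2[1], 0.999)
  d <- c(-1.2, -0.4, -7, 0)
  expect_equal(class_probabilities(d), class_probabilities(d - 7),
               tolerance = 1e-12)
  expect_equal(sum(class_probabilities(d)), 1)
  # matrix form
  m <- matrix(rnorm(12), 3, 4)
  pm <- class_probabilities(m)
  expect_equal(rowSums(pm), rep(1, 3))
})

test_that("both printed forms of the projection metric agree", {
  set.seed(44)
  mk <- function(basis) structure(
    list(mean = numeric(nrow(basis)), basis = basis, rank = ncol(basis),
         class_id = NA), class = "class_subspace")
  for (trial in 1:100) {
    d <- sample(6:10, 1); r <- sample(2:3, 1)
    a <- mk(random_basis(d, r)); b <- mk(random_basis(d, r))
    lhs <- sum((a$basis %*% t(a$basis) - b$basis %*% t(b$basis))^2)
    expect_equal(grassmann_projection_metric(a, b), lhs,
                 tolerance = 1e-8)
  }
  a <- mk(random_basis(8, 3))
  expect_equal(subspace_overlap(a, a), 3)
  expect_equal(grassmann_projection_metric(a, a), 0)
  perp <- mk(qr.Q(qr(cbind(a$basis, matrix(rnorm(40), 8, 5))))[, 4:6])
  expect_equal(subspace_overlap(a, perp), 0, tolerance = 1e-12)
  expect_equal(grassmann_projection_metric(a, perp), 2 * 3)
  expect_error(subspace_overlap(a, mk(random_basis(8, 2))), "rank")
})

test_that("episode_loss reproduces its closed-form limits", {
  mk <- function(basis) structure(
    list(mean = numeric(nrow(basis)), basis = basis, rank = ncol(basis),
         class_id = NA), class = "class_subspace")
  n_way <- 5; m <- 5; r <- 2
  uniform <- matrix(1 / n_way, n_way * m, n_way)
  labels <- rep(1:n_way, each = m)
  expect_equal(episode_loss(uniform, labels, list(), 0), log(5))

  # perfect probabilities + orthogonal subspaces -> loss 0
  perfect <- matrix(0, n_way * m, n_way)
  perfect[cbind(seq_along(labels), labels)] <- 1
  big <- qr.Q(qr(matrix(rnorm(20 * 10), 20, 10)))
  subs <- lapply(1:n_way, function(i) mk(big[, (2 * i - 1):(2 * i)]))
  expect_equal(episode_loss(perfect, labels, subs, 0.03), 0)

  # identical subspaces add lambda * r * n_way * (n_way - 1) exactly
  same <- replicate(n_way, mk(random_basis(9, r)), simplify = FALSE)
  same <- lapply(seq_len(n_way), function(i) same[[1]])
  lam <- 0.03
  expect_equal(episode_loss(perfect, labels, same, lam),
               lam * r * n_way * (n_way - 1))
})

test_that("coarse dropout zeroes 4-8 pixel positions deterministically", {
  ti <- small_items()[[1]]
  a1 <- withr::with_seed(3, coarse_dropout_augment(ti))
  a2 <- withr::with_seed(3, coarse_dropout_augment(ti))
  expect_identical(a1, a2)
  diffpos <- apply(a1$pixels != ti$pixels, c(1, 2), any)
  # 4-8 positions are zeroed; fewer differ only if a zeroed pixel was
  # already zero
  expect_lte(sum(diffpos), 8)
  expect_gte(sum(diffpos), 1)
  expect_true(all(a1$pixels[a1$pixels != ti$pixels] == 0L))
  z <- thickness_image("z", array(0L, c(128, 64, 3)))
  expect_true(all(withr::with_seed(1, coarse_dropout_augment(z))$pixels == 0))
})
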
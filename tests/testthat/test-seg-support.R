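test_that("auto_zero_pad squares images with trailing-extra balance", {
  sq <- matrix(1:100, 10, 10)
  expect_identical(auto_zero_pad(sq), sq)

  a <- matrix(1, 8, 6)
  pa <- auto_zero_pad(a)
  expect_equal(dim(pa), c(8, 8))
  expect_true(all(pa[, 1] == 0) && all(pa[, 8] == 0))
  expect_true(all(pa[, 2:7] == 1))

  b <- matrix(1, 8, 5)
  pb <- auto_zero_pad(b)
  expect_equal(dim(pb), c(8, 8))
  expect_true(all(pb[, 1] == 0))              # one leading zero column
  expect_true(all(pb[, 7:8] == 0))            # two trailing zero columns
  expect_true(all(pb[, 2:6] == 1))

  # channelled input and tall images
  cimg <- array(runif(5 * 9 * 3), c(5, 9, 3))
  pc <- auto_zero_pad(cimg)
  expect_equal(dim(pc), c(9, 9, 3))
  expect_equal(pc[3:7, , ], cimg)
})

test_that("resize_image honours the nearest and bilinear contracts", {
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  expect_identical(resize_image(lab, c(8, 8)), lab)
  up <- resize_image(lab, c(16, 16), "nearest")
  expect_setequal(unique(as.vector(up)), unique(as.vector(lab)))

  const <- matrix(7, 9, 13)
  expect_true(all(abs(resize_image(const, c(4, 30), "bilinear") - 7) < 1e-12))
  expect_true(all(resize_image(const, c(18, 5), "nearest") == 7))

  r <- matrix(runif(400), 20, 20)
  dn <- resize_image(r, c(7, 7), "bilinear")
  expect_gte(min(dn), min(r)); expect_lte(max(dn), max(r))
})

test_that("triplicate_channels copies one channel three times", {
  z <- matrix(0, 6, 4)
  t3 <- triplicate_channels(z)
  expect_equal(dim(t3), c(6, 4, 3))
  g <- matrix(runif(24), 6, 4)
  tg <- triplicate_channels(g)
  expect_identical(tg[, , 1], tg[, , 2])
  expect_identical(tg[, , 2], tg[, , 3])
  expect_error(triplicate_channels(array(0, c(4, 4, 3))), "channels")
})

test_that("ensemble_average is order-invariant and exact in trivial cases", {
  m <- make_slice_label_map(slice_geometry(c(16.5, 16.5), 6, 2, 3),
                            c(32, 32))
  s1 <- make_probability_maps(m, 0.4, seed = 1)
  s2 <- make_probability_maps(m, 0.4, seed = 2)
  s3 <- make_probability_maps(m, 0.4, seed = 3)
  expect_identical(ensemble_average(list(s1, s2, s3)),
                   ensemble_average(list(s3, s1, s2)))
  clean <- make_probability_maps(m, 0)
  expect_identical(ensemble_average(list(clean)),
                   matrix(as.integer(m), 32, 32))
  expect_identical(ensemble_average(rep(list(clean), 5)),
                   matrix(as.integer(m), 32, 32))
  expect_error(ensemble_average(list(s1, s1[1:10, , , drop = FALSE])),
               "shape")
})

test_that("postprocess_mask fills holes, keeps largest components, idempotent", {
  # solid disc with an interior background hole
  m <- make_slice_label_map(slice_geometry(c(16.5, 16.5), 8, 0, 0),
                            c(32, 32))
  holed <- m; holed[16:17, 16:17] <- 0L
  expect_identical(postprocess_mask(holed), m)

  # one large + one small RV blob: only the large survives
  two <- matrix(0L, 32, 32)
  two[5:12, 5:12] <- 1L
  two[25:26, 25:26] <- 1L
  cleaned <- postprocess_mask(two)
  expect_true(all(cleaned[25:26, 25:26] == 0L))
  expect_true(all(cleaned[5:12, 5:12] == 1L))

  # the LV cavity inside the myocardial annulus must NOT be overwritten
  anat <- make_slice_label_map(slice_geometry(c(16.5, 16.5), 6, 3, 5),
                               c(32, 32))
  expect_identical(postprocess_mask(anat), anat)

  # idempotence on a noisy map
  set.seed(8)
  noisy <- anat
  noisy[sample(length(noisy), 30)] <- sample(0:3, 30, TRUE)
  once <- postprocess_mask(noisy)
  expect_identical(postprocess_mask(once), once)
})

test_that("jaccard_loss matches hand counts and its invariants", {
  g <- matrix(0, 4, 4); p <- matrix(0, 4, 4)
  expect_equal(jaccard_loss(g, p), 0) # both empty -> perfect agreement
  g[1, 1] <- 1; p <- g
  expect_equal(jaccard_loss(g, p), 0)
  p <- matrix(0, 4, 4); p[4, 4] <- 1
  expect_equal(jaccard_loss(g, p), 1)
  # |G| = |P| = 2, |G and P| = 1  ->  1 - 1/3
  g2 <- matrix(0, 4, 4); g2[1, 1] <- 1; g2[1, 2] <- 1
  p2 <- matrix(0, 4, 4); p2[1, 2] <- 1; p2[2, 2] <- 1
  expect_equal(jaccard_loss(g2, p2), 2 / 3)
  # symmetry, bounds, soft variant
  set.seed(3)
  for (i in 1:20) {
    ga <- matrix(rbinom(16, 1, 0.4), 4, 4)
    pa <- matrix(runif(16), 4, 4)
    expect_equal(jaccard_loss(ga, pa), jaccard_loss(pa, ga))
    l <- jaccard_loss(ga, pa)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  # monotone non-increasing in the intersection at fixed |G|, |P|
  g3 <- matrix(0, 1, 6); g3[1:2] <- 1
  p_low <- matrix(0, 1, 6); p_low[3:4] <- 1   # intersection 0
  p_mid <- matrix(0, 1, 6); p_mid[2:3] <- 1   # intersection 1
  p_hi <- g3                                  # intersection 2
  expect_true(jaccard_loss(g3, p_low) > jaccard_loss(g3, p_mid))
  expect_true(jaccard_loss(g3, p_mid) > jaccard_loss(g3, p_hi))
})
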
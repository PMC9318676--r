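test_that("training-head gradients agree with finite differences", {
  hf_ <- thickshot:::head_forward
  hb_ <- thickshot:::head_backward
  set.seed(42)
  n_way <- 3; k <- 4; m <- 2; d <- 6; r <- 2; lam <- 0.05
  fs <- matrix(rnorm(n_way * k * d), n_way * k, d)
  fq <- matrix(rnorm(n_way * m * d), n_way * m, d)
  sc <- rep(1:n_way, each = k); qc <- rep(1:n_way, each = m)
  loss_of <- function(fs, fq)
    hf_(fs, fq, sc, qc, n_way, r, lam, jitter = FALSE)$loss
  hf <- hf_(fs, fq, sc, qc, n_way, r, lam, jitter = FALSE)
  hb <- hb_(hf, fs, fq, qc, n_way, r, lam)
  eps <- 1e-6
  for (i in seq_len(nrow(fs))) for (j in c(1, 4, 6)) {
    a <- fs; a[i, j] <- a[i, j] + eps
    b <- fs; b[i, j] <- b[i, j] - eps
    expect_equal(hb$df_support[i, j],
                 (loss_of(a, fq) - loss_of(b, fq)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in seq_len(nrow(fq))) for (j in c(2, 5)) {
    a <- fq; a[i, j] <- a[i, j] + eps
    b <- fq; b[i, j] <- b[i, j] - eps
    expect_equal(hb$df_query[i, j],
                 (loss_of(fs, a) - loss_of(fs, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("training head is consistent with the inference-route ops", {
  hf_ <- thickshot:::head_forward
  set.seed(13)
  n_way <- 4; k <- 5; m <- 3; d <- 10; r <- 3
  fs <- matrix(rnorm(n_way * k * d), n_way * k, d)
  fq <- matrix(rnorm(n_way * m * d), n_way * m, d)
  sc <- rep(1:n_way, each = k); qc <- rep(1:n_way, each = m)
  hf <- hf_(fs, fq, sc, qc, n_way, r, 0.03, jitter = FALSE)
  subs <- lapply(1:n_way, function(c)
    build_class_subspace(fs[sc == c, , drop = FALSE], r))
  for (q in seq_len(nrow(fq)))
    for (c in seq_len(n_way))
      expect_equal(hf$dists[q, c], subspace_distance(fq[q, ], subs[[c]]),
                   tolerance = 1e-6)
  # the head's loss equals episode_loss computed from the exposed ops
  expect_equal(hf$loss, episode_loss(hf$probs, qc, subs, 0.03),
               tolerance = 1e-6)
  # lambda = 0 reduces the loss to pure cross-entropy
  hf0 <- hf_(fs, fq, sc, qc, n_way, r, 0, jitter = FALSE)
  expect_equal(hf0$loss, hf0$ce)
})

test_that("episodic training is reproducible and reduces the loss", {
  items <- small_items()
  cfg <- tiny_config(seed = 5)
  m1 <- train_fewshot(items, cfg, encoder_args = tiny_encoder_args)
  m2 <- train_fewshot(items, cfg, encoder_args = tiny_encoder_args)
  expect_identical(m1$history, m2$history) # bitwise under the seed
  expect_identical(m1$encoder$params, m2$encoder$params)
  m3 <- train_fewshot(items, tiny_config(seed = 6),
                      encoder_args = tiny_encoder_args)
  expect_false(identical(m1$history, m3$history))

  # a slightly longer run must reduce the episode loss
  cfg2 <- few_shot_config(k_shot = 3, m_query = 2, subspace_rank = 2,
                          episodes_per_epoch = 10, epochs = 3, seed = 5)
  m4 <- train_fewshot(items, cfg2, encoder_args = tiny_encoder_args)
  expect_lt(m4$history$mean_loss[3], m4$history$mean_loss[1])
  expect_equal(nrow(m4$history), 3)
})

test_that("augmented training runs and differs from unaugmented", {
  items <- small_items()
  m1 <- train_fewshot(items, tiny_config(seed = 5, augment = TRUE),
                      encoder_args = tiny_encoder_args)
  m2 <- train_fewshot(items, tiny_config(seed = 5),
                      encoder_args = tiny_encoder_args)
  expect_false(identical(m1$encoder$params, m2$encoder$params))
})

test_that("majority voting, ensembling and evaluation behave", {
  items <- small_items()
  model <- fixture("tiny_model", function()
    train_fewshot(items, tiny_config(seed = 5),
                  encoder_args = tiny_encoder_args))
  labels <- dataset_labels(small_patients())
  set.seed(77)
  pred <- predict_majority_vote(model, items, items, n_episodes = 10,
                                queries_per_episode = 10)
  expect_setequal(pred$patient_id, labels$patient_id)
  expect_true(all(pred$total_votes >= 1)) # every patient got a vote
  votes <- attr(pred, "vote_matrix")
  expect_equal(rowSums(votes), pred$total_votes, ignore_attr = TRUE)

  # determinism of the evaluation protocol
  set.seed(77)
  pred2 <- predict_majority_vote(model, items, items, n_episodes = 10,
                                 queries_per_episode = 10)
  expect_identical(pred, pred2)

  # ensembling: counting and tie rules
  mk <- function(lab) data.frame(patient_id = c("p1", "p2"),
                                 predicted_class = lab,
                                 stringsAsFactors = FALSE)
  runs <- list(mk(c("DCM", "NOR")), mk(c("DCM", "NOR")),
               mk(c("HCM", "ARV")), mk(c("HCM", "ARV")),
               mk(c("HCM", "ARV")))
  ens <- ensemble_predict(runs)
  expect_identical(ens$predicted_class, c("HCM", "ARV"))
  # tie -> lowest class index in the fixed ordering
  tie <- ensemble_predict(list(mk(c("NOR", "DCM")), mk(c("DCM", "NOR"))))
  expect_identical(tie$predicted_class, c("DCM", "DCM"))
  # single run -> passthrough
  expect_identical(ensemble_predict(runs[1])$predicted_class,
                   runs[[1]]$predicted_class)
  expect_error(ensemble_predict(list(mk(c("a", "b")),
                                     mk(c("a", "b"))[1, ])),
               "different patient sets")

  # evaluation on perfect predictions
  perfect <- data.frame(patient_id = labels$patient_id,
                        predicted_class = labels$condition)
  ev <- evaluate_predictions(perfect, labels)
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$confusion[row(ev$confusion) != col(ev$confusion)] == 0))

  # support must cover every class with k_shot items
  few_sup <- items[item_conditions(items) != "NOR"]
  expect_error(predict_majority_vote(model, few_sup, items), "NOR")
})

test_that("checkpoints round trip a trained model", {
  model <- fixture("tiny_model", function()
    train_fewshot(small_items(), tiny_config(seed = 5),
                  encoder_args = tiny_encoder_args))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$encoder$params, model$encoder$params, tolerance = 1e-12)
  expect_identical(back$classes, model$classes)
  expect_equal(back$config$lambda_reg, model$config$lambda_reg)
  f1 <- encoder_forward(model$encoder, small_items()[1])$features
  f2 <- encoder_forward(back$encoder, small_items()[1])$features
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_error(load_checkpoint(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "checkpoint")
})
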
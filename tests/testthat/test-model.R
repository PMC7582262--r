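test_that("a tree ensemble memorises perfectly separable data", {
  data <- separable_frame(n = 100)
  fit <- train_hotspot_model(data, n_trees = 100, seed = 1)
  pred <- predict_hs_probability(fit, data)
  expect_equal(pred$predicted_class_raw, data$label)
  expect_true(all(pred$raw_hs_probability >= 0 & pred$raw_hs_probability <= 1))
  # probabilities concentrate on the correct side of 0.5
  expect_true(all(pred$raw_hs_probability[data$label == "HS"] > 0.5))
  expect_true(all(pred$raw_hs_probability[data$label == "NS"] < 0.5))
})

test_that("training and prediction are deterministic under a fixed seed", {
  data <- separable_frame(n = 80)
  p1 <- predict_hs_probability(train_hotspot_model(data, n_trees = 60, seed = 5), data)
  p2 <- predict_hs_probability(train_hotspot_model(data, n_trees = 60, seed = 5), data)
  expect_identical(p1$raw_hs_probability, p2$raw_hs_probability)
  p3 <- predict_hs_probability(train_hotspot_model(data, n_trees = 60, seed = 6), data)
  expect_false(identical(p1$raw_hs_probability, p3$raw_hs_probability))
})

test_that("duplicated input rows receive identical probabilities", {
  data <- separable_frame(n = 60)
  fit <- train_hotspot_model(data, n_trees = 50, seed = 2)
  dup <- data[c(1, 1, 2, 2), ]
  pred <- predict_hs_probability(fit, dup)
  expect_equal(pred$raw_hs_probability[1], pred$raw_hs_probability[2])
  expect_equal(pred$raw_hs_probability[3], pred$raw_hs_probability[4])
})

test_that("schema violations abort: single class, width mismatch", {
  data <- separable_frame(n = 40)
  single <- dplyr::mutate(data, label = "NS")
  expect_error(train_hotspot_model(single, n_trees = 10), "single class")
  fit <- train_hotspot_model(data, n_trees = 10, seed = 1)
  expect_error(predict_hs_probability(fit, dplyr::select(data, -signal)),
               "schema")
  reordered <- dplyr::relocate(data, noise_3, .before = signal)
  expect_error(predict_hs_probability(fit, reordered), "schema")
  expect_error(train_hotspot_model(dplyr::mutate(data, signal = NA_real_)),
               "finite")
})

test_that("permuting labels drops held-out accuracy to chance on balanced data", {
  data <- separable_frame(n = 200, seed = 11)
  train_idx <- seq_len(120)
  shuffled <- data[train_idx, ]
  withr::with_seed(13, shuffled$label <- sample(shuffled$label))
  fit <- train_hotspot_model(shuffled, n_trees = 100, seed = 3)
  pred <- predict_hs_probability(fit, data[-train_idx, ])
  acc <- mean(pred$predicted_class_raw == data$label[-train_idx])
  expect_lt(acc, 0.65)  # majority rate is 0.5 on this balanced set
})

test_that("informative features are recovered with high held-out accuracy", {
  # HS is a noisy threshold function of 3 window-averaged properties
  spec <- fixture_spec(effect_size = 6, label_noise = 0, seed = 21)
  d <- generate_hotspot_dataset(spec)
  feats <- extract_features(d$chains)
  data <- dplyr::inner_join(d$labels, feats,
                            by = c("chain_id", "position", "amino_acid"))
  n <- nrow(data)
  expect_gte(n, 550)
  withr::with_seed(1, test_idx <- sample(n, round(n / 4)))
  fit <- train_hotspot_model(data[-test_idx, ], seed = 2)
  pred <- predict_hs_probability(fit, data[test_idx, ])
  acc <- mean(pred$predicted_class_raw == data$label[test_idx])
  expect_gte(acc, 0.9)
  # the informative properties dominate the importance ranking through
  # their window-averaged versions
  top <- tidy(fit)$feature[1:10]
  informative <- paste0(rep(spec$informative_properties, each = 8),
                        c("", paste0("_w", c(2, 5, 7, 10, 25, 50, 75))))
  expect_gte(sum(top %in% informative), 3)
})

test_that("probability variance across seeds shrinks as the ensemble grows", {
  data <- separable_frame(n = 80, margin = 0.8, seed = 31)
  spread <- purrr::map_dbl(c(10, 100, 500), function(nt) {
    probs <- purrr::map(1:5, function(s) {
      fit <- train_hotspot_model(data, n_trees = nt, seed = s)
      predict_hs_probability(fit, data)$raw_hs_probability
    })
    mean(apply(do.call(cbind, probs), 1, stats::var))
  })
  expect_true(spread[2] < spread[1])
  expect_true(spread[3] < spread[2])
})

test_that("grid search returns the dominating candidate with a full score table", {
  data <- separable_frame(n = 90)
  one <- tune_hotspot_model(data, grid = tibble::tibble(n_trees = 25), folds = 3)
  expect_equal(one$best_params$n_trees, 25)
  expect_equal(nrow(one$scores), 3L)

  # a 1-tree stump on noise-dominated mtry=1 vs a proper ensemble
  grid <- tibble::tibble(n_trees = c(1, 50), mtry = c(1, 3))
  res <- tune_hotspot_model(data, grid = grid, folds = 4, seed = 2)
  expect_equal(nrow(res$scores), 8L)  # |grid| x folds
  by_cand <- tapply(res$scores$score, res$scores$candidate, mean)
  expect_equal(unname(which.max(by_cand)), 2L)
  expect_equal(res$best_params$n_trees, 50)

  expect_error(tune_hotspot_model(data, grid = grid[0, ], folds = 3),
               "at least one")
  expect_error(tune_hotspot_model(data, grid = grid, folds = 200),
               "minority-class")
})

test_that("model bundles round-trip and refuse a changed property table", {
  data <- separable_frame(n = 50)
  fit <- train_hotspot_model(data, n_trees = 20, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_hotspot_model(fit, path)
  back <- read_hotspot_model(path)
  expect_identical(predict_hs_probability(back, data)$raw_hs_probability,
                   predict_hs_probability(fit, data)$raw_hs_probability)
  altered <- amino_acid_properties()
  altered$residue_mass <- altered$residue_mass + 1
  expect_error(read_hotspot_model(path, properties = altered),
               "checksum mismatch")
})

test_that("tidy and glance summarise a fitted model", {
  data <- separable_frame(n = 60)
  fit <- train_hotspot_model(data, n_trees = 30, seed = 8)
  td <- tidy(fit)
  expect_setequal(td$feature, c("signal", paste0("noise_", 1:5)))
  expect_equal(td$feature[1], "signal")  # the separating column ranks first
  gl <- glance(fit)
  expect_equal(gl$n_train, 60L)
  expect_equal(gl$n_hs + gl$n_ns, 60L)
  expect_equal(gl$n_trees, 30)
})

test_that("baseline hook scores with conventional classifiers", {
  skip_if_not_installed("rpart")
  data <- separable_frame(n = 80)
  pred <- baseline_classifier(data, data, method = "tree", seed = 1)
  expect_true(all(pred$raw_hs_probability >= 0 & pred$raw_hs_probability <= 1))
  expect_gt(mean(pred$predicted_class_raw == data$label), 0.9)
})
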
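cal_row <- function(cal, aa) cal[cal$amino_acid == aa, ]

test_that("the correction factor is 0.50 minus the highest false-negative probability", {
  preds <- tibble::tibble(
    amino_acid = c("Y", "Y", "Y"),
    raw_hs_probability = c(0.42, 0.30, 0.70),
    label = c("HS", "NS", "HS")
  )
  cal <- fit_correction(preds)
  expect_equal(cal_row(cal, "Y")$correction, 0.08)
  expect_equal(cal_row(cal, "Y")$max_fn_prob, 0.42)
  expect_equal(cal_row(cal, "Y")$max_tn_prob, 0.30)
})

test_that("the guard blocks corrections that would create false positives", {
  # a true negative sits above the highest false negative
  preds <- tibble::tibble(amino_acid = "W",
                          raw_hs_probability = c(0.30, 0.45),
                          label = c("HS", "NS"))
  expect_equal(cal_row(fit_correction(preds), "W")$correction, 0)
  # no false negatives -> nothing to correct
  preds2 <- tibble::tibble(amino_acid = "R",
                           raw_hs_probability = c(0.8, 0.2),
                           label = c("HS", "NS"))
  expect_equal(cal_row(fit_correction(preds2), "R")$correction, 0)
  # false negatives but no true negatives: mTN treated as -Inf, guard passes
  preds3 <- tibble::tibble(amino_acid = "K",
                           raw_hs_probability = c(0.41, 0.9),
                           label = c("HS", "HS"))
  expect_equal(cal_row(fit_correction(preds3), "K")$correction, 0.09)
})

test_that("corrections are clamped to [0, 0.5] and 0 for absent amino acids", {
  preds <- tibble::tibble(amino_acid = "F",
                          raw_hs_probability = 1e-6,  # near-zero FN probability
                          label = "HS")
  cal <- fit_correction(preds)
  expect_lte(cal_row(cal, "F")$correction, 0.5)
  expect_gte(cal_row(cal, "F")$correction, 0)
  absent <- setdiff(aa_codes(), "F")
  expect_true(all(cal$correction[cal$amino_acid %in% absent] == 0))
  expect_true(all(cal$n_tuning[cal$amino_acid %in% absent] == 0L))
  expect_error(fit_correction(preds[0, ]), "empty tuning set")
  expect_error(fit_correction(dplyr::select(preds, -label)), "missing column")
})

test_that("applying a correction lifts the boundary case into the HS class", {
  cal <- fit_correction(tibble::tibble(amino_acid = "Y",
                                       raw_hs_probability = c(0.42, 0.30),
                                       label = c("HS", "NS")))
  out <- apply_correction(tibble::tibble(amino_acid = "Y",
                                         raw_hs_probability = 0.42), cal)
  expect_equal(out$corrected_hs_probability, 0.5)
  expect_equal(out$predicted_class, "HS")
  expect_equal(out$predicted_class_raw, "NS")
})

test_that("an all-zero table is the identity calibration", {
  cal <- fit_correction(tibble::tibble(amino_acid = "Y",
                                       raw_hs_probability = c(0.9, 0.1),
                                       label = c("HS", "NS")))
  expect_true(all(cal$correction == 0))
  withr::with_seed(5, preds <- tibble::tibble(
    amino_acid = sample(aa_codes(), 30, replace = TRUE),
    raw_hs_probability = runif(30)))
  out <- apply_correction(preds, cal)
  expect_equal(out$corrected_hs_probability, out$raw_hs_probability)
  expect_equal(out$predicted_class, out$predicted_class_raw)
  # the boundary tie: with no correction, raw exactly 0.5 stays NS
  tie <- apply_correction(tibble::tibble(amino_acid = "Y",
                                         raw_hs_probability = 0.5), cal)
  expect_equal(tie$predicted_class, "NS")
})

test_that("corrected probabilities stay in [0,1], monotone, and never demote an HS call", {
  withr::with_seed(8, {
    tune <- tibble::tibble(
      amino_acid = sample(c("Y", "W", "K"), 60, replace = TRUE),
      raw_hs_probability = runif(60),
      label = sample(c("HS", "NS"), 60, replace = TRUE)
    )
  })
  cal <- fit_correction(tune)
  out <- apply_correction(tune, cal)
  expect_true(all(out$corrected_hs_probability >= 0 &
                    out$corrected_hs_probability <= 1))
  expect_true(all(out$corrected_hs_probability >= out$raw_hs_probability))
  # monotone within each amino acid
  for (aa in c("Y", "W", "K")) {
    sub <- out[out$amino_acid == aa, ]
    ord <- order(sub$raw_hs_probability)
    expect_false(is.unsorted(sub$corrected_hs_probability[ord]))
  }
  # raw HS calls survive correction
  expect_true(all(out$predicted_class[out$predicted_class_raw == "HS"] == "HS"))
})

test_that("on its own tuning set a fitted table adds TPs but never FPs", {
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      tune <- tibble::tibble(
        amino_acid = sample(aa_codes(), 120, replace = TRUE),
        raw_hs_probability = round(runif(120), 2),
        label = sample(c("HS", "NS"), 120, replace = TRUE, prob = c(0.3, 0.7))
      )
    })
    cal <- fit_correction(tune)
    out <- apply_correction(tune, cal)
    before <- confusion_counts(out$predicted_class_raw, out$label)
    after <- confusion_counts(out$predicted_class, out$label)
    expect_lte(after$fp, before$fp)
    expect_gte(after$tp, before$tp)
  }
})

test_that("calibration tables round-trip through JSON", {
  withr::with_seed(12, {
    tune <- tibble::tibble(amino_acid = sample(c("Y", "H", "C"), 40, replace = TRUE),
                           raw_hs_probability = runif(40),
                           label = sample(c("HS", "NS"), 40, replace = TRUE))
  })
  cal <- fit_correction(tune)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(cal))
  expect_s3_class(back, "hotspot_calibration")
})

test_that("calibration wrapper refuses tuning rows seen in training", {
  data <- separable_frame(n = 60)
  fit <- train_hotspot_model(data, n_trees = 20, seed = 1)
  expect_error(calibrate_hotspot_model(fit, data[1:10, ]), "overlaps")
  fresh <- separable_frame(n = 60, seed = 99)
  fresh$position <- fresh$position + 1000  # distinct residue keys
  cal <- calibrate_hotspot_model(fit, fresh)
  expect_s3_class(cal, "hotspot_calibration")
})
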
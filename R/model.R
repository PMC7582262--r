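METADATA_COLS <- c("chain_id", "position", "amino_acid", "label", "partition", "ddg")

# split a features+label tibble into X matrix / y factor / metadata
split_feature_frame <- function(data, require_label = TRUE) {
  if (require_label && !"label" %in% names(data)) {
    abort("`data` must contain a `label` column ('HS'/'NS')")
  }
  feat_cols <- setdiff(names(data), METADATA_COLS)
  if (length(feat_cols) == 0) abort("`data` contains no feature columns")
  X <- as.matrix(data[feat_cols])
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("Feature columns must be finite numerics")
  }
  list(X = X,
       y = if ("label" %in% names(data)) factor(data$label, levels = c("HS", "NS")),
       meta = data[intersect(METADATA_COLS, names(data))],
       feature_names = feat_cols)
}

#' Train the extremely-randomized-trees hot-spot classifier
#'
#' Fits an ensemble of extremely randomized trees (split thresholds drawn
#' fully at random, one random threshold per candidate feature) on per-residue
#' feature vectors, predicting the hot-spot (HS) class. Defaults follow the
#' pipeline's tuned configuration: 500 trees, bootstrap replicas per tree, and
#' balanced class weighting (case weights inversely proportional to class
#' frequencies) to counter the roughly 1:3 HS:NS imbalance of alanine-scanning
#' datasets. Remaining tree settings are frozen, documented defaults:
#' unlimited depth, `sqrt(p)` candidate features per split, minimum node size
#' 1.
#'
#' @param data Tibble holding the feature columns (anything outside
#'   `chain_id`, `position`, `amino_acid`, `label`, `partition`, `ddg`) plus a
#'   `label` column with values `"HS"`/`"NS"`. Typically
#'   [extract_features()] output joined with labels.
#' @param n_trees Number of trees (default 500).
#' @param bootstrap Train each tree on a bootstrap replica (default `TRUE`)
#'   rather than the full training set.
#' @param class_weighting `"balanced"` (default) or `"none"`.
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param min_node_size Minimum node size (default 1).
#' @param seed Integer seed; fixes the ensemble exactly.
#' @return A `hotspot_model` holding the fitted ensemble, the frozen feature
#'   order, the parameters, a per-(amino acid, label) training fingerprint and
#'   the training residue keys (used downstream to detect leakage).
#' @export
train_hotspot_model <- function(data,
                                n_trees = 500,
                                bootstrap = TRUE,
                                class_weighting = c("balanced", "none"),
                                mtry = NULL,
                                min_node_size = 1,
                                seed = 1) {
  class_weighting <- match.arg(class_weighting)
  if (n_trees < 1) abort("`n_trees` must be >= 1")
  parts <- split_feature_frame(data)
  y <- parts$y
  if (any(is.na(y))) abort("Labels must be 'HS' or 'NS'")
  if (dplyr::n_distinct(y) < 2) {
    abort("Training labels contain a single class; both HS and NS are required")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(parts$X))))

  w <- if (class_weighting == "balanced") {
    (length(y) / (2 * table(y)))[as.character(y)]
  } else {
    rep(1, length(y))
  }

  forest <- ranger::ranger(
    x = as.data.frame(parts$X), y = y,
    num.trees = n_trees,
    mtry = mtry,
    min.node.size = min_node_size,
    splitrule = "extratrees",
    num.random.splits = 1,
    replace = bootstrap,
    sample.fraction = 1,
    case.weights = as.numeric(w),
    probability = TRUE,
    importance = "impurity",
    respect.unordered.factors = "ignore",
    seed = as.integer(seed),
    num.threads = 1
  )

  fingerprint <- if (all(c("amino_acid", "label") %in% names(parts$meta))) {
    count(parts$meta, .data$amino_acid, .data$label)
  }
  keys <- if (all(c("chain_id", "position") %in% names(parts$meta))) {
    residue_keys(parts$meta)
  }

  structure(list(forest = forest,
                 feature_names = parts$feature_names,
                 params = list(n_trees = n_trees, bootstrap = bootstrap,
                               class_weighting = class_weighting, mtry = mtry,
                               min_node_size = min_node_size, seed = as.integer(seed)),
                 training_fingerprint = fingerprint,
                 training_keys = keys,
                 n_train = length(y)),
            class = "hotspot_model")
}

residue_keys <- function(meta) paste(meta$chain_id, meta$position, sep = ":")

#' @export
print.hotspot_model <- function(x, ...) {
  cat(sprintf(paste0("<hotspot_model> extremely randomized trees: %d trees, ",
                     "mtry %d, %s class weighting, %d training residues, %d features\n"),
              x$params$n_trees, x$params$mtry, x$params$class_weighting,
              x$n_train, length(x$feature_names)))
  invisible(x)
}

#' Raw per-residue hot-spot probability
#'
#' Averages the positive-class leaf frequencies over the ensemble. Class
#' assignment (including the per-amino-acid probability correction) is done
#' separately; the raw class reported here is simply HS when the probability
#' exceeds 0.5.
#'
#' @param model A `hotspot_model`.
#' @param data Feature tibble whose feature columns match the model's frozen
#'   order exactly (a schema mismatch aborts).
#' @return `data`'s metadata columns plus `raw_hs_probability` in \[0, 1\] and
#'   `predicted_class_raw`.
#' @export
predict_hs_probability <- function(model, data) {
  stopifnot(inherits(model, "hotspot_model"))
  parts <- split_feature_frame(data, require_label = FALSE)
  if (!identical(parts$feature_names, model$feature_names)) {
    abort(c("Feature columns do not match the model's training schema",
            paste0("expected ", length(model$feature_names), " columns in the frozen order")))
  }
  pr <- predict(model$forest, data = as.data.frame(parts$X),
                num.threads = 1)$predictions[, "HS"]
  bind_cols(parts$meta,
            tibble(raw_hs_probability = as.numeric(pr),
                   predicted_class_raw = ifelse(pr > 0.5, "HS", "NS")))
}

#' Grid search with stratified k-fold cross-validation
#'
#' Exhaustively evaluates a lattice of training parameters by stratified
#' k-fold cross-validation on the training set only and returns the candidate
#' with the best mean validation score.
#'
#' @param data Feature tibble with `label`, as for [train_hotspot_model()].
#' @param grid Data frame of candidate parameter combinations; columns must be
#'   arguments of [train_hotspot_model()] (e.g. `n_trees`, `mtry`,
#'   `min_node_size`, `class_weighting`).
#' @param folds Number of cross-validation folds (default 10); must not
#'   exceed the minority-class size.
#' @param metric Validation score to maximise: `"f1"` (default),
#'   `"accuracy"` or `"auroc"`.
#' @param seed Integer seed for fold assignment and tree randomness.
#' @return List with `best_params` (one-row tibble), `scores` (one row per
#'   candidate x fold) and `summary` (mean score per candidate).
#' @export
tune_hotspot_model <- function(data, grid, folds = 10,
                               metric = c("f1", "accuracy", "auroc"),
                               seed = 1) {
  metric <- match.arg(metric)
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("`grid` must contain at least one candidate")
  if (folds < 2) abort("`folds` must be >= 2")
  parts <- split_feature_frame(data)
  n_min <- min(table(parts$y))
  if (folds > n_min) {
    abort(sprintf("folds (%d) exceeds the minority-class size (%d)", folds, n_min))
  }

  withr::local_seed(as.integer(seed))
  fold_id <- integer(nrow(data))
  for (cl in levels(parts$y)) {
    rows <- which(parts$y == cl)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }

  scores <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cand <- as.list(grid[g, ])
    purrr::map_dfr(seq_len(folds), function(k) {
      tr <- data[fold_id != k, ]
      va <- data[fold_id == k, ]
      fit <- rlang::exec(train_hotspot_model, data = tr, !!!cand,
                         seed = seed + k)
      pred <- predict_hs_probability(fit, va)
      sc <- fold_score(pred, va$label, metric)
      bind_cols(grid[g, ], tibble(candidate = g, fold = k, score = sc))
    })
  })

  summary <- scores |>
    group_by(.data$candidate) |>
    summarise(mean_score = mean(.data$score, na.rm = TRUE), .groups = "drop")
  best <- summary$candidate[which.max(summary$mean_score)]
  list(best_params = grid[best, ],
       scores = scores,
       summary = bind_cols(grid[summary$candidate, ], summary),
       metric = metric)
}

fold_score <- function(pred, actual, metric) {
  if (metric == "auroc") {
    return(auroc(pred$raw_hs_probability, actual))
  }
  m <- scalar_metrics(confusion_counts(pred$predicted_class_raw, actual))
  val <- m[[if (metric == "f1") "f1" else "accuracy"]]
  if (is.na(val)) 0 else val  # degenerate folds score 0, not NA, for ranking
}

#' @rdname hotspot_model_broom
#' @method tidy hotspot_model
#' @export
tidy.hotspot_model <- function(x, ...) {
  imp <- ranger::importance(x$forest)
  tibble(feature = names(imp), importance = as.numeric(imp)) |>
    arrange(dplyr::desc(.data$importance)) |>
    mutate(rank = dplyr::row_number())
}

#' Broom-style accessors for fitted hot-spot models
#'
#' `tidy()` returns the per-feature impurity importances (one row per feature,
#' ranked); `glance()` returns a one-row model summary including the
#' out-of-bag Brier score.
#'
#' @param x A `hotspot_model`.
#' @param ... Unused.
#' @name hotspot_model_broom
#' @method glance hotspot_model
#' @export
glance.hotspot_model <- function(x, ...) {
  fp <- x$training_fingerprint
  tibble(n_trees = x$params$n_trees,
         mtry = x$params$mtry,
         min_node_size = x$params$min_node_size,
         class_weighting = x$params$class_weighting,
         n_train = x$n_train,
         n_hs = if (!is.null(fp)) sum(fp$n[fp$label == "HS"]) else NA_integer_,
         n_ns = if (!is.null(fp)) sum(fp$n[fp$label == "NS"]) else NA_integer_,
         oob_brier = x$forest$prediction.error)
}

#' Save / load a fitted model bundle
#'
#' The bundle stores the ensemble together with the frozen feature order,
#' parameters, seed and a checksum of the property table used at extraction
#' time; loading verifies the checksum against the supplied table and refuses
#' to continue on mismatch, so predictions can never silently use a different
#' feature definition than training did.
#'
#' @param model A `hotspot_model`.
#' @param path File path for the serialized bundle.
#' @param properties Property table the features were extracted with.
#' @return `save_hotspot_model()` returns `path` invisibly;
#'   `read_hotspot_model()` returns the `hotspot_model`.
#' @export
save_hotspot_model <- function(model, path, properties = amino_acid_properties()) {
  stopifnot(inherits(model, "hotspot_model"))
  bundle <- list(format_version = 1L,
                 model = model,
                 property_checksum = rlang::hash(properties))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_hotspot_model
#' @export
read_hotspot_model <- function(path, properties = amino_acid_properties()) {
  if (!file.exists(path)) abort(paste0("Model file not found: ", path))
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, 1L)) {
    abort("Unrecognized model bundle format")
  }
  if (!identical(bundle$property_checksum, rlang::hash(properties))) {
    abort(paste0("Property-table checksum mismatch: the model was trained with ",
                 "a different property table than the one supplied"))
  }
  bundle$model
}

#' Baseline classifiers for comparison
#'
#' A single optional hook exposing four conventional classifiers (random
#' forest, support-vector machine, single-hidden-layer neural network,
#' recursive-partitioning tree) at default settings, for side-by-side
#' comparison with the extra-trees pipeline. These are not part of the
#' supported prediction path.
#'
#' @param data Training tibble as for [train_hotspot_model()].
#' @param newdata Tibble to score.
#' @param method One of `"random_forest"`, `"svm"`, `"neural_net"`, `"tree"`.
#' @param seed Integer seed.
#' @return Tibble of `newdata` metadata plus `raw_hs_probability` and
#'   `predicted_class_raw`.
#' @export
baseline_classifier <- function(data, newdata,
                                method = c("random_forest", "svm",
                                           "neural_net", "tree"),
                                seed = 1) {
  method <- match.arg(method)
  tr <- split_feature_frame(data)
  te <- split_feature_frame(newdata, require_label = FALSE)
  if (!identical(tr$feature_names, te$feature_names)) {
    abort("Training and scoring feature columns differ")
  }
  withr::local_seed(as.integer(seed))
  Xtr <- as.data.frame(tr$X)
  Xte <- as.data.frame(te$X)
  p <- switch(method,
    random_forest = {
      fit <- ranger::ranger(x = Xtr, y = tr$y, probability = TRUE,
                            seed = as.integer(seed), num.threads = 1)
      predict(fit, Xte, num.threads = 1)$predictions[, "HS"]
    },
    svm = {
      fit <- e1071::svm(x = Xtr, y = tr$y, probability = TRUE)
      attr(predict(fit, Xte, probability = TRUE), "probabilities")[, "HS"]
    },
    neural_net = {
      fit <- nnet::nnet(x = Xtr, y = as.numeric(tr$y == "HS"), size = 5,
                        maxit = 200, trace = FALSE)
      as.numeric(predict(fit, Xte))
    },
    tree = {
      fit <- rpart::rpart(y ~ ., data = cbind(Xtr, y = tr$y), method = "class")
      predict(fit, Xte, type = "prob")[, "HS"]
    })
  bind_cols(te$meta,
            tibble(raw_hs_probability = as.numeric(p),
                   predicted_class_raw = ifelse(p > 0.5, "HS", "NS")))
}
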
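# Two-layer stacked ensemble. Base layer: 4 classifier families x 7
# encodings = 28 probability estimators. Their out-of-fold class
# probabilities form a 28-dimensional "probabilistic feature" vector per
# sample, on which 4 meta-learners are trained; the final score is the mean
# of the 4 meta probabilities, thresholded at 0.5 (ties go positive).

FAMILY_ORDER <- c("RF", "ERT", "GB", "SVM")

#' Canonical names of the 28 base models
#'
#' Encoding-major, family-minor: `Kmer.RF`, `Kmer.ERT`, ..., `TPCP.SVM`.
#' This order is fixed so probabilistic feature vectors are reproducible.
#'
#' @return Character vector of length 28.
#' @export
base_model_names <- function() {
  as.vector(t(outer(ENCODING_ORDER, FAMILY_ORDER, paste, sep = ".")))
}

#' Default hyperparameter grids (desk-scale)
#'
#' Single fixed configuration per family, sized for interactive runs:
#' RF/ERT 100 trees with sqrt(p) candidate features; gradient boosting 100
#' rounds, learning rate 0.1, depth 3; RBF SVM with cost 1 and gamma 1/p.
#' See [full_grids()] for the wider search ranges.
#'
#' @return Named list of one `data.frame` per family.
#' @export
default_grids <- function() {
  list(
    RF  = data.frame(ntree = 100, mtry = "sqrt", stringsAsFactors = FALSE),
    ERT = data.frame(ntree = 100, mtry = "sqrt", stringsAsFactors = FALSE),
    GB  = data.frame(nrounds = 100, eta = 0.1, max_depth = 3),
    SVM = data.frame(cost = 1, gamma = NA_real_)  # NA gamma -> 1/p
  )
}

#' Wider hyperparameter search ranges
#'
#' Grid-searched by 10-fold cross-validated accuracy when passed to the
#' training functions: RF/ERT trees 100-500 with sqrt/log2 feature
#' sampling; boosting rounds/learning-rate/depth combinations; SVM cost
#' 2^-5..2^5 and gamma 2^-7..2^3.
#'
#' @return Named list of one `data.frame` per family.
#' @export
full_grids <- function() {
  list(
    RF  = expand.grid(ntree = seq(100, 500, 100), mtry = c("sqrt", "log2"),
                      stringsAsFactors = FALSE),
    ERT = expand.grid(ntree = seq(100, 500, 100), mtry = c("sqrt", "log2"),
                      stringsAsFactors = FALSE),
    GB  = expand.grid(nrounds = c(50, 100, 200), eta = c(0.01, 0.1),
                      max_depth = c(3, 5)),
    SVM = expand.grid(cost = 2^seq(-5, 5, 2), gamma = 2^seq(-7, 3, 2))
  )
}

resolve_mtry <- function(spec, p) {
  if (is.numeric(spec)) return(max(1L, as.integer(spec)))
  switch(as.character(spec),
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("unknown mtry rule: ", spec, call. = FALSE))
}

as_label_factor <- function(labels) {
  y <- factor(labels, levels = c("neg", "pos"))
  if (any(is.na(y))) stop("labels must be pos/neg with no NA", call. = FALSE)
  if (nlevels(droplevels(y)) < 2) {
    stop("both classes must be present in the training labels", call. = FALSE)
  }
  y
}

# Fit one probability estimator. x: numeric matrix with colnames; y: factor
# neg/pos. Returns a list(family, params, fit) consumed by predict_base().
fit_base <- function(x, y, family, params, seed = 1) {
  p <- ncol(x)
  set.seed(seed)
  fit <- switch(family,
    RF = randomForest::randomForest(
      x = x, y = y, ntree = params$ntree,
      mtry = resolve_mtry(params$mtry, p)),
    ERT = ranger::ranger(
      x = x, y = y, probability = TRUE, num.trees = params$ntree,
      mtry = resolve_mtry(params$mtry, p), splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      seed = seed, num.threads = 1),
    GB = xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "binary:logistic", learning_rate = params$eta,
        max_depth = params$max_depth, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "pos")),
      nrounds = params$nrounds, verbose = 0),
    SVM = e1071::svm(
      x = x, y = y, kernel = "radial", cost = params$cost,
      gamma = if (is.na(params$gamma)) 1 / p else params$gamma,
      probability = TRUE, scale = FALSE),
    stop("unknown classifier family: ", family, call. = FALSE)
  )
  list(family = family, params = params, fit = fit)
}

# Positive-class probability from a fitted base model.
predict_base <- function(model, x) {
  pr <- switch(model$family,
    RF = stats::predict(model$fit, x, type = "prob")[, "pos"],
    ERT = stats::predict(model$fit, data = x,
                         num.threads = 1)$predictions[, "pos"],
    GB = stats::predict(model$fit, xgboost::xgb.DMatrix(x)),
    SVM = attr(stats::predict(model$fit, x, probability = TRUE),
               "probabilities")[, "pos"]
  )
  unname(pmin(1, pmax(0, pr)))
}

# Hard class call used when scoring grid configurations. For the SVM this
# is the margin sign (the calibrated probability can disagree near the
# boundary); for the tree ensembles it is the probability thresholded at
# 0.5.
predict_label_base <- function(model, x) {
  if (model$family == "SVM") {
    as.character(stats::predict(model$fit, x))
  } else {
    ifelse(predict_base(model, x) >= 0.5, "pos", "neg")
  }
}

#' Stratified cross-validation fold assignment
#'
#' @param y Factor of class labels.
#' @param folds Number of folds (each fold receives members of every class
#'   when class sizes allow).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`, one per sample.
#' @export
stratified_folds <- function(y, folds, seed = 1) {
  stopifnot(folds >= 2)
  set.seed(seed)
  assignment <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Grid-search and fit one base model
#'
#' When the grid has more than one row, each configuration is scored by
#' mean stratified k-fold cross-validated accuracy (threshold 0.5) and the
#' best (first on ties) is refit on all data; a single-row grid is fit
#' directly.
#'
#' @param x Numeric feature matrix (rows samples, named columns).
#' @param labels `"pos"`/`"neg"` labels.
#' @param family One of `"RF"`, `"ERT"`, `"GB"`, `"SVM"`.
#' @param grid `data.frame` of configurations (see [default_grids()]).
#' @param folds CV folds for the grid search, default 10.
#' @param seed Integer seed.
#' @return List with `fit` (the base model), `params` (chosen row) and
#'   `cv_acc` (per-row CV accuracies; `NA` for a single-row grid).
#' @export
tune_and_fit_base <- function(x, labels, family, grid = default_grids()[[family]],
                              folds = 10, seed = 1) {
  y <- as_label_factor(labels)
  cv_acc <- rep(NA_real_, nrow(grid))
  best <- 1L
  if (nrow(grid) > 1) {
    fold_id <- stratified_folds(y, folds, seed)
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(folds)) {
        hold <- fold_id == f
        m <- fit_base(x[!hold, , drop = FALSE], y[!hold], family,
                      as.list(grid[g, , drop = FALSE]), seed = seed + f)
        lab <- predict_label_base(m, x[hold, , drop = FALSE])
        correct <- correct + sum(lab == as.character(y[hold]))
      }
      cv_acc[g] <- correct / length(y)
    }
    best <- which.max(cv_acc)
  }
  params <- as.list(grid[best, , drop = FALSE])
  list(fit = fit_base(x, y, family, params, seed = seed),
       params = params, cv_acc = cv_acc)
}

encode_all <- function(samples, tables = list()) {
  out <- lapply(ENCODING_ORDER, function(e) encode_matrix(samples, e, tables))
  names(out) <- ENCODING_ORDER
  out
}

#' Out-of-fold probabilistic features for a training set
#'
#' Each training sample's 28 base-model probabilities are produced by
#' models fitted with that sample's fold held out, the standard stacking
#' guard against information leakage into the meta-layer.
#'
#' @param encodings Named list of the seven encoding matrices (as returned
#'   by the internal encoder; rows aligned with `labels`).
#' @param labels `"pos"`/`"neg"` labels.
#' @param grids Named list of per-family configurations (first row used;
#'   see [default_grids()]). Ignored when `params` is given.
#' @param folds Out-of-fold scheme size, default 10.
#' @param seed Integer seed.
#' @param params Optional named list keyed by base-model name
#'   (`"Kmer.RF"`, ...) of per-model hyperparameter lists, e.g. the
#'   configurations chosen by a grid search.
#' @return Numeric matrix n x 28 (canonical column order) with attribute
#'   `fold` recording each sample's held-out fold.
#' @export
oof_probabilities <- function(encodings, labels, grids = default_grids(),
                              folds = 10, seed = 1, params = NULL) {
  y <- as_label_factor(labels)
  n <- length(y)
  fold_id <- stratified_folds(y, folds, seed)
  for (f in seq_len(folds)) {
    if (nlevels(droplevels(y[fold_id != f])) < 2) {
      stop("fold ", f, " leaves a single-class training set", call. = FALSE)
    }
  }
  pf <- matrix(NA_real_, n, length(base_model_names()),
               dimnames = list(rownames(encodings[[1]]), base_model_names()))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    for (enc in ENCODING_ORDER) {
      x <- encodings[[enc]]
      for (fam in FAMILY_ORDER) {
        key <- paste(enc, fam, sep = ".")
        cfg <- if (is.null(params)) as.list(grids[[fam]][1, , drop = FALSE])
               else params[[key]]
        m <- fit_base(x[!hold, , drop = FALSE], y[!hold], fam, cfg,
                      seed = model_seed(seed, enc, fam, f))
        pf[hold, key] <- predict_base(m, x[hold, , drop = FALSE])
      }
    }
  }
  stopifnot(!anyNA(pf), all(pf >= 0), all(pf <= 1))
  attr(pf, "fold") <- fold_id
  attr(pf, "encoding") <- "PF28"
  pf
}

# Distinct deterministic sub-seed per (model, fold); kept below 2^31.
model_seed <- function(seed, enc, fam, fold = 0L) {
  (seed +
     1009L * match(enc, ENCODING_ORDER) +
     10007L * match(fam, FAMILY_ORDER) +
     100003L * fold) %% .Machine$integer.max
}

#' Fuse the four meta-learner probabilities into one call
#'
#' Arithmetic mean of the four probabilities; label `"pos"` iff the mean is
#' at least 0.5. Averaging subsumes majority voting for four voters and
#' avoids 2-2 label ties.
#'
#' @param meta_probs Numeric vector of exactly four probabilities in
#'   `[0, 1]`.
#' @return List with `probability` and `label`.
#' @export
fuse <- function(meta_probs) {
  if (length(meta_probs) != 4 || any(meta_probs < 0 | meta_probs > 1)) {
    stop("fuse() expects exactly four probabilities in [0, 1]", call. = FALSE)
  }
  p <- mean(meta_probs)
  list(probability = p, label = if (p >= 0.5) "pos" else "neg")
}

#' Train the full stacked ensemble
#'
#' End-to-end pipeline: encode the training windows under all seven
#' encodings; fit the 28 base models (optionally grid-searched); build
#' out-of-fold probabilistic features; fit the four meta-learners on them;
#' package everything with the fusing rule. Fully deterministic under
#' `seed`.
#'
#' @param samples Labelled sample `data.frame`, both classes present.
#' @param seed Integer seed.
#' @param folds Folds for the out-of-fold probabilistic features, default
#'   10.
#' @param grids Per-family hyperparameter grids; multi-row grids are
#'   searched per base model by CV accuracy (see [tune_and_fit_base()]).
#' @param tables Optional property-table overrides (list with `dinuc`,
#'   `trinuc`).
#' @return An object of class `stack4mc_model`.
#' @export
train_stack <- function(samples, seed = 1, folds = 10,
                        grids = default_grids(), tables = list()) {
  labels <- samples$label
  y <- as_label_factor(labels)
  tables <- list(dinuc = tables$dinuc %||% default_dinuc_table(),
                 trinuc = tables$trinuc %||% default_trinuc_table())
  encodings <- encode_all(samples, tables)

  base <- list()
  for (enc in ENCODING_ORDER) {
    for (fam in FAMILY_ORDER) {
      key <- paste(enc, fam, sep = ".")
      tuned <- tune_and_fit_base(encodings[[enc]], labels, fam,
                                 grid = grids[[fam]], folds = folds,
                                 seed = model_seed(seed, enc, fam))
      base[[key]] <- c(tuned["fit"], list(params = tuned$params,
                                          cv_acc = tuned$cv_acc))
    }
  }

  # Meta layer is trained on out-of-fold probabilities using each base
  # model's chosen configuration, so no meta input was produced by a model
  # that saw the sample it scores.
  pf <- oof_probabilities(encodings, labels, folds = folds, seed = seed,
                          params = lapply(base, `[[`, "params"))
  meta <- lapply(FAMILY_ORDER, function(fam) {
    tune_and_fit_base(pf, labels, fam, grid = default_grids()[[fam]],
                      folds = folds, seed = model_seed(seed, "BPF", fam, 99L))
  })
  names(meta) <- FAMILY_ORDER

  structure(list(
    version = "stack4mc-model-1",
    base = base,
    meta = lapply(meta, `[[`, "fit"),
    tables = tables,
    folds = folds,
    seed = seed,
    training_ids = samples$id,
    oof_features = pf
  ), class = "stack4mc_model")
}

#' Base-model probabilistic feature vectors for new windows
#'
#' The 28 positive-class probabilities from the fully-fitted base models,
#' canonical column order.
#'
#' @param model A trained `stack4mc_model`.
#' @param samples Sample `data.frame`.
#' @return Numeric matrix n x 28.
#' @export
probabilistic_features <- function(model, samples) {
  stopifnot(inherits(model, "stack4mc_model"))
  encodings <- encode_all(samples, model$tables)
  pf <- matrix(NA_real_, nrow(samples), length(base_model_names()),
               dimnames = list(samples$id, base_model_names()))
  for (key in base_model_names()) {
    enc <- sub("\\..*$", "", key)
    pf[, key] <- predict_base(model$base[[key]]$fit, encodings[[enc]])
  }
  attr(pf, "encoding") <- "PF28"
  pf
}

#' Predict 4mC status for new windows
#'
#' @param object A trained `stack4mc_model`.
#' @param samples Sample `data.frame` of valid windows.
#' @param ... Unused.
#' @return `data.frame` with `id`, fused `probability`, `label`
#'   (`pos`/`neg`, threshold 0.5, ties positive), the four per-family meta
#'   probabilities (`meta.RF`, ...) and the 28 base probabilities.
#' @export
predict.stack4mc_model <- function(object, samples, ...) {
  if (nrow(samples) == 0) {
    return(data.frame(id = character(0), probability = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  pf <- probabilistic_features(object, samples)
  meta_pr <- vapply(FAMILY_ORDER, function(fam) {
    predict_base(object$meta[[fam]], pf)
  }, numeric(nrow(pf)))
  meta_pr <- matrix(meta_pr, nrow = nrow(pf),
                    dimnames = list(NULL, paste0("meta.", FAMILY_ORDER)))
  prob <- rowMeans(meta_pr)
  out <- data.frame(id = samples$id, probability = prob,
                    label = ifelse(prob >= 0.5, "pos", "neg"),
                    stringsAsFactors = FALSE)
  cbind(out, meta_pr, as.data.frame(pf, optional = TRUE))
}

#' Persist / restore a trained ensemble
#'
#' Single-file bundle (RDS) carrying the version tag, property tables,
#' hyperparameters and fitted states; loading refuses mismatched versions.
#'
#' @param model A `stack4mc_model`.
#' @param path Destination file.
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stack4mc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "stack4mc_model") ||
      !identical(model$version, "stack4mc-model-1")) {
    stop("file does not contain a compatible stack4mc model", call. = FALSE)
  }
  model
}

#' @export
print.stack4mc_model <- function(x, ...) {
  cat("stacked 4mC ensemble (", x$version, ")\n", sep = "")
  cat("  base models: ", length(x$base), " (",
      paste(ENCODING_ORDER, collapse = ", "), " x ",
      paste(FAMILY_ORDER, collapse = "/"), ")\n", sep = "")
  cat("  meta-learners:", paste(names(x$meta), collapse = ", "), "\n")
  cat("  trained on", length(x$training_ids), "windows,",
      x$folds, "out-of-fold folds, seed", x$seed, "\n")
  invisible(x)
}
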
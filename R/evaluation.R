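# Evaluation protocol: confusion-based metrics with rank-based AUC,
# repeated-split summaries, AUC comparison by t-test, position-wise
# composition enrichment, and the correlation structure of the 28
# probabilistic features.

#' Binary classification metrics for one evaluation
#'
#' Computes the confusion counts at `threshold` plus sensitivity
#' `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))` (set to 0
#' with a warning when the denominator vanishes) and the rank-based AUC
#' (Mann-Whitney statistic, equivalent to the trapezoidal ROC area with
#' tied scores averaged).
#'
#' @param labels True `"pos"`/`"neg"` labels.
#' @param probabilities Positive-class scores in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5 (ties positive).
#' @return One-row `data.frame`: TP, TN, FP, FN, SN, SP, ACC, MCC, AUC.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  y <- factor(labels, levels = c("neg", "pos"))
  if (any(is.na(y))) stop("labels must be pos/neg with no NA", call. = FALSE)
  truth <- y == "pos"
  if (all(truth) || !any(truth)) {
    stop("AUC is undefined for single-class truth", call. = FALSE)
  }
  call_pos <- probabilities >= threshold
  tp <- sum(truth & call_pos)
  tn <- sum(!truth & !call_pos)
  fp <- sum(!truth & call_pos)
  fn <- sum(truth & !call_pos)
  denom <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- if (denom == 0) {
    warning("MCC denominator is zero; reporting 0", call. = FALSE)
    0
  } else {
    (tp * tn - fp * fn) / denom
  }
  r <- rank(probabilities)
  auc <- (sum(r[truth]) - tp_fn_pairs(sum(truth))) / (sum(truth) * sum(!truth))
  data.frame(TP = tp, TN = tn, FP = fp, FN = fn,
             SN = tp / (tp + fn), SP = tn / (tn + fp),
             ACC = (tp + tn) / length(truth), MCC = mcc, AUC = auc)
}

tp_fn_pairs <- function(npos) npos * (npos + 1) / 2

#' Repeated stratified cross-validation of a model builder
#'
#' For each repeat, samples are split into stratified folds; the builder is
#' trained on each fold's complement and scores the held-out fold; the
#' pooled out-of-fold scores give one metrics row per repeat, summarized as
#' mean and standard deviation per metric.
#'
#' @param samples Labelled sample `data.frame`.
#' @param builder `function(train_samples, seed)` returning a scoring
#'   function `function(test_samples) -> probabilities`.
#' @param folds Folds per repeat, default 10.
#' @param repeats Number of repeats, default 10.
#' @param seed Integer seed.
#' @return List with `per_repeat` (metrics `data.frame`, one row per
#'   repeat), `mean` and `sd` (named numeric vectors over SN/SP/ACC/MCC/AUC).
#' @export
crossval <- function(samples, builder, folds = 10, repeats = 10, seed = 1) {
  y <- as_label_factor(samples$label)
  if (min(table(y)) < folds) {
    stop("each class needs at least `folds` samples", call. = FALSE)
  }
  rows <- lapply(seq_len(repeats), function(r) {
    fold_id <- stratified_folds(y, folds, seed + 7919L * r)
    prob <- numeric(nrow(samples))
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      train <- samples[!hold, , drop = FALSE]
      stopifnot(!any(train$id %in% samples$id[hold]))
      scorer <- builder(train, seed + 7919L * r + f)
      prob[hold] <- scorer(samples[hold, , drop = FALSE])
    }
    classification_metrics(samples$label, prob)
  })
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("SN", "SP", "ACC", "MCC", "AUC")
  list(per_repeat = per_repeat,
       mean = colMeans(per_repeat[metric_cols]),
       sd = vapply(per_repeat[metric_cols], stats::sd, numeric(1)))
}

#' Evaluate a trained ensemble on an untouched labelled set
#'
#' Errors if any evaluation id overlaps the model's training ids (leakage
#' guard).
#'
#' @param model A trained `stack4mc_model`.
#' @param samples Labelled sample `data.frame` disjoint from training.
#' @return One-row metrics `data.frame` (see [classification_metrics()]).
#' @export
independent_eval <- function(model, samples) {
  if (nrow(samples) == 0) stop("independent set is empty", call. = FALSE)
  overlap <- intersect(samples$id, model$training_ids)
  if (length(overlap) > 0) {
    stop("independent set overlaps training ids: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  preds <- stats::predict(model, samples)
  classification_metrics(samples$label, preds$probability)
}

#' Two-tailed t-test comparing two AUC samples
#'
#' @param auc_a,auc_b Equal-length numeric vectors of per-repeat AUCs
#'   (n >= 2).
#' @param paired Pair observations across repeats (default unpaired,
#'   equal-variance two-sample test).
#' @return Two-tailed p-value in `[0, 1]` (1 when both vectors are constant
#'   and equal).
#' @export
compare_auc_ttest <- function(auc_a, auc_b, paired = FALSE) {
  stopifnot(length(auc_a) == length(auc_b), length(auc_a) >= 2)
  if (stats::sd(auc_a) == 0 && stats::sd(auc_b) == 0) {
    return(if (isTRUE(all.equal(mean(auc_a), mean(auc_b)))) 1 else 0)
  }
  stats::t.test(auc_a, auc_b, alternative = "two.sided", paired = paired,
                var.equal = !paired)$p.value
}

#' Position-specific composition enrichment between classes
#'
#' Per position (1..41) and base, counts in each class, the frequency
#' difference (positives minus negatives), a two-proportion z-test without
#' continuity correction, and Benjamini-Hochberg adjusted p-values across
#' all 41 x 4 tests. Positions constant in both classes (the centered C)
#' get `NA` p-values and are flagged.
#'
#' @param positives,negatives Sample `data.frame`s of valid windows.
#' @return `data.frame` with columns `position`, `base`, `count_pos`,
#'   `count_neg`, `freq_pos`, `freq_neg`, `diff`, `z`, `p`, `p_adj`,
#'   `constant`.
#' @export
position_enrichment <- function(positives, negatives) {
  stopifnot(nrow(positives) > 0, nrow(negatives) > 0)
  count_at <- function(samples) {
    chars <- do.call(rbind, strsplit(samples$seq, "", fixed = TRUE))
    vapply(BASES, function(b) colSums(chars == b),
           numeric(WINDOW_LEN))  # 41 x 4
  }
  cp <- count_at(positives)
  cn <- count_at(negatives)
  n1 <- nrow(positives)
  n2 <- nrow(negatives)
  grid <- expand.grid(position = seq_len(WINDOW_LEN), base = BASES,
                      stringsAsFactors = FALSE)
  grid$count_pos <- cp[cbind(grid$position, match(grid$base, BASES))]
  grid$count_neg <- cn[cbind(grid$position, match(grid$base, BASES))]
  grid$freq_pos <- grid$count_pos / n1
  grid$freq_neg <- grid$count_neg / n2
  grid$diff <- grid$freq_pos - grid$freq_neg
  pool <- (grid$count_pos + grid$count_neg) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  grid$z <- ifelse(se > 0, grid$diff / se, NA_real_)
  grid$p <- 2 * stats::pnorm(-abs(grid$z))
  grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  grid$constant <- pool %in% c(0, 1)
  grid[order(grid$position, match(grid$base, BASES)), ]
}

#' Correlation structure of the 28 probabilistic features
#'
#' Pearson correlation matrix plus an average-linkage hierarchical
#' clustering (distance `1 - r`) of the features and the 2-cluster
#' membership. Zero-variance columns get `NA` correlations and are flagged.
#'
#' @param pf Numeric matrix of probabilistic features (n >= 3 rows).
#' @return List with `correlation` (28 x 28), `order` (dendrogram leaf
#'   permutation), `clusters` (named 2-group membership) and
#'   `zero_variance` (logical per column).
#' @export
correlation_analysis <- function(pf) {
  stopifnot(nrow(pf) >= 3)
  sds <- apply(pf, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(pf, method = "pearson"))
  corr[sds == 0, ] <- NA_real_
  corr[, sds == 0] <- NA_real_
  diag(corr) <- 1
  usable <- sds > 0
  cfill <- corr
  cfill[is.na(cfill)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cfill), method = "average")
  list(correlation = corr,
       order = hc$order,
       clusters = stats::cutree(hc, k = 2),
       zero_variance = stats::setNames(sds == 0, colnames(pf)))
}
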
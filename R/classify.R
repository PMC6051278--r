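#' Train the random-forest J-wave detector
#'
#' Bagged ensemble of CART trees (150 by default), each grown on a
#' bootstrap sample with a random sqrt(d) feature subset per split. Beats
#' are the training unit; the record-level split must already have been
#' made upstream.
#'
#' @param features Feature data frame from [extract_features_all()]
#'   (training split only): metadata columns `record_id`, `r_index`,
#'   `label` plus numeric feature columns.
#' @param n_trees Number of base learners (150).
#' @param seed Integer seed; fixed seed gives a reproducible model.
#' @param columns Optional character vector restricting the feature
#'   columns used (e.g. only the `re_` block).
#' @return A `jwave_rf` model handle exposing prediction, scores and
#'   importances.
#' @export
train_rf <- function(features, n_trees = 150, seed = 1, columns = NULL) {
  meta <- c("record_id", "r_index", "label")
  stopifnot(all(meta %in% names(features)))
  fcols <- setdiff(names(features), meta)
  if (!is.null(columns)) {
    stopifnot(all(columns %in% fcols))
    fcols <- columns
  }
  y <- factor(features$label, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes")
  x <- features[, fcols, drop = FALSE]
  # undefined entropies: impute with the column median so trees can split
  for (j in seq_along(x)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) x[[j]][bad] <- stats::median(x[[j]][!bad])
  }
  set.seed(seed)
  model <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = max(1, floor(sqrt(length(fcols)))),
    importance = TRUE)
  structure(list(model = model,
                 feature_names = fcols,
                 train_records = unique(features$record_id),
                 n_trees = n_trees,
                 seed = seed),
            class = "jwave_rf")
}

#' @export
print.jwave_rf <- function(x, ...) {
  cat(sprintf("jwave_rf: %d trees on %d features, %d training record(s)\n",
              x$n_trees, length(x$feature_names), length(x$train_records)))
  invisible(x)
}

# Positive-class score = fraction of trees voting positive.
rf_scores <- function(fit, features) {
  x <- features[, fit$feature_names, drop = FALSE]
  for (j in seq_along(x)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) x[[j]][bad] <- stats::median(x[[j]][!bad], na.rm = TRUE)
  }
  as.numeric(stats::predict(fit$model, x, type = "vote",
                            norm.votes = TRUE)[, "positive"])
}

#' Beat-level classification metrics
#'
#' Sensitivity, specificity and accuracy in percent, the Matthews
#' correlation coefficient, and the rank-based (Mann-Whitney) AUC, all
#' from beat-level predictions. MCC is `NA` (flagged, not zero) when any
#' confusion-matrix marginal is empty.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @param scores,labels Optional continuous scores and true labels for the
#'   AUC.
#' @return A `metrics_report` list: `Se`, `Sp`, `Acc` (percent), `MCC`,
#'   `AUC`, `confusion`.
#' @export
metrics_report <- function(tp, fn, tn, fp, scores = NULL, labels = NULL) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  confusion <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  # counts enter products of order n^4: compute in double precision
  tp <- as.numeric(tp); fn <- as.numeric(fn)
  tn <- as.numeric(tn); fp <- as.numeric(fp)
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  denom <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  auc <- if (!is.null(scores)) rank_auc(scores, labels) else NA_real_
  structure(list(Se = se, Sp = sp, Acc = acc, MCC = mcc, AUC = auc,
                 confusion = confusion),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Se %.1f%%  Sp %.1f%%  Acc %.1f%%  MCC %.3f  AUC %.3f\n",
              x$Se, x$Sp, x$Acc, x$MCC, x$AUC))
  cat(sprintf("confusion: TP %.0f FN %.0f TN %.0f FP %.0f\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' @param scores Continuous classifier scores, higher = more positive.
#' @param labels True labels ("positive"/"negative" or a factor).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  pos <- labels == "positive"
  np <- sum(pos); nn <- sum(!pos)
  stopifnot(np > 0, nn > 0)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a fitted model on a held-out test split
#'
#' Scores every test beat, thresholds at 0.5 tree-vote fraction, and
#' reports beat-level metrics plus a record-level majority-vote summary.
#' Errors out if any test record was seen in training (record-level split
#' hygiene).
#'
#' @param fit A `jwave_rf`.
#' @param features Test-split feature data frame.
#' @return A `metrics_report` with extra fields `scores` and
#'   `record_votes`.
#' @export
evaluate_model <- function(fit, features) {
  stopifnot(inherits(fit, "jwave_rf"))
  overlap <- intersect(unique(features$record_id), fit$train_records)
  if (length(overlap))
    stop("record-level split violated: ", paste(overlap, collapse = ", "),
         " present in both train and test")
  sc <- rf_scores(fit, features)
  pred <- ifelse(sc >= 0.5, "positive", "negative")
  lab <- features$label
  rep <- metrics_report(tp = sum(pred == "positive" & lab == "positive"),
                        fn = sum(pred == "negative" & lab == "positive"),
                        tn = sum(pred == "negative" & lab == "negative"),
                        fp = sum(pred == "positive" & lab == "negative"),
                        scores = sc, labels = lab)
  votes <- tapply(pred == "positive", features$record_id, mean)
  truth <- tapply(lab, features$record_id, function(z) z[1])
  rep$scores <- sc
  rep$record_votes <- data.frame(record_id = names(votes),
                                 frac_positive = as.numeric(votes),
                                 majority = ifelse(votes >= 0.5,
                                                   "positive", "negative"),
                                 label = as.character(truth),
                                 stringsAsFactors = FALSE)
  rep
}

#' Welch's two-tailed t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; used to judge per-feature separation between the J-positive
#' and J-negative classes.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return List with `t`, `p` (two-tailed) and `df`.
#' @export
welch_ttest <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop("degenerate test: both groups have zero variance")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Feature importance ranking and per-feature class statistics
#'
#' Normalised random-forest importances (mean decrease in Gini, summing to
#' 1) sorted descending, with a Welch t-test between classes per feature
#' on the supplied (training) data, a Bonferroni-adjusted p column, and
#' per-class mean/SD summaries.
#'
#' @param fit A `jwave_rf`.
#' @param features Training-split feature data frame.
#' @return Data frame sorted by importance: feature, importance, t, p,
#'   p_bonferroni, mean/sd per class.
#' @export
feature_report <- function(fit, features) {
  stopifnot(inherits(fit, "jwave_rf"))
  imp <- randomForest::importance(fit$model, type = 2)[, 1]
  imp <- imp / sum(imp)
  pos <- features$label == "positive"
  stats_row <- function(f) {
    a <- features[[f]][pos]
    b <- features[[f]][!pos]
    tt <- tryCatch(welch_ttest(a, b),
                   error = function(e) list(t = NA_real_, p = NA_real_,
                                            df = NA_real_))
    c(t = tt$t, p = tt$p,
      mean_pos = mean(a[is.finite(a)]), sd_pos = stats::sd(a[is.finite(a)]),
      mean_neg = mean(b[is.finite(b)]), sd_neg = stats::sd(b[is.finite(b)]))
  }
  st <- t(vapply(fit$feature_names, stats_row, numeric(6)))
  out <- data.frame(feature = fit$feature_names,
                    importance = unname(imp[fit$feature_names]),
                    st, row.names = NULL, stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out[order(out$importance, decreasing = TRUE), ]
}

#' ROC curve from scores
#'
#' Stepwise ROC points ordered by descending threshold; the trapezoidal
#' area equals the rank-based AUC.
#'
#' @param scores Continuous scores.
#' @param labels True labels.
#' @return Data frame with columns `threshold`, `FPR`, `TPR`, plus
#'   attribute `auc` (trapezoidal area).
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == "positive"
  np <- sum(pos); nn <- sum(!pos)
  stopifnot(np > 0, nn > 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single steps
  dup <- rev(duplicated(rev(s)))
  tpr <- cumsum(p)[!dup] / np
  fpr <- cumsum(!p)[!dup] / nn
  out <- data.frame(threshold = c(Inf, s[!dup]),
                    FPR = c(0, fpr), TPR = c(0, tpr))
  auc <- sum(diff(out$FPR) * (utils::head(out$TPR, -1) +
                                utils::tail(out$TPR, -1)) / 2)
  attr(out, "auc") <- auc
  out
}
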
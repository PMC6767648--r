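# Confusion-based metrics, ROC/PR curves and AUCs, and calibration of the
# default prediction cutoff.

#' The three prediction cutoffs
#'
#' Score thresholds for calling an individual CD: a loose cutoff (0,
#' highest recall), the calibrated default (14.3, balanced precision and
#' recall), and a strict cutoff (45, highest precision). A score greater
#' than or equal to the cutoff is called CD.
#'
#' @param loose,default,strict numeric cutoffs, strictly increasing.
#' @return Named numeric vector of class `avadx_cutoffs`.
#' @export
cutoff_set <- function(loose = 0, default = 14.3, strict = 45) {
  if (!(loose < default && default < strict)) {
    stop("cutoffs must satisfy loose < default < strict")
  }
  structure(c(loose = loose, default = default, strict = strict),
            class = "avadx_cutoffs")
}

#' Confusion counts at a score cutoff
#'
#' Tallies true/false positives/negatives with CD as the positive class;
#' a score `>= cutoff` (ties included) is a CD call.
#'
#' @param scores numeric prediction scores.
#' @param labels aligned `"CD"` / `"HC"` truth labels.
#' @param cutoff numeric threshold.
#' @return list of class `avadx_confusion` with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  call_cd <- scores >= cutoff
  structure(list(
    tp = sum(call_cd & labels == "CD"),
    fn = sum(!call_cd & labels == "CD"),
    tn = sum(!call_cd & labels == "HC"),
    fp = sum(call_cd & labels == "HC")
  ), class = "avadx_confusion")
}

#' Metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, false positive
#' rate `FP/(FP+TN)`, F1 `2TP/(2TP+FP+FN)`, the Matthews correlation
#' coefficient, and balanced precision `TPR/(TPR+FPR)` — precision
#' standardized to equal class sizes (it coincides with precision exactly
#' when the classes are balanced). Undefined 0/0 ratios are reported as
#' `NA`, except the MCC, which is 0 by convention whenever any factor of
#' its denominator is 0.
#'
#' @param counts an [confusion_at_cutoff()] result, or a list with
#'   elements `tp`, `fn`, `tn`, `fp`.
#' @return list with `precision`, `recall`, `fpr`, `f1`, `mcc`,
#'   `balanced_precision`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  stopifnot(all(c(tp, fn, tn, fp) >= 0))
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  fpr <- rat(fp, fp + tn)
  f1 <- rat(2 * tp, 2 * tp + fp + fn)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  bal <- if (is.na(recall) || is.na(fpr) || (recall + fpr) == 0) NA_real_
         else recall / (recall + fpr)
  list(precision = precision, recall = recall, fpr = fpr, f1 = f1,
       mcc = mcc, balanced_precision = bal)
}

#' ROC AUC by trapezoidal integration
#'
#' Sweeps the classification threshold over every distinct score (ties
#' handled jointly), builds the ROC curve, and integrates it with the
#' trapezoidal rule — equivalent to the normalized Mann-Whitney U
#' statistic with ties counted one-half.
#'
#' @param scores numeric prediction scores.
#' @param labels aligned `"CD"` / `"HC"` labels; both classes required.
#' @return The ROC AUC.
#' @export
roc_auc <- function(scores, labels) {
  pts <- .roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

.check_two_classes <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("CD", "HC"))) stop("labels must be CD or HC")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  labels
}

.roc_points <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  np <- sum(labels == "CD"); nn <- sum(labels == "HC")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == "CD"), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == "HC"), numeric(1))
  list(tpr = c(0, tp / np), fpr = c(0, fp / nn))
}

#' Precision-recall AUC by trapezoidal integration
#'
#' Integrates precision over the achieved recall points (threshold swept
#' over distinct scores, descending), anchoring the curve at recall 0
#' with the first achieved precision. The baseline is the positive-class
#' prevalence, i.e., the PR AUC of a random scorer.
#'
#' @inheritParams roc_auc
#' @return list with `auc` and `baseline`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  np <- sum(labels == "CD")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == "CD"), numeric(1))
  pos <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  rec <- c(0, tp / np)
  prec <- c((tp / pos)[1], tp / pos)
  auc <- sum(diff(rec) * (utils::head(prec, -1) + prec[-1]) / 2)
  list(auc = auc, baseline = np / length(labels))
}

#' Calibrate the default prediction cutoff
#'
#' Repeats the fixed-gene-set cross-validation with heavy per-class
#' resampling (the reference protocol resamples to 500 of each class),
#' takes the mean of the held-out CD scores and the mean of the held-out
#' HC scores, and uses the midpoint of those two means as that round's
#' cutoff. The returned default is the most common cutoff across rounds
#' after rounding to one decimal (ties broken toward the smaller value).
#'
#' @param scores individuals x genes matrix (pruned).
#' @param pheno data.frame with `individual_id`, `status`, `family_id`.
#' @param genes the fixed gene set to model (e.g. the top-125 DKM genes
#'   selected on the full panel).
#' @param config a [model_config()].
#' @param n_rounds resampling rounds (the reference protocol uses 1000).
#' @param resample_target per-class bootstrap size per round.
#' @param seed master seed.
#' @return The modal cutoff (numeric scalar); all per-round cutoffs are
#'   attached as attribute `"rounds"`.
#' @export
select_default_cutoff <- function(scores, pheno, genes,
                                  config = model_config(),
                                  n_rounds = 1000, resample_target = 500,
                                  seed = NULL) {
  seeds <- .fan_seeds(seed, n_rounds)
  cuts <- numeric(n_rounds)
  for (i in seq_len(n_rounds)) {
    cv <- run_crossvalidation(scores, pheno, method = "fixed",
                              fixed_genes = genes, n_repeats = 1,
                              balance = resample_target, config = config,
                              seed = seeds[i])
    s <- cv$held_scores[, 1]
    cuts[i] <- (mean(s[cv$labels == "CD"], na.rm = TRUE) +
                mean(s[cv$labels == "HC"], na.rm = TRUE)) / 2
  }
  tab <- table(round(cuts, 1))
  mode_cut <- as.numeric(names(tab)[which.max(tab)])  # first max = smallest value
  structure(mode_cut, rounds = cuts)
}
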
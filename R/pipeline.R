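# End-to-end orchestration: train-with-CV on a panel, and per-individual
# prediction with batch adjustment and model retraining.

#' Pipeline configuration
#'
#' Gathers every tunable constant of the pipeline so the reference values
#' are defaults rather than magic numbers scattered through calls.
#'
#' @param vscore a [vscore_params()] object.
#' @param fs_method feature-selection method for cross-validation.
#' @param top_k ranked-gene count for `"dkm"` (default 125).
#' @param n_repeats CV model-training repeats per fold (reference: 100).
#' @param balance class balancing during CV (`"match-major"` or integer).
#' @param resample_target per-class bootstrap size for per-individual
#'   prediction models and cutoff calibration (reference: 500).
#' @param cutoff_rounds calibration rounds for [select_default_cutoff()]
#'   (reference: 1000).
#' @param n_perm label permutations for [permutation_null()] (reference:
#'   1000); 0 skips the permutation test.
#' @param cutoffs a [cutoff_set()].
#' @param model a [model_config()].
#' @param min_overlap fraction of training loci a test individual should
#'   share; below this a degraded-accuracy warning is raised.
#' @param calibrate_cutoff replace the default cutoff with a fresh
#'   [select_default_cutoff()] calibration during [run_train()].
#' @param seed master seed for all randomness.
#' @return list of class `avadx_config`.
#' @export
avadx_config <- function(vscore = vscore_params(), fs_method = "dkm",
                         top_k = 125, n_repeats = 100,
                         balance = "match-major", resample_target = 500,
                         cutoff_rounds = 1000, n_perm = 1000,
                         cutoffs = cutoff_set(), model = model_config(),
                         min_overlap = 0.58, calibrate_cutoff = FALSE,
                         seed = 1) {
  structure(as.list(environment()), class = "avadx_config")
}

#' Train the full pipeline on an annotated panel
#'
#' Runs the training workflow end to end: variant filtering, gene
#' scoring, matrix pruning, a full-panel feature selection that fixes the
#' prediction feature set (top-`top_k` DKM genes by default), in-fold
#' cross-validation with the configured method, optional permutation
#' test, and (optionally) cutoff calibration.
#'
#' @param panel a loaded, annotated [new_panel()] object with CD and HC
#'   individuals (see [load_panel()] / [load_annotations()]).
#' @param config an [avadx_config()].
#' @return list of class `avadx_train` with the pruned matrix, the fixed
#'   feature genes, the CV report, per-fold gene sets, the prediction
#'   cutoffs, training loci, and the configuration.
#' @export
run_train <- function(panel, config = avadx_config()) {
  stopifnot(inherits(panel, "avadx_panel"), inherits(config, "avadx_config"))
  panel <- filter_training_variants(panel)
  if (is.null(panel$annotations)) stop("stage score: panel is not annotated")
  scores <- build_gene_score_matrix(panel, config$vscore)
  pruned <- prune_genes(scores)
  message(sprintf("stage score: %d individuals x %d genes (%d after pruning)",
                  nrow(pruned), ncol(scores), ncol(pruned)))
  pheno <- panel$individuals
  labels <- stats::setNames(pheno$status, pheno$individual_id)

  # fixed feature set for later per-individual prediction models
  fixed_genes <- select_genes(pruned, labels[rownames(pruned)],
                              method = config$fs_method, top_k = config$top_k)
  if (config$fs_method == "dkm") fixed_genes <- utils::head(fixed_genes, config$top_k)

  cv <- run_crossvalidation(pruned, pheno, method = config$fs_method,
                            gene_count = config$top_k,
                            n_repeats = config$n_repeats,
                            balance = config$balance, config = config$model,
                            seed = config$seed)
  perm <- NULL
  if (config$n_perm > 0) {
    perm <- permutation_null(pruned, pheno, method = config$fs_method,
                             gene_count = config$top_k, n_perm = config$n_perm,
                             observed_roc = cv$roc_mean,
                             observed_pr = cv$pr_mean,
                             balance = config$balance, config = config$model,
                             seed = config$seed + 1L)
  }
  cutoffs <- config$cutoffs
  if (isTRUE(config$calibrate_cutoff)) {
    def <- select_default_cutoff(pruned, pheno, fixed_genes,
                                 config = config$model,
                                 n_rounds = config$cutoff_rounds,
                                 resample_target = config$resample_target,
                                 seed = config$seed + 2L)
    cutoffs <- cutoff_set(default = as.numeric(def),
                          loose = min(cutoffs["loose"], as.numeric(def) - 1e-9),
                          strict = max(cutoffs["strict"], as.numeric(def) + 1e-9))
  }
  structure(list(
    train_loci = panel_loci(panel), pruned = pruned, pheno = pheno,
    fixed_genes = fixed_genes, cv = cv, permutation = perm,
    cutoffs = cutoffs, config = config
  ), class = "avadx_train")
}

#' @export
print.avadx_train <- function(x, ...) {
  cat(sprintf("avadx trained pipeline: %d loci, %d pruned genes, %d fixed features\n",
              length(x$train_loci), ncol(x$pruned), length(x$fixed_genes)))
  print(x$cv)
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p (ROC/PR): %.3g / %.3g\n",
                x$permutation$p_roc, x$permutation$p_pr))
  }
  invisible(x)
}

#' Predict the disease status of one previously unseen individual
#'
#' Reproduces the per-individual prediction protocol: the test exome is
#' restricted to the training loci, its gene scores are computed, the
#' mean-only batch adjustment is run for this single individual against
#' the whole training panel, the training panel is bootstrap-resampled to
#' `resample_target` of each class, a fresh model is trained on the
#' adjusted, resampled panel over the fixed feature genes, and the
#' adjusted test vector is scored. The test individual is never part of
#' training.
#'
#' @param artifacts an [run_train()] result.
#' @param test_panel an annotated [new_panel()] object containing the
#'   individual (more individuals may be present; only one is used).
#' @param individual_id the individual to predict.
#' @param seed RNG seed for the resampling (defaults to the trained
#'   configuration's seed).
#' @return list with `score`, `calls` (named character vector `"CD"` /
#'   `"HC"` at the three cutoffs), and `retained_fraction` of the test
#'   individual's loci.
#' @export
run_predict_individual <- function(artifacts, test_panel, individual_id,
                                   seed = NULL) {
  stopifnot(inherits(artifacts, "avadx_train"),
            inherits(test_panel, "avadx_panel"))
  cfg <- artifacts$config
  one <- subset_panel(test_panel, individual_id, drop_empty = TRUE)
  one <- restrict_test_variants(one, artifacts$train_loci)
  frac <- one$log$retained_fraction
  if (frac < cfg$min_overlap) {
    warning(sprintf("test individual shares only %.0f%% of training loci; accuracy degraded",
                    100 * frac))
  }
  if (is.null(one$annotations)) stop("test panel is not annotated")
  test_scores <- build_gene_score_matrix(one, cfg$vscore)
  genes <- colnames(artifacts$pruned)
  test_vec <- stats::setNames(numeric(length(genes)), genes)
  common <- intersect(genes, colnames(test_scores))
  test_vec[common] <- test_scores[1, common]

  adj <- adjust_test_individual(artifacts$pruned, test_vec)
  labels <- stats::setNames(artifacts$pheno$status, artifacts$pheno$individual_id)
  if (!is.null(seed)) set.seed(seed) else set.seed(cfg$seed)
  bal <- bootstrap_balance(rownames(adj$train), labels[rownames(adj$train)],
                           target = cfg$resample_target)
  fit <- train_model(adj$train[bal, artifacts$fixed_genes, drop = FALSE],
                     labels[bal], cfg$model)
  score <- unname(predict_scores(fit, adj$test[artifacts$fixed_genes]))
  calls <- ifelse(score >= artifacts$cutoffs, "CD", "HC")
  names(calls) <- names(artifacts$cutoffs)
  list(score = score, calls = calls, retained_fraction = frac)
}

#' Predict a whole test cohort, one individual at a time
#'
#' Convenience loop over [run_predict_individual()]: one fresh model per
#' test individual, exactly as the per-individual protocol demands.
#'
#' @inheritParams run_predict_individual
#' @param individual_ids IDs to predict (default: everyone in the panel).
#' @return data.frame with `individual_id`, `score`, `status` (truth, may
#'   be `NA`), and the calls at the three cutoffs.
#' @export
predict_cohort <- function(artifacts, test_panel, individual_ids = NULL,
                           seed = NULL) {
  if (is.null(individual_ids)) {
    individual_ids <- test_panel$individuals$individual_id
  }
  seeds <- .fan_seeds(seed %||% artifacts$config$seed, length(individual_ids))
  rows <- lapply(seq_along(individual_ids), function(i) {
    p <- run_predict_individual(artifacts, test_panel, individual_ids[i],
                                seed = seeds[i])
    data.frame(individual_id = individual_ids[i], score = p$score,
               call_loose = p$calls["loose"], call_default = p$calls["default"],
               call_strict = p$calls["strict"], stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$status <- test_panel$individuals$status[
    match(out$individual_id, test_panel$individuals$individual_id)]
  out
}

#' Score a prediction table at the three cutoffs
#'
#' Builds the confusion counts and [compute_metrics()] report at each
#' cutoff, plus ROC/PR AUCs, for a [predict_cohort()] table (or any
#' aligned scores/labels).
#'
#' @param scores numeric prediction scores.
#' @param labels aligned `"CD"` / `"HC"` labels.
#' @param cutoffs a [cutoff_set()].
#' @return list with `per_cutoff` (data.frame: cutoff, TP/FN/TN/FP and
#'   metrics) and `auc` (list: roc, pr, pr_baseline).
#' @export
evaluate_predictions <- function(scores, labels, cutoffs = cutoff_set()) {
  per <- do.call(rbind, lapply(names(cutoffs), function(nm) {
    cc <- confusion_at_cutoff(scores, labels, cutoffs[[nm]])
    m <- compute_metrics(cc)
    data.frame(cutoff_name = nm, cutoff = cutoffs[[nm]],
               tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
               precision = m$precision, balanced_precision = m$balanced_precision,
               recall = m$recall, f1 = m$f1, mcc = m$mcc,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  pr <- pr_auc(scores, labels)
  list(per_cutoff = per,
       auc = list(roc = roc_auc(scores, labels), pr = pr$auc,
                  pr_baseline = pr$baseline))
}
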
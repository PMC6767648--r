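# Family-aware LOOCV, bootstrap class balancing, SVM training/scoring,
# and permutation nulls.

#' Model configuration
#'
#' Settings for the SVM scorer. Class labels are numeric +100 (CD) and
#' -100 (HC); with `mode = "regression"` (default) an epsilon support
#' vector regressor with RBF kernel and library-default hyperparameters is
#' fitted on these targets, so predictions are continuous scores where
#' more positive means more CD-like. `mode = "classification"` instead
#' fits a C-classification SVM and uses its decision values (rescaled by
#' 100) as scores.
#'
#' @param label_cd,label_hc numeric training targets; `label_cd` must
#'   exceed `label_hc`.
#' @param mode `"regression"` or `"classification"`.
#' @param kernel SVM kernel, passed to [e1071::svm()].
#' @param scale scale features before fitting (passed through).
#' @return A list of class `avadx_model_config`.
#' @export
model_config <- function(label_cd = 100, label_hc = -100,
                         mode = c("regression", "classification"),
                         kernel = "radial", scale = TRUE) {
  mode <- match.arg(mode)
  if (!(label_cd > label_hc)) stop("label_cd must exceed label_hc")
  structure(list(label_cd = label_cd, label_hc = label_hc, mode = mode,
                 kernel = kernel, scale = scale),
            class = "avadx_model_config")
}

#' Plan family-aware leave-one-out folds
#'
#' One fold per family group: all members of a family are held out
#' together, so related individuals never appear on both sides of a fold.
#' Individuals with a unique (or missing) family ID form singleton folds.
#' 111 individuals containing two related pairs yield 109 folds.
#'
#' @param panel an [new_panel()] object, or a data.frame with columns
#'   `individual_id` and `family_id`.
#' @return A list of class `avadx_fold_plan`: each element holds
#'   `held_out` and `train` ID vectors; the held-out sets partition the
#'   panel.
#' @export
plan_loocv_folds <- function(panel) {
  ind <- if (inherits(panel, "avadx_panel")) panel$individuals else panel
  stopifnot(is.data.frame(ind), all(c("individual_id", "family_id") %in% names(ind)))
  ids <- as.character(ind$individual_id)
  fam <- as.character(ind$family_id)
  blank <- is.na(fam) | fam == "" | fam == "."
  fam[blank] <- paste0(".singleton.", ids[blank])
  groups <- split(ids, factor(fam, levels = unique(fam)))
  folds <- lapply(groups, function(held) {
    list(held_out = held, train = setdiff(ids, held))
  })
  names(folds) <- NULL
  structure(folds, class = "avadx_fold_plan")
}

#' Bootstrap-balance a training set
#'
#' Resampling with replacement to balance class sizes: with
#' `target = "match-major"` the minor class is resampled up to the major
#' class size (the major class is kept as-is); with an integer target both
#' classes are resampled with replacement to exactly that many individuals
#' each.
#'
#' @param ids character vector of training individual IDs.
#' @param labels aligned `"CD"` / `"HC"` labels.
#' @param target `"match-major"` or a positive integer per-class size.
#' @return Character vector (multiset) of resampled IDs.
#' @export
bootstrap_balance <- function(ids, labels, target = "match-major") {
  stopifnot(length(ids) == length(labels))
  labels <- as.character(labels)
  cd <- ids[labels == "CD"]
  hc <- ids[labels == "HC"]
  if (!length(cd) || !length(hc)) stop("both classes must be non-empty")
  if (identical(target, "match-major")) {
    n <- max(length(cd), length(hc))
    boot <- function(x) if (length(x) == n) x else c(x, sample(x, n - length(x), replace = TRUE))
    c(boot(cd), boot(hc))
  } else {
    stopifnot(is.numeric(target), target >= 1)
    c(sample(cd, target, replace = TRUE), sample(hc, target, replace = TRUE))
  }
}

#' Train an SVM scorer on a gene-score matrix
#'
#' Fits the model described by [model_config()] on the given rows and
#' records the exact (ordered) gene list; predictions later require that
#' same list.
#'
#' @param x numeric matrix, rows = (possibly resampled) individuals,
#'   columns = genes.
#' @param labels `"CD"` / `"HC"` vector aligned to rows of `x`.
#' @param config a [model_config()].
#' @return An object of class `avadx_model`.
#' @export
train_model <- function(x, labels, config = model_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need both classes to train")
  constant <- all(apply(x, 2, function(v) length(unique(v)) == 1L))
  if (constant) warning("constant feature matrix; scores will be ~constant")
  # guard e1071's scaling against zero-variance columns
  scale_cols <- if (isTRUE(config$scale)) apply(x, 2, stats::sd) > 0 else FALSE
  if (config$mode == "regression") {
    y <- ifelse(labels == "CD", config$label_cd, config$label_hc)
    fit <- e1071::svm(x, y, type = "eps-regression", kernel = config$kernel,
                      scale = scale_cols)
  } else {
    y <- factor(labels, levels = c("HC", "CD"))
    fit <- e1071::svm(x, y, type = "C-classification", kernel = config$kernel,
                      scale = scale_cols)
  }
  structure(list(fit = fit, genes = colnames(x), config = config),
            class = "avadx_model")
}

#' Continuous disease scores for new individuals
#'
#' More positive scores indicate more CD-like individuals. The columns of
#' `x` must be exactly the model's training gene list; a different gene
#' set is a hard error (same set in a different order is realigned).
#'
#' @param model an [train_model()] object.
#' @param x numeric matrix of gene scores, rows = individuals.
#' @return Numeric score vector named by row.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "avadx_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!identical(colnames(x), model$genes)) {
    if (setequal(colnames(x), model$genes) &&
        length(colnames(x)) == length(model$genes)) {
      x <- x[, model$genes, drop = FALSE]
    } else {
      stop("gene list of the matrix does not match the model's training genes")
    }
  }
  if (model$config$mode == "regression") {
    out <- stats::predict(model$fit, x)
  } else {
    pr <- stats::predict(model$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient so that positive means CD, scale to the +/-100 convention
    sgn <- if (grepl("^CD/", colnames(dv)[1])) 1 else -1
    out <- sgn * dv[, 1] * 100
  }
  stats::setNames(as.numeric(out), rownames(x))
}

# Deterministic sub-seed fan-out from one master seed.
.fan_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Family-aware cross-validation of the full modelling stage
#'
#' For every fold of [plan_loocv_folds()]: feature selection is run on the
#' training individuals only; a gene subset is chosen (top-`gene_count`
#' for the ranked `"dkm"` method, `gene_count` genes sampled with
#' replacement per repeat for the unordered set methods, or a caller-fixed
#' set); the training set is bootstrap-balanced; an SVM is trained and the
#' held-out individuals are scored. Requesting more genes than a fold's
#' set contains falls back to the entire set ("max" semantics). Pooled
#' held-out scores give one ROC and one PR AUC per repeat; the only
#' source of between-repeat variation for fixed gene sets is the
#' resampling of individuals.
#'
#' @param scores individuals x genes matrix (pruned).
#' @param pheno data.frame with `individual_id`, `status`, `family_id`
#'   aligned to `scores` rows by ID.
#' @param method feature-selection method: `"dkm"`, `"ks5"`, `"tt5"`,
#'   `"dis"`, or `"fixed"` (use `fixed_genes`).
#' @param gene_count genes per model (`NULL` = entire fold set).
#' @param n_repeats model-training repeats per fold (the reference
#'   protocol uses 100).
#' @param balance `"match-major"` or an integer per-class bootstrap size.
#' @param config a [model_config()].
#' @param fixed_genes gene IDs for `method = "fixed"`.
#' @param permute_train_labels shuffle the training labels within every
#'   fold (class counts preserved) — used by [permutation_null()].
#' @param seed master seed; fans out deterministically over folds,
#'   repeats, and permutations.
#' @return An `avadx_cv` object: held-out score matrix (individuals x
#'   repeats), per-repeat `roc` / `pr` AUC vectors, their means/sds, the
#'   per-fold gene sets, and the fold plan.
#' @export
run_crossvalidation <- function(scores, pheno,
                                method = c("dkm", "ks5", "tt5", "dis", "fixed"),
                                gene_count = NULL, n_repeats = 10,
                                balance = "match-major",
                                config = model_config(),
                                fixed_genes = NULL,
                                permute_train_labels = FALSE,
                                seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(scores))
  pheno <- as.data.frame(pheno)
  idx <- match(rownames(scores), pheno$individual_id)
  if (anyNA(idx)) stop("phenotype table missing individuals present in the matrix")
  pheno <- pheno[idx, , drop = FALSE]
  labels <- stats::setNames(as.character(pheno$status), pheno$individual_id)
  folds <- plan_loocv_folds(pheno)
  if (method == "fixed") {
    if (is.null(fixed_genes)) stop("method = 'fixed' requires fixed_genes")
    if (!all(fixed_genes %in% colnames(scores))) stop("fixed_genes absent from matrix")
  }

  seeds <- matrix(.fan_seeds(seed, length(folds) * (n_repeats + 1L)),
                  nrow = length(folds))
  held_scores <- matrix(NA_real_, nrow(scores), n_repeats,
                        dimnames = list(rownames(scores), NULL))
  fold_sets <- vector("list", length(folds))
  max_used <- FALSE

  for (f in seq_along(folds)) {
    tr_ids <- folds[[f]]$train
    ho_ids <- folds[[f]]$held_out
    tr_labels <- labels[tr_ids]
    if (permute_train_labels) {
      set.seed(seeds[f, n_repeats + 1L])
      tr_labels <- stats::setNames(sample(tr_labels), tr_ids)
    }
    tr_mat <- scores[tr_ids, , drop = FALSE]
    gene_pool <- switch(method,
      dkm = dkm_rank(tr_mat, tr_labels)$gene,
      ks5 = screen_by_test(tr_mat, tr_labels, "KS"),
      tt5 = screen_by_test(tr_mat, tr_labels, "TT"),
      dis = select_dis(tr_mat, tr_labels),
      fixed = fixed_genes
    )
    if (!length(gene_pool)) next  # fold selected nothing; scores stay NA
    fold_sets[[f]] <- gene_pool

    for (r in seq_len(n_repeats)) {
      set.seed(seeds[f, r])
      if (is.null(gene_count) || gene_count >= length(gene_pool) ||
          method == "fixed") {
        genes_r <- if (method == "dkm") utils::head(gene_pool, gene_count %||% length(gene_pool))
                   else gene_pool
        if (!is.null(gene_count) && gene_count > length(gene_pool)) max_used <- TRUE
      } else if (method == "dkm") {
        genes_r <- gene_pool[seq_len(gene_count)]
      } else {
        genes_r <- sample(gene_pool, gene_count, replace = TRUE)
      }
      bal <- bootstrap_balance(tr_ids, tr_labels, balance)
      fit <- train_model(scores[bal, genes_r, drop = FALSE], tr_labels[bal], config)
      held_scores[ho_ids, r] <-
        predict_scores(fit, scores[ho_ids, genes_r, drop = FALSE])
    }
  }
  if (max_used) message("gene_count exceeded some fold gene sets; entire set used there")

  scored <- !apply(is.na(held_scores), 1, all)
  truth <- labels[rownames(held_scores)]
  auc_ok <- scored & !is.na(truth)
  roc <- pr <- rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    s <- held_scores[auc_ok, r]
    if (anyNA(s)) s[is.na(s)] <- min(s, na.rm = TRUE)  # unselectable folds score lowest
    roc[r] <- roc_auc(s, truth[auc_ok])
    pr[r] <- pr_auc(s, truth[auc_ok])$auc
  }
  structure(list(
    held_scores = held_scores, labels = truth, folds = folds,
    fold_gene_sets = fold_sets, method = method, gene_count = gene_count,
    roc = roc, pr = pr,
    roc_mean = mean(roc), roc_sd = stats::sd(roc),
    pr_mean = mean(pr), pr_sd = stats::sd(pr),
    mean_scores = rowMeans(held_scores, na.rm = TRUE)
  ), class = "avadx_cv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.avadx_cv <- function(x, ...) {
  cat(sprintf("avadx cross-validation (%s%s): %d folds, %d repeat(s)\n",
              x$method,
              if (!is.null(x$gene_count)) paste0(", ", x$gene_count, " genes") else "",
              length(x$folds), length(x$roc)))
  cat(sprintf("  ROC AUC %.3f (sd %.3f) | PR AUC %.3f (sd %.3f)\n",
              x$roc_mean, x$roc_sd, x$pr_mean, x$pr_sd))
  invisible(x)
}

#' Permutation null for cross-validated AUCs
#'
#' Re-runs the cross-validation with the training labels of every fold
#' shuffled (class counts preserved; held-out labels keep their true
#' values for scoring), building null distributions of the ROC and PR
#' AUCs. Empirical p-values count the permuted AUCs strictly larger than
#' the observed ones, divided by the number of permutations.
#'
#' @inheritParams run_crossvalidation
#' @param observed_roc,observed_pr the AUCs of the un-permuted run.
#' @param n_perm number of label permutations (the reference protocol
#'   uses 1000).
#' @return list with `p_roc`, `p_pr`, and the null AUC vectors
#'   `null_roc`, `null_pr`.
#' @export
permutation_null <- function(scores, pheno, method = "dkm",
                             gene_count = NULL, n_perm = 1000,
                             observed_roc, observed_pr,
                             balance = "match-major",
                             config = model_config(),
                             fixed_genes = NULL, seed = NULL) {
  seeds <- .fan_seeds(seed, n_perm)
  null_roc <- null_pr <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    cv <- run_crossvalidation(scores, pheno, method = method,
                              gene_count = gene_count, n_repeats = 1,
                              balance = balance, config = config,
                              fixed_genes = fixed_genes,
                              permute_train_labels = TRUE, seed = seeds[i])
    null_roc[i] <- cv$roc_mean
    null_pr[i] <- cv$pr_mean
  }
  list(p_roc = sum(null_roc > observed_roc) / n_perm,
       p_pr = sum(null_pr > observed_pr) / n_perm,
       null_roc = null_roc, null_pr = null_pr)
}
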
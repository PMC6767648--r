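# Empirical-Bayes (ComBat) batch adjustment of gene scores, applied
# one test individual at a time against the whole training panel.

#' ComBat adjustment of a gene-score matrix
#'
#' Location(/scale) empirical-Bayes batch adjustment of per-gene scores,
#' delegated to [sva::ComBat()]: each gene is standardized by its grand
#' mean and pooled standard deviation, per-batch location (and, unless
#' `mean_only`, scale) effects are estimated and shrunken across genes
#' with parametric priors, then removed. No covariates are modelled —
#' class labels are deliberately never consulted, so both batches move
#' toward the common mean regardless of disease status. Adjusted scores
#' may become negative; they are not clamped. Following the underlying
#' ComBat implementation, a gene whose scores are uniform within some
#' multi-sample batch (e.g. all zero there) is passed through unadjusted;
#' single-sample batches are exempt from that guard.
#'
#' @param scores individuals x genes matrix (pruned; genes constant across
#'   all individuals are a hard error and must be removed upstream).
#' @param batch character/factor batch label per individual (>= 2 batches,
#'   each non-empty). A batch holding a single individual forces
#'   `mean_only` regardless of the flag.
#' @param mean_only adjust only per-batch means, never variances.
#' @return The adjusted matrix, same dimensions and dimnames.
#' @export
combat_adjust <- function(scores, batch, mean_only = FALSE) {
  stopifnot(is.matrix(scores), length(batch) == nrow(scores))
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) stop("combat_adjust requires at least 2 batches")
  if (any(table(batch) == 0)) stop("every batch must be non-empty")
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0)) {
    stop("gene(s) constant across all individuals: ",
         paste(utils::head(colnames(scores)[sds == 0], 5), collapse = ", "),
         "; prune before adjusting")
  }
  if (any(table(batch) == 1)) mean_only <- TRUE
  dat <- t(scores)  # ComBat wants genes x samples
  adj <- suppressMessages(
    sva::ComBat(dat = dat, batch = batch, mod = NULL, mean.only = mean_only)
  )
  out <- t(adj)
  dimnames(out) <- dimnames(scores)
  out
}

#' Adjust a single test individual against the training panel
#'
#' Emulates prediction "in the wild", where the unknown batch holds one
#' person: the test vector is stacked onto the training matrix, the
#' two-batch (train vs. test) mean-only ComBat adjustment is run, and the
#' adjusted pieces are returned. Because the test batch has one sample,
#' only means are ever adjusted; training-panel variances are untouched up
#' to the EB back-transform. Class labels play no role.
#'
#' @param train_scores individuals x genes training matrix (pruned).
#' @param test_vector named numeric vector of the test individual's gene
#'   scores over exactly the training genes (any order).
#' @return list with `train` (adjusted matrix) and `test` (adjusted named
#'   vector).
#' @export
adjust_test_individual <- function(train_scores, test_vector) {
  stopifnot(is.matrix(train_scores))
  if (!setequal(names(test_vector), colnames(train_scores)) ||
      length(test_vector) != ncol(train_scores)) {
    stop("test vector genes do not match the training matrix genes")
  }
  test_vector <- test_vector[colnames(train_scores)]
  combined <- rbind(train_scores, .avadx.test. = test_vector)
  batch <- c(rep("train", nrow(train_scores)), "test")
  adj <- combat_adjust(combined, batch, mean_only = TRUE)
  list(train = adj[-nrow(adj), , drop = FALSE],
       test = adj[nrow(adj), ])
}
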
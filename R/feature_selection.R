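# In-fold gene selection: case-exclusive patterns, distribution screens,
# DKM merit ranking, gene-set overlap, and the variant-level Fisher screen.

#' Case-exclusive (DIS) gene selection
#'
#' Selects genes that are non-zero in at least `min_cases` cases and zero
#' in every control — the "disease set" pattern. Raising `min_cases` can
#' only shrink the selection.
#'
#' @param scores individuals x genes matrix (see [build_gene_score_matrix()]).
#' @param labels character/factor vector over `c("CD", "HC")`, aligned to
#'   rows of `scores`.
#' @param min_cases minimum number of non-zero cases (default 3).
#' @return Character vector of selected gene IDs (sorted).
#' @export
select_dis <- function(scores, labels, min_cases = 3) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  labels <- as.character(labels)
  cd <- scores[labels == "CD", , drop = FALSE]
  hc <- scores[labels == "HC", , drop = FALSE]
  if (nrow(cd) < min_cases) stop("fewer than min_cases CD individuals in panel")
  sel <- colSums(cd != 0) >= min_cases & colSums(hc != 0) == 0
  sort(colnames(scores)[sel])
}

#' Distribution-difference gene screens (KS / t-test)
#'
#' Selects genes whose case and control score distributions differ at
#' `p < alpha` under a two-sided two-sample test: the exact two-sample
#' Kolmogorov-Smirnov test (`"KS"`) or Welch's t-test (`"TT"`). No multiple
#' testing correction is applied — this is deliberate screening behaviour.
#' Genes constant within both classes are excluded (p treated as 1).
#'
#' @inheritParams select_dis
#' @param test `"KS"` or `"TT"`.
#' @param alpha selection threshold on the per-gene p-value (default 0.05).
#' @return Character vector of selected gene IDs (sorted).
#' @export
screen_by_test <- function(scores, labels, test = c("KS", "TT"), alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  labels <- as.character(labels)
  if (sum(labels == "CD") < 2 || sum(labels == "HC") < 2) {
    stop("need at least 2 individuals per class")
  }
  cd <- labels == "CD"
  p <- apply(scores, 2, function(x) {
    a <- x[cd]; b <- x[!cd]
    if (length(unique(c(a, b))) == 1L) return(1)
    if (test == "KS") {
      suppressWarnings(stats::ks.test(a, b, exact = TRUE)$p.value)
    } else {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
      suppressWarnings(stats::t.test(a, b, var.equal = FALSE)$p.value)
    }
  })
  p[is.na(p)] <- 1
  sort(colnames(scores)[p < alpha])
}

# DKM impurity on the (cost-weighted) case probability.
.dkm_impurity <- function(p) 2 * sqrt(p * (1 - p))

#' Rank genes by the (cost-sensitive) DKM split criterion
#'
#' For each gene, the merit is the largest impurity decrease achievable by
#' a single binary threshold split of its scores, using the
#' Dietterich-Kearns-Mansour impurity `f(p) = 2 * sqrt(p * (1 - p))` on the
#' cost-weighted case probability:
#' `merit = f(p_root) - sum_parts (n_part / n) * f(p_part)`,
#' with candidate thresholds at midpoints between consecutive distinct
#' sorted values. Class weights derive from the misclassification cost
#' matrix; the uniform default makes the criterion the plain DKM. Merit
#' ties are broken lexicographically by gene ID for determinism.
#'
#' @inheritParams select_dis
#' @param cost_matrix 2x2 misclassification cost matrix, rows = true class
#'   (CD, HC), columns = predicted class (CD, HC); only the off-diagonal
#'   costs matter. `NULL` (default) means uniform costs.
#' @param top_k number of top genes to return; `NULL` returns all. Asking
#'   for more genes than exist returns all with a warning.
#' @return data.frame with columns `gene` and `merit`, sorted by merit
#'   descending (ties by gene ID).
#' @export
dkm_rank <- function(scores, labels, cost_matrix = NULL, top_k = NULL) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels), ncol(scores) >= 1)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("CD", "HC")))
  if (is.null(cost_matrix)) cost_matrix <- matrix(c(0, 1, 1, 0), 2, 2)
  stopifnot(is.matrix(cost_matrix), all(dim(cost_matrix) == 2))
  w_cd <- cost_matrix[1, 2]  # cost of calling a CD individual HC
  w_hc <- cost_matrix[2, 1]  # cost of calling an HC individual CD
  if (w_cd <= 0 || w_hc <= 0) stop("misclassification costs must be positive")
  w <- ifelse(labels == "CD", w_cd, w_hc)
  wc <- w * (labels == "CD")
  W <- sum(w); Wc <- sum(wc)
  root <- .dkm_impurity(Wc / W)

  merit <- vapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    o <- order(x)
    xs <- x[o]
    cw <- cumsum(w[o])
    cwc <- cumsum(wc[o])
    n <- length(xs)
    cut <- which(xs[-n] < xs[-1])  # splits between distinct values only
    if (!length(cut)) return(0)
    pl <- cwc[cut] / cw[cut]
    pr <- (Wc - cwc[cut]) / (W - cw[cut])
    child <- (cw[cut] / W) * .dkm_impurity(pl) +
      ((W - cw[cut]) / W) * .dkm_impurity(pr)
    max(root - child)
  }, numeric(1))

  out <- data.frame(gene = colnames(scores), merit = merit,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$merit, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) {
    if (top_k > nrow(out)) {
      warning("top_k exceeds the number of genes; returning all ", nrow(out))
      top_k <- nrow(out)
    }
    out <- out[seq_len(top_k), , drop = FALSE]
  }
  out
}

#' Hypergeometric overlap between two gene sets
#'
#' Upper-tail hypergeometric test of the overlap between sets `a` and `b`
#' against a background universe: the p-value is `P(X >= |a intersect b|)`
#' when drawing `|a|` genes from the background of which `|b|` are
#' "successes".
#'
#' @param a,b character vectors of gene IDs, both subsets of `background`.
#' @param background character vector: the universe of variant-affected
#'   genes.
#' @return list with `overlap` (integer) and `p` (numeric).
#' @export
gene_set_overlap <- function(a, b, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background gene universe")
  a <- unique(a); b <- unique(b)
  if (!all(a %in% background) || !all(b %in% background)) {
    stop("gene sets must be subsets of the background")
  }
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(b), length(background) - length(b),
                     length(a), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Variant-level Fisher screen with FDR correction
#'
#' For every variant, tests carrier status (at least one alternate allele)
#' against CD/HC status with Fisher's exact test, and adds
#' Benjamini-Hochberg q-values. On small panels this screen typically finds
#' nothing significant — the gene-level scores exist precisely because
#' single-variant association is underpowered here.
#'
#' @param panel a filtered [new_panel()] object with CD and HC individuals.
#' @return data.frame with columns `key`, `carriers_cd`, `carriers_hc`,
#'   `p`, `q`, ordered as in the panel.
#' @export
variant_fisher_screen <- function(panel) {
  stopifnot(inherits(panel, "avadx_panel"))
  status <- panel$individuals$status
  n_cd <- sum(status == "CD", na.rm = TRUE)
  n_hc <- sum(status == "HC", na.rm = TRUE)
  if (n_cd == 0 || n_hc == 0) stop("panel must contain both CD and HC individuals")
  carrier <- panel$geno > 0
  cc <- rowSums(carrier[, which(status == "CD"), drop = FALSE], na.rm = TRUE)
  ch <- rowSums(carrier[, which(status == "HC"), drop = FALSE], na.rm = TRUE)
  p <- vapply(seq_along(cc), function(i) {
    m <- matrix(c(cc[i], n_cd - cc[i], ch[i], n_hc - ch[i]), 2, 2)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  data.frame(key = panel$variants$key, carriers_cd = cc, carriers_hc = ch,
             p = p, q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run one feature-selection method on a training matrix
#'
#' Dispatch helper used inside cross-validation folds. `"dis"`, `"ks5"`,
#' and `"tt5"` return unordered gene sets; `"dkm"` returns the ranked list
#' (use `top_k` to truncate). `"diso"` is the overfit sanity check — DIS
#' computed on the *full* panel — and must be requested explicitly; it is
#' never part of reported models.
#'
#' @inheritParams select_dis
#' @param method one of `"dis"`, `"ks5"`, `"tt5"`, `"dkm"`, `"diso"`.
#' @param top_k ranked-list truncation for `"dkm"`.
#' @param alpha screen threshold for `"ks5"` / `"tt5"`.
#' @param overfit_check must be `TRUE` to allow `"diso"`.
#' @return Character vector of gene IDs (ordered for `"dkm"`).
#' @export
select_genes <- function(scores, labels,
                         method = c("dkm", "ks5", "tt5", "dis", "diso"),
                         top_k = NULL, alpha = 0.05, min_cases = 3,
                         overfit_check = FALSE) {
  method <- match.arg(method)
  switch(method,
    dis = select_dis(scores, labels, min_cases),
    diso = {
      if (!overfit_check) {
        stop("'diso' deliberately overfits (full-panel selection); ",
             "set overfit_check = TRUE to acknowledge")
      }
      select_dis(scores, labels, min_cases)
    },
    ks5 = screen_by_test(scores, labels, "KS", alpha),
    tt5 = screen_by_test(scores, labels, "TT", alpha),
    dkm = dkm_rank(scores, labels, top_k = top_k)$gene
  )
}
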
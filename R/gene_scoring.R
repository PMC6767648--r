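# v_score mapping and per-gene functional-deficit aggregation.

#' v_score parameters
#'
#' Constants mapping a variant's consequence class (and, for nonsynonymous
#' variants, its functional-effect score in \[-100, 100\]) to a v_score in
#' \[0, 1\]:
#' \itemize{
#'   \item nonsynonymous, effect score s >= 0: `effect_base + (s/100) * effect_span`
#'   \item nonsynonymous, effect score s < 0 (predicted neutral): `neutral`
#'   \item synonymous: `synonymous`
#'   \item indel: `indel` (a heuristic proxy for likely loss of function)
#'   \item unscorable (no effect prediction available): `unscorable`
#' }
#' `het_weight` down-weights heterozygous genotypes in the gene-level sum
#' (homozygous alternate calls weigh 1).
#'
#' @param effect_base,effect_span affine map of non-negative effect scores;
#'   must sum to 1 so a score of 100 maps to a v_score of exactly 1.
#' @param neutral,synonymous,indel,unscorable fixed class v_scores.
#' @param het_weight heterozygous multiplier.
#' @return A list of class `vscore_params`.
#' @export
vscore_params <- function(effect_base = 0.06, effect_span = 0.94,
                          neutral = 0.055, synonymous = 0.05,
                          indel = 1.0, unscorable = 0.055,
                          het_weight = 0.25) {
  p <- list(effect_base = effect_base, effect_span = effect_span,
            neutral = neutral, synonymous = synonymous, indel = indel,
            unscorable = unscorable, het_weight = het_weight)
  vals <- unlist(p)
  if (any(vals < 0 | vals > 1)) stop("all vscore parameters must lie in [0, 1]")
  if (abs(effect_base + effect_span - 1) > 1e-12) {
    stop("effect_base + effect_span must equal 1")
  }
  structure(p, class = "vscore_params")
}

#' Raw v_score of a variant
#'
#' Maps consequence class and effect score to the raw v_score. Zygosity is
#' *not* applied here; the heterozygous weight enters in [gene_score()].
#' An effect score of exactly 0 is treated as an effect (v_score
#' `effect_base`), following the operational score table rather than the
#' narrative neutral/effect split.
#'
#' @param consequence character vector over
#'   `c("synonymous", "nonsynonymous", "indel", "unscorable")`.
#' @param effect_score numeric vector in \[-100, 100\]; required (non-`NA`)
#'   where `consequence == "nonsynonymous"`, ignored elsewhere.
#' @param params a [vscore_params()] object.
#' @return Numeric vector of v_scores in \[0, 1\].
#' @export
variant_score <- function(consequence, effect_score = NA_real_,
                          params = vscore_params()) {
  stopifnot(inherits(params, "vscore_params"))
  consequence <- as.character(consequence)
  bad <- setdiff(unique(consequence), .CONSEQUENCES)
  if (length(bad)) stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  effect_score <- rep_len(as.numeric(effect_score), length(consequence))
  ns <- consequence == "nonsynonymous"
  if (any(ns & is.na(effect_score))) {
    stop("nonsynonymous variant without an effect score")
  }
  if (any(ns & abs(effect_score) > 100)) {
    stop("effect score outside [-100, 100]")
  }
  v <- numeric(length(consequence))
  v[consequence == "synonymous"] <- params$synonymous
  v[consequence == "indel"] <- params$indel
  v[consequence == "unscorable"] <- params$unscorable
  eff <- ns & effect_score >= 0
  v[eff] <- params$effect_base + (effect_score[eff] / 100) * params$effect_span
  v[ns & effect_score < 0] <- params$neutral
  v
}

#' Gene functional-deficit score of one individual
#'
#' The zygosity-weighted sum of v_scores over the variants an individual
#' carries in one gene: heterozygous calls contribute
#' `het_weight * v_score`, homozygous-alternate calls the full v_score.
#' An empty variant list scores 0 (a gene with no variants at all).
#'
#' @param v_scores numeric vector of raw v_scores (from [variant_score()]).
#' @param zygosity character vector over
#'   `c("heterozygous", "homozygous_alt")`, same length.
#' @param params a [vscore_params()] object.
#' @return A single non-negative score.
#' @export
gene_score <- function(v_scores, zygosity, params = vscore_params()) {
  if (!length(v_scores)) return(0)
  stopifnot(length(v_scores) == length(zygosity))
  bad <- setdiff(unique(zygosity), c("heterozygous", "homozygous_alt"))
  if (length(bad)) stop("zygosity must be heterozygous or homozygous_alt, got: ",
                        paste(bad, collapse = ", "))
  w <- ifelse(zygosity == "heterozygous", params$het_weight, 1)
  sum(w * v_scores)
}

#' Build the individuals x genes gene-score matrix
#'
#' Computes every individual's [gene_score()] for every gene touched by at
#' least one variant in at least one panel individual. A variant annotated
#' to several genes contributes to each of them; cells for (individual,
#' gene) pairs with no scored variant are 0.
#'
#' @param panel a filtered, annotated [new_panel()] object.
#' @param params a [vscore_params()] object.
#' @return Numeric matrix, rows = individuals, columns = genes (both named).
#' @export
build_gene_score_matrix <- function(panel, params = vscore_params()) {
  stopifnot(inherits(panel, "avadx_panel"))
  if (is.null(panel$annotations)) stop("panel is not annotated; run load_annotations()")
  if (nrow(panel$individuals) == 0L) stop("empty panel")
  ann <- panel$annotations
  if (nrow(ann) == 0L) stop("panel has no annotated variants")
  v <- variant_score(ann$consequence, ann$effect_score, params)
  g <- panel$geno[match(ann$key, panel$variants$key), , drop = FALSE]
  w <- matrix(0, nrow(g), ncol(g))
  w[g == 1L] <- params$het_weight
  w[g == 2L] <- 1
  w[is.na(g)] <- 0  # missing calls contribute nothing
  contrib <- w * v  # row-recycled by column: v along rows
  scores <- rowsum(contrib, group = ann$gene)
  out <- t(scores)
  rownames(out) <- panel$individuals$individual_id
  out[, order(colnames(out)), drop = FALSE]
}

#' Prune uninformative genes from a gene-score matrix
#'
#' Removes (a) genes with no variant in any individual (all-zero columns),
#' (b) genes whose score is identical and non-zero in every individual
#' (constant, hence uninformative), and (c) genes non-zero in exactly one
#' individual. Idempotent.
#'
#' @param scores matrix from [build_gene_score_matrix()].
#' @return The pruned matrix (possibly with zero columns).
#' @export
prune_genes <- function(scores) {
  stopifnot(is.matrix(scores))
  nz <- colSums(scores != 0)
  constant <- apply(scores, 2, function(x) length(unique(x)) == 1L)
  keep <- nz > 1L & !(constant & scores[1, ] != 0)
  scores[, keep, drop = FALSE]
}
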
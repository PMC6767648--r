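# Panel ingestion: VCF + phenotype + annotation tables, and the variant
# filters applied to training and test panels.

.AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))
.CONSEQUENCES <- c("synonymous", "nonsynonymous", "indel", "unscorable")

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a panel object
#'
#' A panel bundles the individuals of one cohort (IDs, CD/HC status, family
#' and batch labels) with its variant loci and a genotype matrix. Genotypes
#' are coded as the per-individual count of the variant's alternate allele:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing call. Multi-allelic VCF records are split into one row per
#' alternate allele before coding, so the coding is always per-allele.
#'
#' @param individuals data.frame with columns `individual_id`, `status`
#'   (`"CD"`, `"HC"`, or `NA` for unlabeled test individuals), `family_id`,
#'   `batch_id`.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `filter` (the VCF FILTER field).
#' @param geno integer matrix, variants x individuals, coded as above.
#' @param annotations `NULL`, or a data.frame with columns `key`, `gene`,
#'   `consequence`, `effect_score` (one row per variant-gene mapping).
#' @return An object of class `avadx_panel`.
#' @export
new_panel <- function(individuals, variants, geno, annotations = NULL) {
  stopifnot(is.data.frame(individuals), is.data.frame(variants))
  individuals$individual_id <- as.character(individuals$individual_id)
  if (anyDuplicated(individuals$individual_id)) {
    stop("duplicate individual IDs in panel")
  }
  bad <- setdiff(stats::na.omit(unique(individuals$status)), c("CD", "HC"))
  if (length(bad)) stop("unknown status label(s): ", paste(bad, collapse = ", "))
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  stopifnot(nrow(geno) == nrow(variants), ncol(geno) == nrow(individuals))
  rownames(geno) <- variants$key
  colnames(geno) <- individuals$individual_id
  structure(
    list(individuals = individuals, variants = variants, geno = geno,
         annotations = annotations, log = list()),
    class = "avadx_panel"
  )
}

#' @export
print.avadx_panel <- function(x, ...) {
  ncd <- sum(x$individuals$status == "CD", na.rm = TRUE)
  nhc <- sum(x$individuals$status == "HC", na.rm = TRUE)
  cat(sprintf("avadx panel: %d individuals (%d CD / %d HC), %d variants, %s\n",
              nrow(x$individuals), ncd, nhc, nrow(x$variants),
              if (is.null(x$annotations)) "unannotated"
              else sprintf("%d annotation rows", nrow(x$annotations))))
  invisible(x)
}

#' Load a multi-sample VCF and phenotype table into a panel
#'
#' Reads genotypes with \pkg{vcfR}, splits multi-allelic records into one
#' variant per alternate allele, and joins the phenotype table. Every sample
#' in the VCF must appear in the phenotype table; the converse is not
#' required (extra phenotype rows are ignored).
#'
#' @param vcf_path path to a VCF v4.x file (optionally bgzipped).
#' @param phenotype_path path to a tab-separated table with header
#'   `individual_id status family_id batch_id`.
#' @return An [new_panel()] object with raw, unfiltered variants.
#' @export
load_panel <- function(vcf_path, phenotype_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  pheno <- utils::read.table(phenotype_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, colClasses = "character")
  need <- c("individual_id", "status", "family_id", "batch_id")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  missing_ph <- setdiff(samples, pheno$individual_id)
  if (length(missing_ph)) {
    stop("VCF sample(s) absent from phenotype table: ",
         paste(missing_ph, collapse = ", "))
  }
  pheno <- pheno[match(samples, pheno$individual_id), need]
  pheno$status[pheno$status %in% c("", "NA", ".")] <- NA_character_

  # split multi-allelic records: one variant row per alt allele
  alt_list <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_along(alt_list), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  variants <- data.frame(
    chrom = as.character(fix[rec, "CHROM"]),
    pos = as.integer(fix[rec, "POS"]),
    ref = as.character(fix[rec, "REF"]),
    alt = unlist(alt_list, use.names = FALSE),
    filter = as.character(fix[rec, "FILTER"]),
    stringsAsFactors = FALSE
  )

  geno <- matrix(NA_integer_, nrow(variants), length(samples))
  for (j in seq_along(samples)) {
    col <- gt[, j]
    # per record, count the relevant alt allele index
    geno[, j] <- .gt_to_count_rows(col[rec], alt_idx)
  }
  new_panel(pheno, variants, geno)
}

# Vectorized GT decoding where each row may target a different alt index.
.gt_to_count_rows <- function(gt, alt_idx) {
  key <- paste(gt, alt_idx)
  u <- !duplicated(key)
  code <- mapply(function(g, k) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]", perl = TRUE)[[1]]
    if (any(al == "." | al == "")) return(NA_integer_)
    as.integer(sum(al == as.character(k)))
  }, gt[u], alt_idx[u], USE.NAMES = FALSE)
  code[match(key, key[u])]
}

#' Apply the training-panel variant filters
#'
#' Keeps only autosomal variants whose FILTER field is `PASS` and that have
#' a confident genotype call in every individual of the panel (any missing
#' call removes the locus). Sex chromosomes and mitochondrial records are
#' dropped. Variant order is preserved and the operation is idempotent.
#'
#' @param panel an [new_panel()] object.
#' @return The filtered panel.
#' @export
filter_training_variants <- function(panel) {
  stopifnot(inherits(panel, "avadx_panel"))
  keep <- panel$variants$filter == "PASS" &
    panel$variants$chrom %in% .AUTOSOMES &
    !apply(is.na(panel$geno), 1, any)
  if (!any(keep)) warning("no variants survive training filters")
  .subset_variants(panel, which(keep))
}

.subset_variants <- function(panel, idx) {
  panel$variants <- panel$variants[idx, , drop = FALSE]
  panel$geno <- panel$geno[idx, , drop = FALSE]
  if (!is.null(panel$annotations)) {
    panel$annotations <-
      panel$annotations[panel$annotations$key %in% panel$variants$key, , drop = FALSE]
  }
  panel
}

#' Variant locus keys of a panel
#'
#' @param panel an [new_panel()] object.
#' @return Character vector of `chrom:pos:ref:alt` keys, one per variant.
#' @export
panel_loci <- function(panel) panel$variants$key

#' Restrict a test panel to training loci
#'
#' Drops every test variant whose exact `(chrom, pos, ref, alt)` tuple is
#' not among the training loci; loci are matched as identity tuples, with no
#' left-normalization. Prediction is impossible with zero overlap, which is
#' a hard error.
#'
#' @param test_panel an [new_panel()] object.
#' @param train_loci character vector of keys from [panel_loci()] on a
#'   filtered training panel.
#' @return The restricted test panel; the retained fraction is recorded in
#'   `panel$log$retained_fraction`.
#' @export
restrict_test_variants <- function(test_panel, train_loci) {
  stopifnot(inherits(test_panel, "avadx_panel"))
  keep <- which(test_panel$variants$key %in% train_loci)
  if (!length(keep)) stop("no test variant overlaps the training loci; prediction impossible")
  frac <- length(keep) / nrow(test_panel$variants)
  test_panel <- .subset_variants(test_panel, keep)
  test_panel$log$retained_fraction <- frac
  test_panel
}

#' Join a variant annotation table onto a panel
#'
#' The annotation table maps each variant to one or more genes, a
#' consequence class, and (for nonsynonymous variants) a functional-effect
#' score in \[-100, 100\]. A variant mapping to several genes contributes to
#' each of them. Panel variants with no annotation row are dropped and
#' counted; nonsynonymous rows lacking an effect score are demoted to
#' `unscorable` (they will receive the fixed unscorable v_score).
#'
#' @param panel an [new_panel()] object (normally already filtered).
#' @param annotation_path tab-separated table with header
#'   `chrom pos ref alt gene consequence effect_score` (`effect_score` empty
#'   or `NA` where not applicable).
#' @return The panel with an `annotations` data.frame attached;
#'   `panel$log$n_unannotated` counts dropped variants.
#' @export
load_annotations <- function(panel, annotation_path) {
  stopifnot(inherits(panel, "avadx_panel"))
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character", pos = "integer",
                                          ref = "character", alt = "character",
                                          gene = "character",
                                          consequence = "character",
                                          effect_score = "numeric"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "effect_score")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  bad_cons <- setdiff(unique(ann$consequence), .CONSEQUENCES)
  if (length(bad_cons)) stop("unknown consequence class(es): ", paste(bad_cons, collapse = ", "))
  if (any(!is.na(ann$effect_score) & abs(ann$effect_score) > 100)) {
    stop("effect_score outside [-100, 100] in annotation table")
  }
  no_score <- ann$consequence == "nonsynonymous" & is.na(ann$effect_score)
  if (any(no_score)) {
    message(sum(no_score), " nonsynonymous annotation row(s) without effect score treated as unscorable")
    ann$consequence[no_score] <- "unscorable"
  }
  ann <- ann[ann$key %in% panel$variants$key, c("key", "gene", "consequence", "effect_score")]
  annotated <- panel$variants$key %in% ann$key
  n_drop <- sum(!annotated)
  if (n_drop) message(n_drop, " variant(s) without annotation dropped")
  panel <- .subset_variants(panel, which(annotated))
  panel$annotations <- ann
  panel$log$n_unannotated <- n_drop
  panel
}

#' Subset a panel to a set of individuals
#'
#' Used to carve training and test cohorts out of one generated population.
#' With `drop_empty = TRUE` (default), variant loci at which no retained
#' individual carries an alternate allele are removed, mimicking a VCF
#' called on just those samples.
#'
#' @param panel an [new_panel()] object.
#' @param individual_ids IDs to keep.
#' @param drop_empty drop loci with no alt carrier among the kept samples.
#' @return The subset panel.
#' @export
subset_panel <- function(panel, individual_ids, drop_empty = TRUE) {
  stopifnot(inherits(panel, "avadx_panel"))
  idx <- match(individual_ids, panel$individuals$individual_id)
  if (anyNA(idx)) stop("unknown individual ID(s): ",
                       paste(individual_ids[is.na(idx)], collapse = ", "))
  panel$individuals <- panel$individuals[idx, , drop = FALSE]
  panel$geno <- panel$geno[, idx, drop = FALSE]
  if (drop_empty) {
    carried <- rowSums(panel$geno > 0, na.rm = TRUE) > 0
    panel <- .subset_variants(panel, which(carried))
  }
  panel
}
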
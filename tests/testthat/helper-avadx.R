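# Shared fixture builders: tiny in-memory panels and files, built in code.

# A hand-sized panel: 5 individuals, explicit genotypes.
# geno rows follow `variants` order; values 0/1/2/NA.
toy_panel <- function(geno, variants, status = NULL, family = NULL,
                      batch = NULL, n = ncol(geno)) {
  ids <- sprintf("I%02d", seq_len(n))
  ind <- data.frame(
    individual_id = ids,
    status = status %||% rep(c("CD", "HC"), length.out = n),
    family_id = family %||% ids,
    batch_id = batch %||% "B1",
    stringsAsFactors = FALSE
  )
  new_panel(ind, variants, geno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small VCF + phenotype + annotation fixture to a temp dir.
write_toy_vcf_set <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "1\t200\t.\tC\tT,G\t50\tPASS\t.\tGT\t1/2\t0/1\t./.",
    "chrX\t300\t.\tG\tA\t50\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "2\t400\t.\tT\tC\t50\tq10\t.\tGT\t0/1\t0/0\t0/0",
    "3\t500\t.\tG\tC\t50\tPASS\t.\tGT\t0/1\t0/1\t1/1"
  )
  pheno <- c(
    "individual_id\tstatus\tfamily_id\tbatch_id",
    "S1\tCD\tS1\tB1", "S2\tCD\tS2\tB1", "S3\tHC\tS3\tB1"
  )
  anno <- c(
    "chrom\tpos\tref\talt\tgene\tconsequence\teffect_score",
    "1\t100\tA\tG\tGENE1\tnonsynonymous\t50",
    "1\t100\tA\tG\tGENE2\tnonsynonymous\t50",   # multi-gene mapping
    "1\t200\tC\tT\tGENE1\tsynonymous\tNA",
    "1\t200\tC\tG\tGENE1\tindel\tNA",
    "3\t500\tG\tC\tGENE3\tnonsynonymous\tNA"    # missing score -> unscorable
    # 2:400 and chrX:300 left unannotated on purpose
  )
  paths <- list(vcf = file.path(dir, "toy.vcf"),
                pheno = file.path(dir, "pheno.tsv"),
                anno = file.path(dir, "anno.tsv"))
  writeLines(vcf, paths$vcf)
  writeLines(pheno, paths$pheno)
  writeLines(anno, paths$anno)
  paths
}

# Small, fast synthetic cohorts for unit tests (acceptance tests use the
# generator defaults, which are the full study conditions).
small_cohort_config <- function(seed, n_cases = 30, n_controls = 30,
                                n_genes = 300, n_causal = 5,
                                case_enrichment = 0.5, ...) {
  cohort_config(n_cases = n_cases, n_controls = n_controls,
                n_genes = n_genes, n_causal = n_causal,
                case_enrichment = case_enrichment, seed = seed, ...)
}

# Independent brute-force oracle for the gene-score matrix: loops over
# individuals, genes, and annotation rows, never touching matrix algebra.
brute_force_gene_scores <- function(panel, params = vscore_params()) {
  ids <- panel$individuals$individual_id
  genes <- sort(unique(panel$annotations$gene))
  out <- matrix(0, length(ids), length(genes), dimnames = list(ids, genes))
  for (i in seq_along(ids)) {
    for (r in seq_len(nrow(panel$annotations))) {
      ann <- panel$annotations[r, ]
      g <- panel$geno[match(ann$key, panel$variants$key), ids[i]]
      if (is.na(g) || g == 0) next
      v <- variant_score(ann$consequence, ann$effect_score, params)
      w <- if (g == 1) params$het_weight else 1
      out[ids[i], ann$gene] <- out[ids[i], ann$gene] + w * v
    }
  }
  out
}

# Independent DKM oracle: for one gene, enumerate every threshold between
# sorted values and evaluate the impurity decrease from first principles.
brute_force_dkm_merit <- function(x, labels, w_cd = 1, w_hc = 1) {
  w <- ifelse(labels == "CD", w_cd, w_hc)
  f <- function(p) 2 * sqrt(p * (1 - p))
  imp <- function(idx) {
    if (!length(idx)) return(0)
    f(sum(w[idx] * (labels[idx] == "CD")) / sum(w[idx]))
  }
  root <- imp(seq_along(x))
  thr <- sort(unique(x))
  if (length(thr) < 2) return(0)
  mids <- (thr[-1] + thr[-length(thr)]) / 2
  best <- 0
  for (t in mids) {
    left <- which(x <= t); right <- which(x > t)
    dec <- root - (sum(w[left]) / sum(w)) * imp(left) -
      (sum(w[right]) / sum(w)) * imp(right)
    best <- max(best, dec)
  }
  best
}
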
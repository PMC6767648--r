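# Fully synthetic diploid case-control exome cohorts with planted disease
# genes, family structure, and inter-batch shifts, so every pipeline stage
# is testable without access-restricted data.

#' Synthetic cohort configuration
#'
#' Defaults emulate a small exome case-control panel with a handful of
#' planted disease genes: genotypes are drawn under Hardy-Weinberg
#' equilibrium at per-variant allele frequencies from `af_range`; each
#' causal gene carries one high-effect ("risk") nonsynonymous variant
#' whose carrier probability is elevated by `case_enrichment` in cases;
#' background nonsynonymous variants draw effect scores from a mixture
#' centred below 0 (mostly neutral); a fraction of variants are
#' synonymous or indels; `n_families` related pairs share a fraction of
#' their genotypes. No linkage disequilibrium, population structure, or
#' sequencing-error model is simulated.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_genes,n_causal total and planted disease gene counts.
#' @param variants_per_gene mean variants per gene (min 1).
#' @param af_range alternate allele frequency range (uniform draw).
#' @param case_enrichment excess carrier probability of each causal
#'   gene's risk variant in cases, in \[0, 1\].
#' @param causal_effect_range effect-score range for risk variants.
#' @param background_effect_mean,background_effect_sd normal parameters
#'   (clamped to \[-100, 100\]) for background nonsynonymous scores.
#' @param frac_synonymous,frac_indel consequence-class mix of background
#'   variants.
#' @param n_families number of related same-status pairs.
#' @param family_share fraction of genotypes a pair shares.
#' @param non_pass_fraction fraction of variants marked non-PASS (to
#'   exercise the filters).
#' @param missing_rate per-call missingness probability.
#' @param seed RNG seed; the generated cohort is a deterministic function
#'   of the configuration.
#' @return list of class `avadx_cohort_config`.
#' @export
cohort_config <- function(n_cases = 60, n_controls = 60,
                          n_genes = 2000, n_causal = 10,
                          variants_per_gene = 3, af_range = c(0.005, 0.15),
                          case_enrichment = 0.5,
                          causal_effect_range = c(40, 100),
                          background_effect_mean = -20,
                          background_effect_sd = 30,
                          frac_synonymous = 0.3, frac_indel = 0.03,
                          n_families = 2, family_share = 0.5,
                          non_pass_fraction = 0, missing_rate = 0,
                          seed = 1) {
  cfg <- as.list(environment())
  if (n_causal > n_genes) stop("n_causal must not exceed n_genes")
  probs <- c(case_enrichment, frac_synonymous, frac_indel,
             non_pass_fraction, missing_rate, family_share, af_range)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (frac_synonymous + frac_indel > 1) stop("consequence fractions exceed 1")
  if (n_genes < 1 || variants_per_gene < 1) stop("infeasible config: no variants")
  if (2 * n_families > min(n_cases, n_controls)) stop("too many families for the cohort size")
  structure(cfg, class = "avadx_cohort_config")
}

#' Generate a synthetic case-control cohort
#'
#' Draws a full cohort under [cohort_config()]: variant table, diploid
#' genotypes, per-variant annotations (gene, consequence, effect score),
#' and a phenotype table with family and batch labels (everyone starts in
#' batch `"B1"`; see [plant_batch_shift()]). The planted truth (causal
#' genes and their risk variant keys) is recorded alongside.
#'
#' @param config an [cohort_config()] object.
#' @return list of class `avadx_cohort` with elements `panel` (an
#'   annotated [new_panel()] object), `truth` (list: `causal_genes`,
#'   `risk_keys`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "avadx_cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  ids <- c(sprintf("CASE%03d", seq_len(config$n_cases)),
           sprintf("CTRL%03d", seq_len(config$n_controls)))
  status <- c(rep("CD", config$n_cases), rep("HC", config$n_controls))

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  causal <- sort(sample(genes, config$n_causal))
  nv <- 1L + stats::rpois(config$n_genes, max(0, config$variants_per_gene - 1))
  gene_of <- rep(genes, nv)
  V <- length(gene_of)
  within <- unlist(lapply(nv, seq_len), use.names = FALSE)

  gene_idx <- rep(seq_len(config$n_genes), nv)
  chrom <- as.character(1L + (gene_idx - 1L) %% 22L)
  pos <- gene_idx * 100000L + within * 10L

  # consequence classes; the first variant of each causal gene is the
  # high-effect risk variant
  u <- stats::runif(V)
  consequence <- ifelse(u < config$frac_synonymous, "synonymous",
                 ifelse(u < config$frac_synonymous + config$frac_indel,
                        "indel", "nonsynonymous"))
  is_risk <- gene_of %in% causal & within == 1L
  consequence[is_risk] <- "nonsynonymous"
  effect <- rep(NA_real_, V)
  ns <- consequence == "nonsynonymous"
  effect[ns] <- pmin(100, pmax(-100,
    stats::rnorm(sum(ns), config$background_effect_mean, config$background_effect_sd)))
  effect[is_risk] <- stats::runif(sum(is_risk),
                                  config$causal_effect_range[1],
                                  config$causal_effect_range[2])

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  ins <- consequence == "indel"
  alt[ins] <- paste0(alt[ins], sample(bases, sum(ins), replace = TRUE))

  af <- stats::runif(V, config$af_range[1], config$af_range[2])
  geno <- matrix(stats::rbinom(V * n, 2L, rep(af, n)), nrow = V)

  # carrier enrichment of risk variants in cases
  for (i in which(is_risk)) {
    lift <- stats::runif(config$n_cases) < config$case_enrichment &
      geno[i, seq_len(config$n_cases)] == 0L
    geno[i, seq_len(config$n_cases)][lift] <- 1L
  }

  # related pairs: second member copies a share of the first's genotypes
  family_id <- ids
  if (config$n_families > 0) {
    case_pool <- seq_len(config$n_cases)
    ctrl_pool <- config$n_cases + seq_len(config$n_controls)
    for (k in seq_len(config$n_families)) {
      pool <- if (k %% 2L == 1L) case_pool else ctrl_pool
      pair <- sample(pool[family_id[pool] == ids[pool]], 2)
      shared <- stats::runif(V) < config$family_share
      geno[shared, pair[2]] <- geno[shared, pair[1]]
      family_id[pair] <- sprintf("FAM%02d", k)
    }
  }

  if (config$missing_rate > 0) {
    geno[matrix(stats::runif(V * n) < config$missing_rate, V, n)] <- NA_integer_
  }
  filter <- rep("PASS", V)
  if (config$non_pass_fraction > 0) {
    filter[stats::runif(V) < config$non_pass_fraction] <- "VQSRTrancheSNP99.90to100.00"
  }

  individuals <- data.frame(individual_id = ids, status = status,
                            family_id = family_id, batch_id = "B1",
                            stringsAsFactors = FALSE)
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         filter = filter, stringsAsFactors = FALSE)
  panel <- new_panel(individuals, variants, geno)
  panel$annotations <- data.frame(
    key = panel$variants$key, gene = gene_of, consequence = consequence,
    effect_score = effect, stringsAsFactors = FALSE)

  structure(list(panel = panel,
                 truth = list(causal_genes = causal,
                              risk_keys = panel$variants$key[is_risk]),
                 config = config),
            class = "avadx_cohort")
}

#' @export
print.avadx_cohort <- function(x, ...) {
  cat(sprintf("avadx synthetic cohort: %d CD / %d HC, %d genes (%d causal), %d variants\n",
              x$config$n_cases, x$config$n_controls, x$config$n_genes,
              x$config$n_causal, nrow(x$panel$variants)))
  invisible(x)
}

#' Displace a batch of individuals' gene scores
#'
#' Plants an inter-batch shift: for a fraction of genes, the gene's
#' existing variant genotypes gain one alternate allele (0/0 to 0/1, 0/1
#' to 1/1; missing calls become 0/1) in each shifted individual with
#' probability 0.8, variant by variant, until the mean gene-score
#' displacement reaches `shift` (capped by the gene's variant content).
#' Because only loci already present in the cohort are touched, the shift
#' survives restriction of a test panel to training loci — as real
#' calling-pipeline batch effects do — and the displacement varies
#' between individuals, as real batch effects do. The shifted individuals
#' are relabelled batch `"B2"`. With `shift = 0` only the batch label
#' changes.
#'
#' @param cohort an [generate_cohort()] object.
#' @param shift target mean gene-score displacement per affected gene.
#' @param affected_fraction fraction of genes displaced.
#' @param individuals IDs to shift; default: the second half of the cases
#'   and the second half of the controls.
#' @param seed RNG seed for choosing affected genes.
#' @return The modified cohort.
#' @export
plant_batch_shift <- function(cohort, shift, affected_fraction = 0.5,
                              individuals = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "avadx_cohort"), shift >= 0)
  panel <- cohort$panel
  if (is.null(individuals)) {
    ind <- panel$individuals
    cases <- ind$individual_id[ind$status == "CD"]
    ctrls <- ind$individual_id[ind$status == "HC"]
    individuals <- c(cases[seq(ceiling(length(cases) / 2) + 1, length(cases))],
                     ctrls[seq(ceiling(length(ctrls) / 2) + 1, length(ctrls))])
  }
  cols <- match(individuals, panel$individuals$individual_id)
  if (anyNA(cols)) stop("unknown individual ID(s) in batch shift")
  set.seed(seed %||% (cohort$config$seed + 1L))

  if (shift > 0) {
    ann <- panel$annotations
    genes <- unique(ann$gene)
    affected <- sample(genes, round(affected_fraction * length(genes)))
    params <- vscore_params()
    v_all <- variant_score(ann$consequence, ann$effect_score, params)
    zyg_w <- function(g) ifelse(is.na(g), 0,
                                ifelse(g == 1L, params$het_weight, g / 2))
    for (g in affected) {
      rows <- match(ann$key[ann$gene == g], panel$variants$key)
      vs <- v_all[ann$gene == g]
      added <- 0
      for (j in seq_along(rows)) {
        cur <- panel$geno[rows[j], cols]
        bumped <- pmin(ifelse(is.na(cur), 0L, cur) + 1L, 2L)
        hit <- stats::runif(length(cols)) < 0.8
        new <- ifelse(hit, bumped, ifelse(is.na(cur), NA_integer_, cur))
        added <- added + vs[j] * mean(zyg_w(new) - zyg_w(cur))
        panel$geno[rows[j], cols] <- new
        if (added >= shift) break
      }
    }
  }
  panel$individuals$batch_id[cols] <- "B2"
  cohort$panel <- panel
  cohort
}

#' Write a cohort to VCF + annotation + phenotype files
#'
#' Emits a VCF v4.2 (`cohort.vcf`), an annotation table
#' (`annotations.tsv`), and a phenotype table (`phenotype.tsv`) that
#' round-trip through [load_panel()] and [load_annotations()] with no
#' drops. Output is byte-deterministic for a given cohort.
#'
#' @param cohort an [generate_cohort()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths (named list).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "avadx_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- cohort$panel
  vcf_path <- file.path(dir, "cohort.vcf")
  anno_path <- file.path(dir, "annotations.tsv")
  pheno_path <- file.path(dir, "phenotype.tsv")

  gt <- matrix("./.", nrow(panel$geno), ncol(panel$geno))
  gt[which(panel$geno == 0L)] <- "0/0"
  gt[which(panel$geno == 1L)] <- "0/1"
  gt[which(panel$geno == 2L)] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=avadx synthetic cohort generator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals$individual_id), collapse = "\t")
  )
  body <- paste(panel$variants$chrom, panel$variants$pos, ".",
                panel$variants$ref, panel$variants$alt, "50",
                panel$variants$filter, ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  ann <- panel$annotations
  v <- panel$variants[match(ann$key, panel$variants$key), ]
  utils::write.table(
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               gene = ann$gene, consequence = ann$consequence,
               effect_score = ann$effect_score),
    anno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$individuals, pheno_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf_path, annotations = anno_path, phenotype = pheno_path))
}
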
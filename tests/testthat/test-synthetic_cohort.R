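# The synthetic cohort generator: determinism, planted structure, shifts.

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_causal = 10, n_genes = 5), "n_causal")
  expect_error(cohort_config(case_enrichment = 1.5), "probabilities")
  expect_error(cohort_config(frac_synonymous = 0.8, frac_indel = 0.5), "exceed 1")
  expect_error(cohort_config(n_genes = 0, n_causal = 0), "infeasible")
  expect_error(cohort_config(n_families = 20, n_cases = 10, n_controls = 10),
               "families")
})

test_that("the same seed reproduces byte-identical output files", {
  cfg <- small_cohort_config(seed = 77, n_cases = 8, n_controls = 8,
                             n_genes = 30)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("cohort.vcf", "annotations.tsv", "phenotype.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("genotype frequencies follow Hardy-Weinberg at the configured frequencies", {
  cfg <- cohort_config(n_cases = 500, n_controls = 500, n_genes = 60,
                       n_causal = 0, variants_per_gene = 2,
                       af_range = c(0.1, 0.1), n_families = 0, seed = 3)
  co <- generate_cohort(cfg)
  g <- co$panel$geno
  p <- 0.1
  expect_equal(mean(g == 1L), 2 * p * (1 - p), tolerance = 0.05)
  expect_equal(mean(g == 2L), p^2, tolerance = 0.2)
  # carrier frequency within binomial sampling error at n = 1000
  carrier <- rowMeans(g > 0)
  expect_equal(mean(carrier), 1 - (1 - p)^2, tolerance = 0.02)
})

test_that("risk variants are carrier-enriched in cases by the configured excess", {
  cfg <- cohort_config(n_cases = 500, n_controls = 500, n_genes = 40,
                       n_causal = 20, case_enrichment = 0.4,
                       af_range = c(0.05, 0.05), n_families = 0, seed = 8)
  co <- generate_cohort(cfg)
  risk <- match(co$truth$risk_keys, co$panel$variants$key)
  cd_cols <- which(co$panel$individuals$status == "CD")
  hc_cols <- which(co$panel$individuals$status == "HC")
  f_cd <- mean(co$panel$geno[risk, cd_cols] > 0)
  f_hc <- mean(co$panel$geno[risk, hc_cols] > 0)
  q0 <- 1 - 0.95^2
  expect_equal(f_hc, q0, tolerance = 0.1)
  # excess carrier probability = enrichment * (1 - baseline)
  expect_equal(f_cd - f_hc, 0.4 * (1 - q0), tolerance = 0.05)
})

test_that("family pairs share genotypes and get one family ID", {
  co <- generate_cohort(small_cohort_config(seed = 12, n_cases = 20,
                                            n_controls = 20, n_genes = 100,
                                            n_families = 2))
  fam <- co$panel$individuals$family_id
  expect_equal(sum(fam == "FAM01"), 2L)
  expect_equal(sum(fam == "FAM02"), 2L)
  pair <- which(fam == "FAM01")
  same_status <- co$panel$individuals$status[pair]
  expect_length(unique(same_status), 1L)
  agree <- mean(co$panel$geno[, pair[1]] == co$panel$geno[, pair[2]])
  unrelated <- mean(co$panel$geno[, pair[1]] ==
                    co$panel$geno[, which(fam == "FAM02")[1]])
  expect_gt(agree, unrelated)
})

test_that("a zero shift leaves the batches statistically indistinguishable", {
  co <- generate_cohort(small_cohort_config(seed = 91, n_cases = 20,
                                            n_controls = 20, n_genes = 120,
                                            case_enrichment = 0))
  b2 <- co$panel$individuals$individual_id[c(11:20, 31:40)]
  co0 <- plant_batch_shift(co, shift = 0, individuals = b2)
  expect_equal(sort(unique(co0$panel$individuals$batch_id)), c("B1", "B2"))
  m <- prune_genes(build_gene_score_matrix(co0$panel))
  grp <- rownames(m) %in% b2
  pvals <- apply(m, 2, function(x)
    suppressWarnings(ks.test(x[grp], x[!grp], exact = TRUE)$p.value))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("a large shift displaces gene scores by about the target amount", {
  co <- generate_cohort(small_cohort_config(seed = 92, n_cases = 20,
                                            n_controls = 20, n_genes = 120,
                                            case_enrichment = 0,
                                            af_range = c(0.1, 0.3)))
  b2 <- co$panel$individuals$individual_id[c(11:20, 31:40)]
  m0 <- build_gene_score_matrix(co$panel)
  shifted <- plant_batch_shift(co, shift = 0.8, affected_fraction = 0.5,
                               individuals = b2)
  m1 <- build_gene_score_matrix(shifted$panel)
  delta <- colMeans(m1[b2, colnames(m0)]) - colMeans(m0[b2, ])
  moved <- delta[delta > 1e-9]
  # roughly the affected fraction of genes move, by a noticeable amount
  # (a gene's displacement is capped by its own variant content, so the
  # mean displacement sits well below an ambitious target shift)
  expect_equal(length(moved) / ncol(m0), 0.5, tolerance = 0.2)
  expect_gt(mean(moved), 0.05)
  # batch 1 individuals are untouched
  b1 <- setdiff(rownames(m0), b2)
  expect_equal(m1[b1, colnames(m0)], m0[b1, ])
})
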
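# Case-exclusive selection, distribution screens, DKM ranking, overlap
# statistics, and the variant-level Fisher screen.

make_labels <- function(n_cd, n_hc) c(rep("CD", n_cd), rep("HC", n_hc))

test_that("the case-exclusive pattern needs >= min_cases cases and zero controls", {
  labels <- make_labels(5, 5)
  m <- cbind(
    three_cd = c(1, 1, 1, 0, 0, rep(0, 5)),
    two_cd = c(1, 1, 0, 0, 0, rep(0, 5)),
    leaky = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  )
  rownames(m) <- sprintf("I%02d", 1:10)
  expect_equal(select_dis(m, labels), "three_cd")
  # monotone in min_cases: raising it never adds genes
  for (k in 1:4) {
    expect_true(all(select_dis(m, labels, min_cases = k + 1) %in%
                    select_dis(m, labels, min_cases = k)))
  }
})

test_that("the KS screen uses the exact two-sample null", {
  labels <- make_labels(5, 5)
  m <- cbind(separated = c(rep(1, 5), rep(0, 5)),
             identical = rep(c(1, 2, 3, 4, 5), 2))
  rownames(m) <- sprintf("I%02d", 1:10)
  # D = 1 has exact p = 2 / choose(10, 5) ~ 0.0079 < 0.05
  expect_equal(screen_by_test(m, labels, "KS"), "separated")
  p_exact <- 2 / choose(10, 5)
  expect_lt(p_exact, 0.05)
  expect_equal(suppressWarnings(
    ks.test(m[1:5, 1], m[6:10, 1], exact = TRUE)$p.value), p_exact)
})

test_that("constant and identically distributed genes are never selected", {
  labels <- make_labels(5, 5)
  m <- cbind(constant = rep(0.5, 10), identical = rep(1:5, 2))
  rownames(m) <- sprintf("I%02d", 1:10)
  expect_length(screen_by_test(m, labels, "KS"), 0)
  expect_length(screen_by_test(m, labels, "TT"), 0)
})

test_that("the t-test screen picks up clear mean shifts", {
  set.seed(1)
  labels <- make_labels(10, 10)
  m <- cbind(shifted = c(rnorm(10, 3), rnorm(10, 0)),
             null = rnorm(20))
  rownames(m) <- sprintf("I%02d", 1:20)
  expect_equal(screen_by_test(m, labels, "TT"), "shifted")
})

test_that("DKM merit equals exhaustive split search on small matrices", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    labels <- sample(c("CD", "HC"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("CD", "HC")
    m <- matrix(sample(0:3, n * 4, replace = TRUE) / 2, n, 4,
                dimnames = list(NULL, paste0("g", 1:4)))
    ranked <- dkm_rank(m, labels)
    oracle <- vapply(colnames(m), function(g)
      brute_force_dkm_merit(m[, g], labels), numeric(1))
    expect_equal(setNames(ranked$merit, ranked$gene),
                 sort(oracle, decreasing = TRUE)[ranked$gene],
                 tolerance = 1e-12)
  }
})

test_that("DKM merit behaves at the extremes and respects cost weights", {
  labels <- make_labels(3, 3)
  m <- cbind(perfect = c(5, 6, 7, 1, 2, 3), constant = rep(1, 6))
  rownames(m) <- sprintf("I%02d", 1:6)
  r <- dkm_rank(m, labels)
  # perfect separation: both children pure, merit = root impurity = f(1/2) = 1
  expect_equal(r$merit[r$gene == "perfect"], 1)
  expect_equal(r$merit[r$gene == "constant"], 0)
  # cost weighting shifts the root class probability
  cost <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE)
  r_cost <- dkm_rank(m, labels, cost_matrix = cost)
  expect_equal(r_cost$merit[r_cost$gene == "perfect"],
               brute_force_dkm_merit(m[, "perfect"], labels, w_cd = 3, w_hc = 1))
})

test_that("DKM ranking is invariant to strictly monotone transforms", {
  set.seed(11)
  labels <- make_labels(8, 8)
  m <- matrix(rexp(16 * 5), 16, 5, dimnames = list(NULL, paste0("g", 1:5)))
  r1 <- dkm_rank(m, labels)
  r2 <- dkm_rank(log1p(m * 3), labels)
  expect_identical(r1$gene, r2$gene)
  expect_equal(r1$merit, r2$merit, tolerance = 1e-12)
})

test_that("merit ties break lexicographically and top_k over-ask warns", {
  labels <- make_labels(3, 3)
  m <- cbind(zz = rep(1, 6), aa = rep(1, 6))  # both merit 0
  rownames(m) <- sprintf("I%02d", 1:6)
  expect_identical(dkm_rank(m, labels)$gene, c("aa", "zz"))
  expect_warning(r <- dkm_rank(m, labels, top_k = 10), "top_k")
  expect_equal(nrow(r), 2L)
})

test_that("hypergeometric overlap matches closed forms and full enumeration", {
  bg <- paste0("g", 1:20)
  expect_equal(gene_set_overlap(bg[1:5], bg[6:10], bg)$p, 1)  # overlap 0
  full <- gene_set_overlap(bg[1:5], bg[1:5], bg)
  expect_equal(full$overlap, 5L)
  expect_equal(full$p, 1 / choose(20, 5))

  # exhaustive oracle at N = 30: enumerate all draws of |a| = 4
  bg30 <- paste0("g", 1:30)
  set.seed(3)
  b <- sample(bg30, 7)
  a <- sample(bg30, 4)
  obs <- gene_set_overlap(a, b, bg30)
  draws <- combn(30, 4)
  ov <- colSums(matrix(bg30[draws] %in% b, nrow = 4))
  expect_equal(obs$p, mean(ov >= obs$overlap), tolerance = 1e-12)
  expect_error(gene_set_overlap(a, b, character(0)), "background")
  expect_error(gene_set_overlap(c(a, "not_in_bg"), b, bg30), "subsets")
})

test_that("the variant Fisher screen counts carriers and corrects with BH", {
  variants <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                         filter = "PASS")
  # v1: all 10 CD carry, no HC; v2: equal rates; v3: nobody
  geno <- rbind(c(rep(1L, 10), rep(0L, 10)),
                rep(c(1L, 0L), 10),
                rep(0L, 20))
  panel <- toy_panel(geno, variants, status = make_labels(10, 10))
  out <- variant_fisher_screen(panel)
  expect_equal(out$carriers_cd, c(10, 5, 0))
  expect_equal(out$carriers_hc, c(0, 5, 0))
  # exact two-sided null by hypergeometric enumeration for v1
  probs <- dhyper(0:10, 10, 10, 10)
  p_manual <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(out$p[1], p_manual, tolerance = 1e-9)
  expect_equal(out$p[2], 1)
  expect_equal(out$p[3], 1)
  expect_equal(out$q, p.adjust(out$p, "BH"))
})

test_that("the Fisher screen finds nothing significant on null panels", {
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(small_cohort_config(seed = 700 + s, n_cases = 25,
                                              n_controls = 25, n_genes = 150,
                                              case_enrichment = 0))
    out <- variant_fisher_screen(filter_training_variants(co$panel))
    sum(out$q < 0.05)
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("feature selection inside a fold ignores the held-out individual", {
  co <- generate_cohort(small_cohort_config(seed = 31, n_cases = 12,
                                            n_controls = 12, n_genes = 60))
  panel <- filter_training_variants(co$panel)
  m <- prune_genes(build_gene_score_matrix(panel))
  cv1 <- run_crossvalidation(m, panel$individuals, method = "ks5",
                             n_repeats = 1, seed = 5)
  # perturb one held-out individual's scores wildly and rerun
  target <- panel$individuals$individual_id[1]
  m2 <- m
  m2[target, ] <- m2[target, ] + 100
  cv2 <- run_crossvalidation(m2, panel$individuals, method = "ks5",
                             n_repeats = 1, seed = 5)
  fold_idx <- which(vapply(cv1$folds, function(f) target %in% f$held_out,
                           logical(1)))
  expect_identical(cv1$fold_gene_sets[[fold_idx]],
                   cv2$fold_gene_sets[[fold_idx]])
})
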
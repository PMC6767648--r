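# Fold planning, bootstrap balancing, SVM training/scoring, CV, permutations.

fold_pheno <- function(n, fam = NULL) {
  data.frame(individual_id = sprintf("P%03d", seq_len(n)),
             status = rep(c("CD", "HC"), length.out = n),
             family_id = fam %||% sprintf("P%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("family groups are held out together, one fold per group", {
  # 111 individuals with two related pairs -> 109 folds
  fam <- sprintf("P%03d", 1:111)
  fam[c(76, 111)] <- "FAMA"
  fam[c(87, 110)] <- "FAMB"
  plan <- plan_loocv_folds(fold_pheno(111, fam))
  expect_length(plan, 109L)
  held <- lapply(plan, `[[`, "held_out")
  expect_setequal(unlist(held), sprintf("P%03d", 1:111))    # partition
  expect_equal(sum(lengths(held) == 2), 2L)
  # family members never appear in their own training side
  for (f in plan) expect_length(intersect(f$held_out, f$train), 0L)

  # no families -> n singleton folds; a family of 3 in a panel of 5 -> 3 folds
  expect_length(plan_loocv_folds(fold_pheno(7)), 7L)
  expect_length(plan_loocv_folds(fold_pheno(5, c("F", "F", "F", "x", "y"))), 3L)
})

test_that("bootstrap balancing matches the major class or an explicit target", {
  ids <- sprintf("P%03d", 1:111)
  labels <- c(rep("CD", 64), rep("HC", 47))
  set.seed(1)
  bal <- bootstrap_balance(ids, labels)
  expect_equal(sum(bal %in% ids[1:64]), 64L)
  expect_equal(sum(bal %in% ids[65:111]), 64L)
  expect_setequal(intersect(bal, ids[1:64]), ids[1:64])  # major class kept as-is

  even <- bootstrap_balance(ids[1:20], rep(c("CD", "HC"), 10))
  expect_setequal(even, ids[1:20])                       # already balanced
  expect_length(even, 20L)

  big <- bootstrap_balance(ids, labels, target = 500)
  expect_equal(sum(big %in% ids[1:64]), 500L)
  expect_equal(sum(big %in% ids[65:111]), 500L)
  expect_error(bootstrap_balance(ids[1:3], rep("CD", 3)), "non-empty")
})

test_that("the SVM separates separable classes and is deterministic", {
  set.seed(42)
  n <- 40
  x <- rbind(matrix(rnorm(n * 5, 2), n, 5), matrix(rnorm(n * 5, -2), n, 5))
  colnames(x) <- paste0("g", 1:5)
  rownames(x) <- sprintf("P%03d", 1:(2 * n))
  labels <- c(rep("CD", n), rep("HC", n))
  fit <- train_model(x, labels)
  s <- predict_scores(fit, x)
  expect_gt(mean((s > 0) == (labels == "CD")), 0.95)
  expect_gt(cor(s, ifelse(labels == "CD", 100, -100)), 0.8)

  # same data, same seed -> bit-identical scores
  fit2 <- train_model(x, labels)
  expect_identical(predict_scores(fit2, x), s)

  # gene-list mismatch is a hard error; same set reordered is realigned
  bad <- x; colnames(bad) <- paste0("h", 1:5)
  expect_error(predict_scores(fit, bad), "gene list")
  reord <- x[, c(3, 1, 2, 5, 4)]
  expect_equal(predict_scores(fit, reord), s)
})

test_that("a two-point training set scores the midpoint near zero", {
  a <- c(1, 1); b <- -a  # one duplicated point per class
  x <- rbind(matrix(a, 5, 2, byrow = TRUE), matrix(b, 5, 2, byrow = TRUE))
  colnames(x) <- c("g1", "g2")
  labels <- rep(c("CD", "HC"), each = 5)
  fit <- train_model(x, labels, model_config(scale = FALSE))
  mid <- predict_scores(fit, matrix(0, 1, 2, dimnames = list("m", c("g1", "g2"))))
  expect_lt(abs(mid), 1e-3)
})

test_that("classification mode produces CD-positive decision scores", {
  set.seed(8)
  n <- 30
  x <- rbind(matrix(rnorm(n * 4, 1.5), n, 4), matrix(rnorm(n * 4, -1.5), n, 4))
  colnames(x) <- paste0("g", 1:4)
  labels <- c(rep("CD", n), rep("HC", n))
  fit <- train_model(x, labels, model_config(mode = "classification"))
  s <- predict_scores(fit, x)
  expect_gt(mean(s[labels == "CD"]), mean(s[labels == "HC"]))
})

test_that("cross-validation never trains on held-out individuals and is reproducible", {
  co <- generate_cohort(small_cohort_config(seed = 13, n_cases = 15,
                                            n_controls = 15, n_genes = 80,
                                            n_families = 1))
  panel <- filter_training_variants(co$panel)
  m <- prune_genes(build_gene_score_matrix(panel))
  cv <- run_crossvalidation(m, panel$individuals, method = "dkm",
                            gene_count = 10, n_repeats = 2, seed = 99)
  # the family pair shares a fold, so folds = individuals - 1
  expect_length(cv$folds, nrow(panel$individuals) - 1L)
  for (f in cv$folds) expect_length(intersect(f$held_out, f$train), 0L)
  expect_false(anyNA(cv$held_scores))

  cv2 <- run_crossvalidation(m, panel$individuals, method = "dkm",
                             gene_count = 10, n_repeats = 2, seed = 99)
  expect_identical(cv$held_scores, cv2$held_scores)
  expect_identical(cv$roc, cv2$roc)
})

test_that("asking for more genes than a fold set holds falls back to the whole set", {
  co <- generate_cohort(small_cohort_config(seed = 17, n_cases = 10,
                                            n_controls = 10, n_genes = 40))
  panel <- filter_training_variants(co$panel)
  m <- prune_genes(build_gene_score_matrix(panel))
  expect_message(
    cv <- run_crossvalidation(m, panel$individuals, method = "ks5",
                              gene_count = 300, n_repeats = 1, seed = 1),
    "entire set")
  expect_s3_class(cv, "avadx_cv")
})

test_that("permutation p-values follow the printed counting rule", {
  co <- generate_cohort(small_cohort_config(seed = 23, n_cases = 8,
                                            n_controls = 8, n_genes = 30))
  panel <- filter_training_variants(co$panel)
  m <- prune_genes(build_gene_score_matrix(panel))
  genes <- colnames(m)[1:5]
  pn <- permutation_null(m, panel$individuals, method = "fixed",
                         fixed_genes = genes, n_perm = 5,
                         observed_roc = Inf, observed_pr = Inf, seed = 2)
  expect_equal(pn$p_roc, 0)   # observed above every permuted AUC
  expect_equal(pn$p_pr, 0)
  pn2 <- permutation_null(m, panel$individuals, method = "fixed",
                          fixed_genes = genes, n_perm = 5,
                          observed_roc = -Inf, observed_pr = -Inf, seed = 2)
  expect_equal(pn2$p_roc, 1)  # observed below every permuted AUC
  expect_equal(pn2$p_pr, 1)
  expect_length(pn$null_roc, 5L)
})
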
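test_that("half-minimum imputation fills only the gaps", {
  tab <- tiny_table()
  imp <- impute_missing(tab)
  expect_equal(unname(imp$intensity["f1", ]), c(4, 2, 8, 10))
  # untouched rows identical
  expect_equal(imp$intensity["f2", ], tab$intensity["f2", ])
  # table without missing values is returned unchanged
  full <- tiny_table(matrix(1:8 + 0.5, 2, 4,
                            dimnames = list(c("a", "b"), paste0("s", 1:4))))
  expect_identical(impute_missing(full)$intensity, full$intensity)
  # all-missing feature is dropped with a warning
  m <- tiny_table()$intensity
  m["f2", ] <- NA
  expect_warning(imp2 <- impute_missing(omics_table(m, rep("A", 4))),
                 "all-missing")
  expect_false("f2" %in% rownames(imp2$intensity))
})

test_that("imputed values never exceed the observed feature minimum", {
  p <- gen_proteomics(syn_config(seed = 9))
  imp <- impute_missing(p$table)
  was_na <- is.na(p$table$intensity)
  mins <- apply(p$table$intensity, 1, min, na.rm = TRUE)
  for (f in rownames(imp$intensity)[rowSums(was_na) > 0]) {
    expect_true(all(imp$intensity[f, was_na[f, ]] <= mins[f]))
  }
})

test_that("standard-sample CV matches its definition", {
  mat <- matrix(c(90, 100, 110,
                  50, 50, 50), 2, 3, byrow = TRUE,
                dimnames = list(c("f1", "f2"), paste0("std", 1:3)))
  tab <- omics_table(mat, rep("STD", 3))
  qc <- qc_cv(tab)
  expect_equal(unname(qc$cv["f1"]), 10 / 100)  # sample sd = 10
  expect_equal(unname(qc$cv["f2"]), 0)
  expect_error(qc_cv(omics_table(mat[, 1, drop = FALSE], "STD")),
               "2 standard")
})

test_that("sample correlation QC behaves on duplicated and opposed samples", {
  set.seed(1)
  base <- 2^rnorm(50, 10, 1)
  mat <- cbind(s1 = base, s2 = base, s3 = 2^(20 - log2(base)))
  rownames(mat) <- sprintf("f%02d", 1:50)
  tab <- omics_table(mat, c("A", "A", "B"))
  cc <- qc_correlation(tab)
  expect_equal(cc["s1", "s2"], 1)
  expect_equal(cc["s1", "s3"], -1)
  expect_equal(diag(cc), c(s1 = 1, s2 = 1, s3 = 1))
})

test_that("differential calling applies the FC and p thresholds jointly", {
  # identical groups: nothing significant
  set.seed(2)
  mat <- matrix(2^rnorm(200, 12, 0.3), 20, 10,
                dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:10)))
  dup <- mat[, c(1:5, 1:5)]
  colnames(dup) <- sprintf("s%d", 1:10)
  tab <- omics_table(dup, rep(c("A", "B"), each = 5))
  d0 <- diff_proteins(tab, "A", "B")
  expect_equal(sum(d0$significant), 0)
  expect_true(all(d0$p[d0$fc == 1] == 1))

  # constructed fold change of 1.21 with infinitesimal jitter
  jit <- c(-1.5e-6, -0.5e-6, 0.5e-6, 1.5e-6)
  mat2 <- rbind(fX = c(100 + jit, 121 + jit))
  colnames(mat2) <- sprintf("s%d", 1:8)
  tab2 <- omics_table(mat2, rep(c("B", "A"), each = 4))
  d2 <- diff_proteins(tab2, "A", "B")
  expect_equal(d2$fc, 1.21, tolerance = 1e-6)
  expect_equal(d2$direction, "up")
  expect_lt(d2$p, 0.05)
  expect_true(d2$significant)

  # per-feature p agrees with the reference t-test
  p <- gen_proteomics(syn_config(seed = 1, missing_rate = 0))
  imp <- p$table
  d <- diff_proteins(imp, "CCQS", "HC")
  x <- log2(imp$intensity)
  grp <- imp$samples$group
  for (f in d$id[c(1, 50, 200)]) {
    ref <- t.test(x[f, grp == "CCQS"], x[f, grp == "HC"],
                  var.equal = TRUE)$p.value
    expect_equal(d$p[d$id == f], ref, tolerance = 1e-12)
  }
})

test_that("differential results are invariant to sample column order", {
  p <- gen_proteomics(syn_config(seed = 3, missing_rate = 0))
  tab <- p$table
  d1 <- diff_proteins(tab, "CCQS", "HC")
  set.seed(1)
  perm <- sample(ncol(tab$intensity))
  tab2 <- omics_table(tab$intensity[, perm], tab$samples$group[perm],
                      tab$samples$is_standard[perm])
  d2 <- diff_proteins(tab2, "CCQS", "HC")
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("null data yields the nominal raw-p hit rate under permutation", {
  cfg <- syn_config(seed = 13, effect_log2fc = 0, missing_rate = 0)
  p <- gen_proteomics(cfg)
  tab <- subset_samples(p$table)
  set.seed(99)
  hit <- replicate(3, {
    perm <- sample(tab$samples$group)
    t2 <- omics_table(tab$intensity, perm)
    mean(diff_proteins(t2, "CCQS", "HC")$p < 0.05)
  })
  # binomial tolerance around 0.05 with 388 features x 3 permutations
  expect_lt(abs(mean(hit) - 0.05), 0.025)
})

test_that("venn partition cardinalities are consistent", {
  # 24 and 23 differential proteins with 7 in common -> 17 and 16 specific
  a <- sprintf("p%02d", 1:24)
  b <- c(sprintf("p%02d", 1:7), sprintf("q%02d", 1:16))
  v <- venn_sets(a, b)
  expect_length(v$common, 7)
  expect_length(v$a_only, 17)
  expect_length(v$b_only, 16)
  # identity |A u B| = |A| + |B| - |common| on random sets
  set.seed(8)
  for (i in 1:20) {
    A <- sample(letters, sample(5:20, 1))
    B <- sample(letters, sample(5:20, 1))
    v <- venn_sets(A, B)
    expect_equal(length(union(A, B)),
                 length(A) + length(B) - length(v$common))
    expect_length(intersect(v$a_only, v$b_only), 0)
  }
  v2 <- venn_sets(letters, letters)
  expect_length(v2$a_only, 0)
  expect_length(v2$b_only, 0)
})

test_that("cohort chi-square statistics flag the comorbidity imbalances", {
  # diabetes 1/30, 20/44, 15/37 and cerebrovascular 2/30, 4/44, 15/37
  dia <- chisq_counts(c(1, 20, 15), c(30, 44, 37))
  expect_lt(dia$p, 0.001)
  cer <- chisq_counts(c(2, 4, 15), c(30, 44, 37))
  expect_lt(cer$p, 0.001)
  # agrees with the base chi-square test without continuity correction
  ref <- chisq.test(cbind(c(1, 20, 15), c(29, 24, 22)), correct = FALSE)
  expect_equal(dia$p, ref$p.value, tolerance = 1e-12)
  # balanced variable is not significant
  arr <- chisq_counts(c(6, 6, 6), c(30, 44, 37))
  expect_gt(arr$p, 0.5)
})

test_that("summary-statistic ANOVA equals raw-data ANOVA", {
  set.seed(21)
  g <- rep(c("a", "b", "c"), times = c(12, 15, 9))
  x <- rnorm(length(g), mean = as.numeric(factor(g)) * 0.4)
  n <- tapply(x, g, length)
  r <- anova_from_summary(n, tapply(x, g, mean), tapply(x, g, sd))
  ref <- anova(aov(x ~ g))
  expect_equal(r$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # equal means and sds: F = 0, p = 1
  r0 <- anova_from_summary(c(10, 10), c(5, 5), c(1, 1))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
})

test_that("cohort_stats reproduces the reference cohort's headline p-values", {
  cohort <- load_cohort_reference()
  res <- cohort_stats(cohort)
  p <- setNames(res$p, res$variable)
  expect_lt(p[["DiabetesMellitus"]], 0.001)
  expect_lt(p[["CerebrovascularDisease"]], 0.001)
  expect_lt(p[["Hypertension"]], 0.001)
  expect_gt(p[["BMI"]], 0.05)
  expect_gt(p[["Arrhythmia"]], 0.05)
  expect_lt(p[["Age"]], 0.05)
})
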
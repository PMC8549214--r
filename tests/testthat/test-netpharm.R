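cmp_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(compound = r[[1]], herb = r[[2]], source = r[[3]],
               OB = r[[4]], DL = r[[5]], grading = r[[6]],
               stringsAsFactors = FALSE)))
}

test_that("activity filtering applies the source-specific rules", {
  cmps <- cmp_df(
    list("c1", "h1", "tcmsp", 30.0, 0.18, NA),   # inclusive boundary: kept
    list("c2", "h1", "tcmsp", 29.9, 0.50, NA),   # OB below: dropped
    list("c3", "h1", "tcmsp", 45.0, 0.17, NA),   # DL below: dropped
    list("c4", "h1", "etcm", NA, NA, "good"),
    list("c5", "h1", "etcm", NA, NA, "moderate"),
    list("c6", "h1", "etcm", NA, NA, "weak"),
    list("c7", "h1", "qmarker", NA, NA, NA)
  )
  act <- filter_active(cmps)
  expect_setequal(act$compound, c("c1", "c4", "c5", "c7"))
  # idempotent
  expect_identical(filter_active(act), act)
  # tcmsp missing OB/DL rejected with warning
  bad <- cmp_df(list("c8", "h1", "tcmsp", NA, 0.3, NA))
  expect_warning(out <- filter_active(rbind(cmps, bad)), "missing OB/DL")
  expect_false("c8" %in% out$compound)
})

test_that("formula target aggregation unions targets and keeps counts", {
  act <- cmp_df(list("c1", "h1", "qmarker", NA, NA, NA),
                list("c2", "h1", "qmarker", NA, NA, NA),
                list("c3", "h2", "qmarker", NA, NA, NA))
  targets <- data.frame(compound = c("c1", "c1", "c2", "c2"),
                        target = c("a", "b", "b", "c"))
  ft <- formula_targets(c("h1", "h2"), act, targets)
  expect_setequal(ft$targets, c("a", "b", "c"))
  expect_equal(ft$n_active, 3)          # c3 counted among actives
  expect_equal(ft$n_active_with_targets, 2)  # but has no targets
  expect_equal(ft$n_targets, 3)
  expect_warning(formula_targets("h9", act, targets), "no active")
})

test_that("signature targets are the triple intersection", {
  expect_equal(signature_targets(c("a", "b", "c"), c("b", "c", "d"),
                                 c("c", "e")), "c")
  expect_length(signature_targets(character(0), c("a"), c("a")), 0)
  # pairwise overlaps can all be non-empty while the triple is empty
  expect_length(signature_targets(c("a", "b"), c("b", "c"), c("c", "a")), 0)
  # subset property on random sets
  set.seed(4)
  for (i in 1:10) {
    s1 <- sample(letters, 10); s2 <- sample(letters, 10)
    s3 <- sample(letters, 10)
    sig <- signature_targets(s1, s2, s3)
    expect_true(all(sig %in% s1) && all(sig %in% s2) && all(sig %in% s3))
  }
})

test_that("signature partitions reproduce the specific counts", {
  # 252 and 218 signature targets with 182 common -> 70 and 36 specific
  f1 <- sprintf("t%03d", 1:252)
  f2 <- c(sprintf("t%03d", 1:182), sprintf("u%03d", 1:36))
  sp <- specific_signatures(f1, f2)
  expect_length(sp$common, 182)
  expect_length(sp$f1_only, 70)
  expect_length(sp$f2_only, 36)
  # partition property
  expect_setequal(c(sp$common, sp$f1_only, sp$f2_only), union(f1, f2))
  sp2 <- specific_signatures(f1, f1)
  expect_length(sp2$f1_only, 0)
  expect_length(sp2$f2_only, 0)
})

test_that("Jaccard index satisfies its algebraic properties", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(letters, letters), 1)
  expect_equal(jaccard(character(0), character(0)), 0)
  set.seed(6)
  for (i in 1:20) {
    A <- sample(letters, sample(3:15, 1))
    B <- sample(letters, sample(3:15, 1))
    j <- jaccard(A, B)
    expect_equal(j, jaccard(B, A))
    expect_gte(j, 0); expect_lte(j, 1)
    if (j == 1) expect_setequal(A, B)
  }
})

test_that("disease similarity applies strict thresholds conjunctively", {
  query <- list(genes = sprintf("g%02d", 1:10),
                variants = sprintf("v%02d", 1:10))
  # candidate with JIg exactly 0.2: 3 shared of 15 union needs care; use
  # 2 shared, 10 union total on each side -> J = 2/10... construct exact:
  # |A|=10, shared=3, |B|=8 -> union 15, J=0.2
  exact <- list(genes = c(sprintf("g%02d", 1:3), sprintf("x%02d", 1:5)),
                variants = sprintf("v%02d", 1:10))
  above <- list(genes = c(sprintf("g%02d", 1:5), sprintf("x%02d", 1:5)),
                variants = c(sprintf("v%02d", 1:2), sprintf("y%02d", 1:5)))
  low_var <- list(genes = above$genes, variants = sprintf("z%02d", 1:5))
  res <- disease_similarity(query,
                            list(exact = exact, above = above,
                                 low_var = low_var))
  expect_equal(res$JIg[res$disease == "exact"], 0.2)
  expect_false(res$related[res$disease == "exact"])   # strict >
  expect_true(res$related[res$disease == "above"])
  expect_false(res$related[res$disease == "low_var"]) # JIv fails the AND
  res_or <- disease_similarity(query, list(low_var = low_var),
                               combine = "or")
  expect_true(res_or$related[1])
})

test_that("ATC categories resolve by longest prefix match", {
  expect_equal(atc_category("A10BA02"), "A10")
  expect_equal(atc_category("a10ba02"), "A10")   # case-insensitive
  expect_equal(atc_category("C07AB03"), "C")
  expect_equal(atc_category("B01AC06"), "B01")
  expect_true(is.na(atc_category("N02BE01")))
})

test_that("drug overlap counts and edges follow the constructed design", {
  partitions <- list(f1_only = c("x", "y"), f2_only = c("z"))
  drugs <- data.frame(
    drug = c("d1", "d1", "d2", "d3"),
    atc = c("A10BA02", "A10BA02", "C01AA05", "N02BE01"),
    target = c("y", "w", "q", "x"))
  res <- suppressMessages(map_drug_overlap(partitions, drugs))
  cnt <- res$counts
  expect_equal(cnt$n_shared_targets[cnt$partition == "f1_only" &
                                      cnt$category == "A10"], 1L)
  expect_equal(sum(cnt$n_shared_targets), 1L)
  expect_equal(nrow(res$edges), 1)
  expect_equal(res$edges$target, "y")
  expect_equal(res$excluded_drugs, "d3")
  # synthetic knowledge base: syndrome-specific partitions hit only their
  # designed drug categories
  kb <- gen_knowledgebase(syn_config(seed = 2))
  parts <- list(f1_only = kb$signature_cores$f1_specific,
                f2_only = kb$signature_cores$f2_specific)
  ov <- suppressMessages(map_drug_overlap(parts, kb$drugs))
  with_hits <- ov$counts[ov$counts$n_shared_targets > 0, ]
  expect_true(all(with_hits$category[with_hits$partition == "f1_only"]
                  == "A10"))
  expect_setequal(with_hits$category[with_hits$partition == "f2_only"],
                  c("A08", "B01"))
})
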
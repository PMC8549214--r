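test_that("hypergeometric ORA matches the exact tail sum", {
  universe <- sprintf("u%02d", 1:20)
  term <- universe[1:5]
  query <- c(universe[1:3], universe[10:11])  # k = 3 of n = 5
  res <- ora(query, list(tt = term), universe)
  # C(5,3)C(15,2) + C(5,4)C(15,1) + C(5,5) over C(20,5) = 1126/15504
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 3); expect_equal(res$K, 5)
  # zero overlap -> p = 1
  res0 <- ora(universe[10:12], list(tt = term), universe)
  expect_equal(res0$p, 1)
  # query = term members = universe -> no enrichment possible
  resU <- ora(universe, list(tt = universe), universe)
  expect_equal(resU$p, 1)
  expect_error(ora(c("zz"), list(tt = term), universe), "no overlap")
})

test_that("ORA equals the one-sided Fisher exact test", {
  set.seed(12)
  for (i in 1:100) {
    N <- sample(15:60, 1)
    universe <- sprintf("i%03d", seq_len(N))
    K <- sample(3:(N - 3), 1)
    n <- sample(3:(N - 3), 1)
    term <- sample(universe, K)
    query <- sample(universe, n)
    p <- ora(query, list(t = term), universe)$p
    k <- length(intersect(term, query))
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
    ref <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p, ref, tolerance = 1e-9)
  }
})

test_that("joint ORA pools queries over a combined universe", {
  genes <- sprintf("g%02d", 1:15)
  mets <- sprintf("m%02d", 1:15)
  universe <- c(genes, mets)
  # term containing only genes, query only metabolites -> k = 0, p = 1
  r0 <- joint_ora(character(0), mets[1:5],
                  list(t = genes[1:6]), universe)
  expect_equal(r0$k, 0); expect_equal(r0$p, 1)
  # reduction to plain ORA on the flattened ids
  term <- c(genes[1:3], mets[1:3])
  rj <- joint_ora(genes[1:3], mets[1:3], list(t = term), universe)
  rf <- ora(term, list(t = term), universe)
  expect_equal(rj$p, rf$p, tolerance = 1e-12)
  # constructed joint configuration N = 30, K = 6, n = 6, k = 4
  termB <- c(genes[1:3], mets[1:3])
  qry_g <- c(genes[1:2], genes[10:11])
  qry_m <- c(mets[1:2])
  rB <- joint_ora(qry_g, qry_m, list(t = termB), universe)
  expect_equal(rB$k, 4)
  ref <- phyper(3, 6, 24, 6, lower.tail = FALSE)
  expect_equal(rB$p, ref, tolerance = 1e-12)
  expect_error(joint_ora(c("shared"), c("shared"), list(t = genes)),
               "disjoint")
})

test_that("report percentages round as published tables do", {
  expect_equal(percentage(5, 24), 20.83)
  expect_equal(percentage(5, 23), 21.74)
  expect_equal(percentage(0, 7), 0)
  expect_error(percentage(1, 0), "n_input")
  expect_error(percentage(5, 4), "exceed")
})

test_that("pairwise kappa matches hand-computed 2x2 tables", {
  items <- c("i1", "i2", "i3", "i4")
  sets <- list(A = c("i1", "i2"), B = c("i1", "i2"),
               C = c("i3", "i4"), D = c("i1", "i3"))
  K <- kappa_matrix(items, sets)
  expect_equal(K["A", "B"], 1)              # identical profiles
  expect_equal(K["A", "C"], -1)             # complementary 2 vs 2
  expect_equal(K["A", "D"], 0)              # Po = Pe = 0.5
  expect_true(isSymmetric(K))
  # degenerate profiles: both terms annotate everything
  expect_warning(
    Kd <- kappa_matrix(items, list(all1 = items, all2 = items)),
    "degenerate")
  expect_equal(Kd["all1", "all2"], 0)
  expect_error(kappa_matrix(items, list(one = "i1")), "at least 2")
})

test_that("term clustering merges kappa blocks and scores clusters", {
  # geometric-mean scoring: p-values 1e-4 and 1e-2 -> score 3
  enr <- data.frame(term = c("t1", "t2"), p = c(1e-4, 1e-2))
  K <- matrix(1, 2, 2, dimnames = list(c("t1", "t2"), c("t1", "t2")))
  cl <- cluster_terms(enr, K, stringency = list(kappa_min = 0.85,
                                                min_partners = 1,
                                                linkage = 0.5))
  expect_equal(cl$enrichment_score[1], 3)
  expect_equal(cl$n_terms[1], 2)
  # all pairwise kappa = 1 over 5 terms -> a single cluster at "high"
  terms5 <- paste0("t", 1:5)
  enr5 <- data.frame(term = terms5, p = rep(1e-3, 5))
  K5 <- matrix(1, 5, 5, dimnames = list(terms5, terms5))
  cl5 <- cluster_terms(enr5, K5, "high")
  expect_equal(nrow(cl5), 1)
  expect_equal(cl5$n_terms, 5)
  # two kappa blocks (within 1, between 0) -> exactly two clusters
  terms8 <- paste0("t", 1:8)
  K8 <- matrix(0, 8, 8, dimnames = list(terms8, terms8))
  K8[1:4, 1:4] <- 1; K8[5:8, 5:8] <- 1
  enr8 <- data.frame(term = terms8, p = c(rep(1e-5, 4), rep(1e-2, 4)))
  cl8 <- cluster_terms(enr8, K8, "high")
  expect_equal(nrow(cl8), 2)
  expect_equal(cl8$enrichment_score, c(5, 2))   # ranked by score
  expect_equal(cl8$rank, 1:2)
  # singleton cluster score equals -log10 of its own p
  enr1 <- data.frame(term = c("t1", "t2"), p = c(1e-6, 0.5))
  K1 <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("t1", "t2"),
                                                 c("t1", "t2")))
  cl1 <- cluster_terms(enr1, K1, "high")
  expect_equal(nrow(cl1), 2)
  expect_equal(cl1$enrichment_score[1], 6)
})

test_that("BH q-values are monotone in the p-value ranking", {
  set.seed(3)
  universe <- sprintf("u%03d", 1:200)
  sets <- lapply(1:15, function(i) sample(universe, 25))
  names(sets) <- paste0("s", 1:15)
  res <- ora(sample(universe, 30), sets, universe)
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  # row order is deterministic: p ascending then term
  ord <- res[order(res$p, res$term), ]
  rownames(ord) <- NULL
  expect_identical(res, ord)
})

test_that("ORA output is invariant to query and set ordering", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:100)
  sets <- lapply(1:8, function(i) sample(universe, 20))
  names(sets) <- paste0("s", 1:8)
  query <- sample(universe, 25)
  r1 <- ora(query, sets, universe)
  r2 <- ora(rev(query), sets[sample(names(sets))], universe)
  expect_equal(r1, r2)
})

test_that("cross-view consistency flags shared and specific pathways", {
  hits <- list(
    CCQS = list(proteomics = c("pwA", "pwB"), metabolomics = c("pwA"),
                integrated = c("pwA", "pwC")),
    QSBS = list(proteomics = c("pwB"), metabolomics = character(0),
                integrated = c("pwB")))
  tab <- cross_view_consistency(hits)
  rowA <- tab[tab$term == "pwA" & tab$syndrome == "CCQS", ]
  expect_equal(rowA$n_views, 3)
  expect_equal(rowA$syndrome_flag, "CCQS-specific")
  expect_true(all(tab$syndrome_flag[tab$term == "pwB"] == "both"))
  rowC <- tab[tab$term == "pwC", ]
  expect_true(rowC$integrated && !rowC$proteomics)
})
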
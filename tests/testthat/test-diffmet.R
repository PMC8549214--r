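test_that("PLS-DA separates constructed clouds and rejects degenerate input", {
  tc <- two_clouds(n = 15, shift = 4)
  m <- fit_plsda(tc$X, tc$y, n_comp = 2)
  t1 <- m$T[, 1]
  expect_true(max(t1[tc$y == "ctrl"]) < min(t1[tc$y == "case"]) ||
              max(t1[tc$y == "case"]) < min(t1[tc$y == "ctrl"]))
  # successive scores orthogonal
  expect_lt(abs(sum(m$T[, 1] * m$T[, 2])), 1e-8)
  expect_error(fit_plsda(tc$X, rep("case", nrow(tc$X))), "two classes")
})

test_that("single-feature PLS scores are the centered/scaled feature", {
  set.seed(3)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "m1"))
  y <- rep(c(0, 1), 15)
  m <- fit_plsda(x, y, n_comp = 1)
  z <- (x[, 1] - mean(x)) / sd(x[, 1])
  # w is +-1, so scores equal the scaled feature up to sign
  expect_equal(abs(cor(m$T[, 1], z)), 1, tolerance = 1e-12)
  expect_equal(sort(abs(m$T[, 1])), sort(abs(z)), tolerance = 1e-12)
})

test_that("OPLS with no orthogonal component reduces to PLS component 1", {
  tc <- two_clouds(n = 20, p = 8, shift = 1.5, seed = 5)
  o <- fit_oplsda(tc$X, tc$y, n_ortho = 0)
  p1 <- fit_plsda(tc$X, tc$y, n_comp = 1)
  expect_equal(o$t, p1$T[, 1], tolerance = 1e-10)
  expect_equal(unname(o$w), unname(p1$W[, 1]), tolerance = 1e-10)
})

test_that("orthogonal components are uncorrelated with the class vector", {
  set.seed(11)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  # class signal on features 1-3, strong y-orthogonal structure elsewhere
  ortho <- rnorm(n, sd = 3) * (1 - 2 * (seq_len(n) %% 2))
  X <- cbind(sapply(1:3, function(i) y + rnorm(n, sd = 0.3)),
             sapply(1:5, function(i) ortho * runif(1, 0.5, 1) +
                      rnorm(n, sd = 0.3)))
  colnames(X) <- paste0("m", 1:8)
  m <- fit_oplsda(X, y, n_ortho = 1)
  yc <- y - mean(y)
  expect_lt(abs(cor(m$T_ortho[, 1], yc)), 1e-8)
  # stripping the structured orthogonal variation improves the predictive
  # fit over plain 1-component PLS on the undeflated matrix
  p1 <- fit_plsda(X, y, n_comp = 1)
  r2_pls <- 1 - sum((yc - p1$T[, 1] * p1$q[1])^2) / sum(yc^2)
  expect_gt(m$R2Y, r2_pls)
})

test_that("VIP is mean-square normalized and ranks informative features", {
  # single feature: normalization forces VIP = 1
  set.seed(7)
  x1 <- matrix(rnorm(24), ncol = 1, dimnames = list(NULL, "only"))
  m1 <- fit_oplsda(x1, rep(c("a", "b"), 12), n_ortho = 0)
  expect_equal(unname(m1$vip), 1, tolerance = 1e-10)
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(inf = y * 1.5 + rnorm(n, sd = 0.5), noise = rnorm(n))
    m <- fit_oplsda(X, y, n_ortho = 0)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-6)
    expect_gt(m$vip[["inf"]], 1)
    expect_lt(m$vip[["noise"]], 1)
  }
})

test_that("Q2 is high for a perfect predictor and seed-stable", {
  set.seed(17)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(dup = y, pad = rnorm(n))
  q <- suppressWarnings(cross_validate_q2(X, y, folds = 10, seed = 1))
  expect_gt(q$Q2, 0.95)
  q2 <- suppressWarnings(cross_validate_q2(X, y, folds = 10, seed = 1))
  expect_identical(q$Q2, q2$Q2)
  expect_error(cross_validate_q2(X[1:3, ], y[1:3]), "at least 4")
})

test_that("Q2 on permuted labels is negative in expectation", {
  tc <- two_clouds(n = 25, p = 10, shift = 2, seed = 23)
  q_signal <- cross_validate_q2(tc$X, tc$y, seed = 1)$Q2
  set.seed(31)
  q_perm <- replicate(20,
    cross_validate_q2(tc$X, sample(tc$y), seed = 1)$Q2)
  expect_lte(mean(q_perm), 0)
  expect_gt(q_signal, max(0.2, mean(q_perm)))
})

test_that("Mann-Whitney p-values and BH q-values match hand-derived cases", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(1, 1, 2, 1, 1, 2))
  g <- rep(c("g1", "g2"), each = 3)
  r <- univariate_mwu_fdr(X, g)
  # complete separation of n=3 vs 3: exact two-sided p = 2/20
  expect_equal(r$p[r$id == "a"], 0.1, tolerance = 1e-12)
  # identical value multisets: p = 1
  expect_equal(r$p[r$id == "b"], 1)
  # BH step-up on (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("DM calls obey the mode-specific rules and strict boundaries", {
  vips <- c(m1 = 1.0, m2 = 1.5, m3 = 2.0, m4 = 0.4)
  uni <- data.frame(id = c("m1", "m2", "m3", "m4"),
                    p = c(0.001, 0.2, 0.01, 0.001),
                    q = c(0.004, 0.3, 0.04, 0.004))
  cats <- c(m1 = "amino_acid", m2 = "fatty_acyl", m3 = "amino_acid",
            m4 = "other")
  un <- call_dms(vips, uni, "untargeted", cats)
  # VIP exactly 1 is not significant; q-rule applies
  expect_equal(un$results$significant[match(c("m1", "m2", "m3", "m4"),
                                            un$results$id)],
               c(FALSE, FALSE, TRUE, FALSE))
  tg <- call_dms(vips, uni, "targeted", cats)
  expect_equal(sum(tg$results$significant), 1)
  expect_equal(un$category_proportions[["amino_acid"]], 1)
  expect_error(call_dms(vips, uni[1:3, ], "targeted"), "same metabolites")
})

test_that("syndrome DM set algebra gives the specific counts", {
  # 200 and 225 differential metabolites sharing 110
  a <- sprintf("m%03d", 1:200)
  b <- c(sprintf("m%03d", 1:110), sprintf("x%03d", 1:115))
  v <- venn_sets(a, b)
  expect_length(v$common, 110)
  expect_length(v$a_only, 90)
  expect_length(v$b_only, 115)
})

test_that("fits are invariant to feature and sample order", {
  tc <- two_clouds(n = 12, p = 6, seed = 41)
  m <- fit_oplsda(tc$X, tc$y)
  set.seed(1)
  fp <- sample(ncol(tc$X)); sp <- sample(nrow(tc$X))
  m2 <- fit_oplsda(tc$X[sp, fp], tc$y[sp])
  expect_equal(m$vip[colnames(tc$X)], m2$vip[colnames(tc$X)],
               tolerance = 1e-8)
  expect_equal(abs(m$t[sp]), abs(m2$t), tolerance = 1e-8)
})

test_that("the predictive scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  tc <- two_clouds(n = 18, p = 10, shift = 1, seed = 55)
  p1 <- fit_plsda(tc$X, tc$y, n_comp = 1)
  ref <- mixOmics::plsda(tc$X, factor(tc$y), ncomp = 1)
  # same subspace up to sign/scale
  expect_gt(abs(cor(p1$T[, 1], ref$variates$X[, 1])), 0.999)
})
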
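#' Impute missing intensities
#'
#' Fills missing entries of an omics table. The default `"halfmin"` policy
#' replaces each feature's missing values with half of that feature's
#' minimum observed intensity, a conservative convention for
#' intensity-dependent dropout in data-independent-acquisition proteomics.
#' Non-missing entries are never changed. Features with no observed value
#' cannot be imputed and are dropped with a warning.
#'
#' @param table an [omics_table].
#' @param policy `"halfmin"` (feature-wise half-minimum) or `"min"`
#'   (feature-wise minimum).
#' @return An [omics_table] with no missing entries.
#' @export
impute_missing <- function(table, policy = c("halfmin", "min")) {
  stopifnot(inherits(table, "omics_table"))
  policy <- match.arg(policy)
  x <- table$intensity
  all_na <- rowSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning(sprintf("dropping %d all-missing feature(s): %s",
                    sum(all_na),
                    paste(head(rownames(x)[all_na], 5), collapse = ", ")))
    x <- x[!all_na, , drop = FALSE]
  }
  if (anyNA(x)) {
    fill <- apply(x, 1L, min, na.rm = TRUE)
    if (policy == "halfmin") fill <- fill / 2
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- fill[idx[, 1L]]
  }
  omics_table(x, table$samples$group, table$samples$is_standard,
              table$feature_meta)
}

#' Coefficient of variation of features across standard samples
#'
#' Computes, per feature, CV = sd/mean over the raw intensities of the
#' standard-sample replicates, the usual QC summary for pooled standards
#' injected throughout an acquisition batch. Features with zero mean are
#' excluded with a warning.
#'
#' @param table an [omics_table] containing standard samples.
#' @param threshold CV threshold for the reported pass fraction
#'   (default 0.10).
#' @return List with `cv` (named numeric vector) and `fraction_below`
#'   (share of features with CV < `threshold`, computed on features with at
#'   least 2 observed standard values).
#' @export
qc_cv <- function(table, threshold = 0.10) {
  stopifnot(inherits(table, "omics_table"))
  std <- table$intensity[, table$samples$is_standard, drop = FALSE]
  if (ncol(std) < 2) stop("at least 2 standard samples are required")
  n_obs <- rowSums(!is.na(std))
  m <- rowMeans(std, na.rm = TRUE)
  s <- apply(std, 1L, sd, na.rm = TRUE)
  ok <- n_obs >= 2 & !is.na(m)
  zero <- ok & m == 0
  if (any(zero)) {
    warning(sprintf("%d feature(s) with zero mean excluded from CV",
                    sum(zero)))
    ok <- ok & !zero
  }
  cv <- s[ok] / m[ok]
  list(cv = cv, fraction_below = mean(cv < threshold),
       threshold = threshold)
}

#' Pairwise sample correlation on log2 intensities
#'
#' @param table an imputed [omics_table].
#' @param drop_standards exclude standard samples (default `TRUE`).
#' @return Symmetric matrix of Pearson correlations; samples with constant
#'   intensity vectors yield `NA` entries.
#' @export
qc_correlation <- function(table, drop_standards = TRUE) {
  stopifnot(inherits(table, "omics_table"))
  t2 <- if (drop_standards) subset_samples(table) else table
  if (anyNA(t2$intensity)) stop("impute the table before correlation QC")
  suppressWarnings(cor(log2(t2$intensity), method = "pearson"))
}

#' Call differential proteins between two groups
#'
#' Two-sample Student t-test (equal variances by default, Welch optional)
#' on log2 intensities, combined with a raw-scale fold-change filter. The
#' fold change is the ratio of raw group means folded to be >= 1, with the
#' direction recorded relative to `group_a` (the disease group) versus
#' `group_b` (the control). A feature is significant when `FC > fc_thresh`
#' and `p < p_thresh` (strict inequalities). Benjamini-Hochberg q-values
#' are reported informatively but play no part in the significance call.
#'
#' @param table an imputed [omics_table].
#' @param group_a,group_b group labels (case and control).
#' @param fc_thresh fold-change threshold (default 1.1).
#' @param p_thresh p-value threshold (default 0.05).
#' @param var_equal pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @param fc_scale compute the fold change on `"raw"` group means (default)
#'   or on `"log"` means (geometric).
#' @return data.frame ordered by (p ascending, id ascending) with columns
#'   `id`, `mean_a`, `mean_b`, `fc`, `direction` (`"up"`/`"down"`), `p`,
#'   `q`, `significant`.
#' @export
diff_proteins <- function(table, group_a, group_b, fc_thresh = 1.1,
                          p_thresh = 0.05, var_equal = TRUE,
                          fc_scale = c("raw", "log")) {
  stopifnot(inherits(table, "omics_table"))
  fc_scale <- match.arg(fc_scale)
  if (anyNA(table$intensity)) stop("impute the table before testing")
  grp <- table$samples$group
  ia <- which(grp == group_a & !table$samples$is_standard)
  ib <- which(grp == group_b & !table$samples$is_standard)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples")
  x <- log2(table$intensity)
  xa <- x[, ia, drop = FALSE]
  xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, var); vb <- apply(xb, 1L, var)
  na <- length(ia); nb <- length(ib)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: identical constants give p = 1
  degen <- se == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  mean_a <- rowMeans(table$intensity[, ia, drop = FALSE])
  mean_b <- rowMeans(table$intensity[, ib, drop = FALSE])
  ratio <- if (fc_scale == "raw") mean_a / mean_b else 2^(ma - mb)
  fc <- pmax(ratio, 1 / ratio)
  res <- data.frame(
    id = rownames(x),
    mean_a = mean_a, mean_b = mean_b,
    fc = fc,
    direction = ifelse(ratio >= 1, "up", "down"),
    p = p,
    q = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  res$significant <- res$fc > fc_thresh & res$p < p_thresh
  res <- res[order(res$p, res$id), ]
  rownames(res) <- NULL
  res
}

#' Two-set Venn partition
#'
#' Splits two identifier sets into their intersection and the two specific
#' remainders, the set algebra behind every two-way Venn diagram in the
#' pipeline (differential proteins, metabolites, signature targets).
#'
#' @param set_a,set_b character vectors (duplicates removed).
#' @return List with `common`, `a_only`, `b_only` (disjoint; their union is
#'   `set_a` union `set_b`).
#' @export
venn_sets <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  list(common = intersect(a, b),
       a_only = setdiff(a, b),
       b_only = setdiff(b, a))
}

#' One-way ANOVA from group summary statistics
#'
#' F-test of equal group means computed from (n, mean, sd) triples via the
#' between/within sum-of-squares decomposition; equivalent to `aov()` on
#' the raw data whenever the summaries come from those data.
#'
#' @param n,means,sds numeric vectors, one entry per group.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, means, sds) {
  stopifnot(length(n) == length(means), length(n) == length(sds))
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("sds must be non-negative")
  k <- length(n)
  N <- sum(n)
  gm <- sum(n * means) / N
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0 && ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Chi-square homogeneity test on event counts
#'
#' Pearson chi-square test (no continuity correction) on the groups x
#' (event, non-event) contingency table, the standard test for categorical
#' cohort variables such as comorbidity prevalence.
#'
#' @param events,n integer vectors: event counts and group sizes.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_counts <- function(events, n) {
  stopifnot(length(events) == length(n), all(events <= n), all(events >= 0))
  tab <- cbind(event = events, nonevent = n - events)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Per-variable cohort statistics
#'
#' Applies [anova_from_summary()] to continuous variables (supplied as
#' per-group n/mean/sd) and [chisq_counts()] to categorical variables
#' (supplied as per-group event counts), reproducing the p-value column of
#' a clinical baseline table.
#'
#' @param cohort data.frame with columns `variable`, `type`
#'   (`"continuous"`/`"categorical"`), `group`, `n`, and either
#'   `mean` + `sd` or `events`.
#' @return data.frame with columns `variable`, `type`, `statistic`, `p`.
#' @export
cohort_stats <- function(cohort) {
  cohort <- as.data.frame(cohort)
  need <- c("variable", "type", "group", "n")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(cohort, cohort$variable), function(d) {
    type <- d$type[1L]
    if (type == "continuous") {
      r <- anova_from_summary(d$n, d$mean, d$sd)
      data.frame(variable = d$variable[1L], type = type,
                 statistic = r$F, p = r$p)
    } else {
      r <- chisq_counts(d$events, d$n)
      data.frame(variable = d$variable[1L], type = type,
                 statistic = r$statistic, p = r$p)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
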
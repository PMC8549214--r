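# Small in-code fixtures shared across test files.

# a tiny omics table with known values; groups A/B plus standards
tiny_table <- function(mat = NULL) {
  if (is.null(mat)) {
    mat <- matrix(c(4, NA, 8, 10,
                    5, 6, 7, 8,
                    90, 100, 110, 100), nrow = 3, byrow = TRUE,
                  dimnames = list(c("f1", "f2", "f3"),
                                  c("s1", "s2", "s3", "s4")))
  }
  omics_table(mat, c("A", "A", "B", "B"))
}

# two well-separated gaussian clouds for discriminant models
two_clouds <- function(n = 20, p = 5, shift = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[seq_len(n), 1] <- X[seq_len(n), 1] + shift
  colnames(X) <- paste0("m", seq_len(p))
  list(X = X, y = rep(c("case", "ctrl"), each = n))
}

# random small molecular network
random_network <- function(n, p_edge = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  # guarantee at least one edge
  if (!any(keep)) keep[1] <- TRUE
  molecular_network(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
               weight = runif(sum(keep), 0.2, 1)),
    data.frame(id = ids, kind = "gene")
  )
}
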
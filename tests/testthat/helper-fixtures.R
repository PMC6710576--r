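# Small fixture graphs built in code, used across tests.

path_network <- function(n) {
  social_network(cbind(seq_len(n - 1), seq_len(n - 1) + 1L), n)
}

cycle_network <- function(n) {
  social_network(rbind(cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
                       c(n, 1L)), n)
}

# 10-node hub-dominated graph: node 1 is a hub tied to 2..7, a secondary hub 8
# tied to the hub and to the peripheral nodes 9 and 10
skewed_fixture <- function() {
  social_network(rbind(
    c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6), c(1, 7),
    c(1, 8), c(8, 9), c(8, 10), c(2, 3)), 10)
}

# independent bias-corrected skewness, written from the defining moments
direct_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

# independent OLS via normal equations with t-distribution p-values
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(beta = as.vector(beta), se = as.vector(se), p = as.vector(p))
}

# small synthetic results table covering all six strata, with a prescribed
# auc-generating function of (structure, T, L, E)
synthetic_results <- function(auc_fun, L_values = c(0.2, 0.5, 0.8),
                              E_values = c(0.1, 0.2, 0.3), replicates = 4) {
  g <- expand.grid(replicate = seq_len(replicates), E = E_values,
                   L = L_values, T = c(1L, 2L),
                   structure = c("light", "moderate", "high"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("structure", "T", "L", "E", "replicate")]
  g$network_seed <- seq_len(nrow(g))
  g$auc <- mapply(auc_fun, g$structure, g$T, g$L, g$E)
  g$final_count <- pmin(40L, as.integer(round(g$auc / 50)))
  class(g) <- c("results_table", "data.frame")
  g
}
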
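#' Exact expected informed counts by state-space enumeration
#'
#' Propagates the full probability distribution over knowledge states
#' (subsets of informed nodes) under the synchronous listening rule, giving
#' the exact expected informed count at the end of every step. Because
#' knowledge is absorbing the reachable states are supersets of the seed
#' set, but the state space is still `2^n`, so the computation refuses
#' networks with more than 12 nodes. Intended as an independent verification
#' oracle for the stochastic simulator on small fixture graphs.
#'
#' @param net a [social_network] with at most 12 nodes.
#' @param params a [diffusion_params] (its `E` is ignored; seeding is given
#'   explicitly).
#' @param seeds integer vector of seeded node indices (1-based), or a logical
#'   vector of length `n`.
#' @return numeric vector of length `n_steps`: exact expected informed count
#'   at the end of each step.
#' @examples
#' path3 <- social_network(rbind(c(1, 2), c(2, 3)), 3)
#' exact_expected_counts(path3, diffusion_params(T = 1, L = 0.5, E = 0,
#'                                               n_steps = 2), seeds = 1)
#' @export
exact_expected_counts <- function(net, params, seeds) {
  stopifnot(is_social_network(net), inherits(params, "diffusion_params"))
  n <- node_count(net)
  if (n > 12L)
    stop("exact enumeration is limited to networks of at most 12 nodes ",
         "(state space 2^n); this network has ", n)
  seeds <- as_seed_indices(seeds, n)
  Tthr <- params$T; L <- params$L
  per_edge <- identical(params$listening_model, "per_edge")

  bit <- as.integer(2^(seq_len(n) - 1L))
  n_states <- as.integer(2^n)
  states <- 0:(n_states - 1L)
  # per-state popcount, built one bit-plane at a time
  popcount <- integer(n_states)
  for (b in bit) popcount <- popcount + as.integer(bitwAnd(states, b) > 0L)
  # neighbour bitmask per node
  A <- adjacency_matrix(net)
  nb_mask <- vapply(seq_len(n), function(i) sum(bit[A[i, ] > 0]), numeric(1))

  p <- numeric(n_states)
  s0 <- if (length(seeds) > 0) sum(bit[seeds]) else 0L
  p[s0 + 1L] <- 1
  expected <- numeric(params$n_steps)

  for (step in seq_len(params$n_steps)) {
    newp <- numeric(n_states)
    for (s in which(p > 0) - 1L) {
      ps <- p[s + 1L]
      uninformed <- which(bitwAnd(s, bit) == 0L)
      if (length(uninformed) == 0L) {
        newp[s + 1L] <- newp[s + 1L] + ps
        next
      }
      n_inf <- vapply(uninformed, function(i)
        popcount[bitwAnd(nb_mask[i], s) + 1L], numeric(1))
      elig <- uninformed[n_inf >= Tthr]
      if (length(elig) == 0L || L == 0) {
        newp[s + 1L] <- newp[s + 1L] + ps
        next
      }
      q <- if (per_edge) 1 - (1 - L)^n_inf[n_inf >= Tthr]
           else rep(L, length(elig))
      # distribute ps over all 2^k subsets of the eligible set
      k <- length(elig)
      for (sub in 0:(2^k - 1L)) {
        on <- bitwAnd(sub, 2^(seq_len(k) - 1L)) > 0L
        pr <- prod(ifelse(on, q, 1 - q))
        if (pr == 0) next
        ns <- s + sum(bit[elig[on]])
        newp[ns + 1L] <- newp[ns + 1L] + ps * pr
      }
    }
    p <- newp
    expected[step] <- sum(p * popcount)
  }
  expected
}

#' Monte-Carlo expected informed counts
#'
#' Simulates many independent replicates of the diffusion simultaneously
#' (one matrix column per replicate) on a fixed network and seed set, and
#' returns the per-step mean informed count with its standard error. This is
#' the stochastic side of the dual-route validation against
#' [exact_expected_counts()].
#'
#' @inheritParams exact_expected_counts
#' @param n_rep number of replicates.
#' @return list with numeric vectors `mean` and `se`, each of length
#'   `n_steps`, plus `n_rep`.
#' @export
mc_expected_counts <- function(net, params, seeds, n_rep = 10000L) {
  stopifnot(is_social_network(net), inherits(params, "diffusion_params"))
  n <- node_count(net)
  seeds <- as_seed_indices(seeds, n)
  A <- adjacency_matrix(net)
  per_edge <- identical(params$listening_model, "per_edge")
  Tthr <- params$T; L <- params$L

  S <- matrix(FALSE, nrow = n, ncol = n_rep)
  if (length(seeds) > 0) S[seeds, ] <- TRUE
  mean_counts <- numeric(params$n_steps)
  se_counts <- numeric(params$n_steps)
  for (step in seq_len(params$n_steps)) {
    if (L > 0 && !all(S)) {
      Ninf <- A %*% S
      elig <- which(!S & Ninf >= Tthr)
      if (length(elig) > 0) {
        pr <- if (per_edge) 1 - (1 - L)^Ninf[elig] else L
        S[elig] <- stats::runif(length(elig)) < pr
      }
    }
    counts <- colSums(S)
    mean_counts[step] <- mean(counts)
    se_counts[step] <- stats::sd(counts) / sqrt(n_rep)
  }
  list(mean = mean_counts, se = se_counts, n_rep = n_rep)
}

as_seed_indices <- function(seeds, n) {
  if (is.logical(seeds)) {
    stopifnot(length(seeds) == n)
    return(which(seeds))
  }
  seeds <- as.integer(seeds)
  if (length(seeds) > 0 && (any(seeds < 1L) || any(seeds > n)))
    stop("seed indices must lie in [1, n]")
  unique(seeds)
}
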
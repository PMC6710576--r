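#' Parameters of the knowledge-diffusion process
#'
#' Bundles the contagion rule's parameters: the listening threshold `T`
#' (minimum number of informed direct contacts an uninformed individual needs
#' before they can take the information up — complex contagion when `T > 1`),
#' the per-time-step listening probability `L`, the patrol effort `E` (the
#' proportion of the community seeded with first-hand knowledge), and the
#' number of discrete time-steps.
#'
#' @param T positive integer listening threshold.
#' @param L listening probability in `[0, 1]`.
#' @param E patrol effort in `[0, 1]`.
#' @param n_steps number of time-steps (default 50).
#' @param listening_model `"per_node"` (default): an eligible individual
#'   listens once per step with probability `L`, the threshold carrying the
#'   repeated-transmission requirement. `"per_edge"`: each informed contact is
#'   an independent chance, so an eligible individual with `k` informed
#'   contacts is informed with probability `1 - (1 - L)^k`. Provided for
#'   sensitivity analysis.
#' @return an object of class `diffusion_params`.
#' @export
diffusion_params <- function(T = 1L, L, E, n_steps = 50L,
                             listening_model = c("per_node", "per_edge")) {
  T <- as.integer(T); n_steps <- as.integer(n_steps)
  if (is.na(T) || T < 1L) stop("'T' must be a positive integer")
  if (is.na(n_steps) || n_steps < 1L) stop("'n_steps' must be >= 1")
  if (!is.numeric(L) || L < 0 || L > 1) stop("'L' must lie in [0, 1]")
  if (!is.numeric(E) || E < 0 || E > 1) stop("'E' must lie in [0, 1]")
  structure(list(T = T, L = as.numeric(L), E = as.numeric(E),
                 n_steps = n_steps,
                 listening_model = match.arg(listening_model)),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("<diffusion_params> T = %d, L = %.3g, E = %.3g, %d steps (%s)\n",
              x$T, x$L, x$E, x$n_steps, x$listening_model))
  invisible(x)
}

#' Seed patrol knowledge into a community
#'
#' `round(E * n)` individuals (rounding half away from zero) receive
#' first-hand knowledge of patrols. Under the default `least_connected`
#' strategy the lowest-degree individuals are chosen — hunting is
#' concentrated in marginal, poorly connected community members — while
#' `best_connected` seeds the hubs instead. Degree ties are broken uniformly
#' at random.
#'
#' @param net a [social_network].
#' @param E patrol effort in `[0, 1]`; the seeded proportion.
#' @param strategy `"least_connected"` (default) or `"best_connected"`.
#' @return logical vector of length `n`: the informed status of each node.
#' @examples
#' set.seed(1)
#' sum(seed_knowledge(generate_network(40, "light", seed = 1), E = 0.25))
#' @export
seed_knowledge <- function(net, E,
                           strategy = c("least_connected", "best_connected")) {
  stopifnot(is_social_network(net))
  strategy <- match.arg(strategy)
  if (!is.numeric(E) || E < 0 || E > 1) stop("'E' must lie in [0, 1]")
  n <- node_count(net)
  k <- as.integer(floor(E * n + 0.5))  # round half away from zero
  informed <- logical(n)
  if (k == 0L) return(informed)
  deg <- degree_sequence(net)
  tie_break <- sample.int(n)
  ord <- if (strategy == "least_connected") order(deg, tie_break)
         else order(-deg, tie_break)
  informed[ord[seq_len(k)]] <- TRUE
  informed
}

#' One synchronous diffusion step
#'
#' Every node that is uninformed at the start of the step and has at least
#' `T` informed direct contacts (counted at the start of the step) becomes
#' informed with probability `L`, independently. Knowledge is absorbing:
#' informed nodes never revert.
#'
#' @param informed logical vector: per-node informed status at step start.
#' @param net a [social_network].
#' @param T listening threshold.
#' @param L listening probability.
#' @param listening_model see [diffusion_params()].
#' @return updated logical informed vector.
#' @export
diffusion_step <- function(informed, net, T, L,
                           listening_model = c("per_node", "per_edge")) {
  stopifnot(is_social_network(net))
  listening_model <- match.arg(listening_model)
  stopifnot(length(informed) == node_count(net))
  step_informed(informed, adjacency_matrix(net), as.integer(T), L,
                listening_model)
}

# hot path: adjacency matrix already extracted
step_informed <- function(informed, A, T, L, listening_model = "per_node") {
  if (L <= 0 || all(informed) || !any(informed)) return(informed)
  n_inf <- as.vector(A %*% informed)
  elig <- !informed & n_inf >= T
  if (!any(elig)) return(informed)
  p <- if (listening_model == "per_edge") 1 - (1 - L)^n_inf[elig] else L
  informed[elig] <- stats::runif(sum(elig)) < p
  informed
}

#' Simulate knowledge diffusion through a community
#'
#' Seeds knowledge with [seed_knowledge()] and applies the synchronous
#' listening rule for `n_steps` steps, recording the informed count at the
#' end of each step. The seeded state itself is not recorded as a curve
#' point, so the area under the curve is the sum of the `n_steps` end-of-step
#' counts and is bounded by `n_steps * n` (2000 for the default 50 steps and
#' 40 individuals).
#'
#' @param net a [social_network].
#' @param params a [diffusion_params].
#' @param strategy seeding strategy, see [seed_knowledge()].
#' @param informed optional logical vector overriding the seeding (used by
#'   the verification oracle and for custom scenarios).
#' @return an object of class `trajectory`: list with `counts` (integer
#'   vector of length `n_steps`), `auc`, `node_count`, `n_steps`, `params`.
#' @examples
#' net <- generate_network(40, "moderate", seed = 2)
#' run_diffusion(net, diffusion_params(T = 2, L = 0.4, E = 0.25))
#' @export
run_diffusion <- function(net, params,
                          strategy = c("least_connected", "best_connected"),
                          informed = NULL) {
  stopifnot(is_social_network(net), inherits(params, "diffusion_params"))
  strategy <- match.arg(strategy)
  n <- node_count(net)
  if (n < 1L) stop("network must be non-empty")
  if (is.null(informed)) {
    informed <- seed_knowledge(net, params$E, strategy)
  } else {
    stopifnot(is.logical(informed), length(informed) == n)
  }
  A <- adjacency_matrix(net)
  counts <- integer(params$n_steps)
  for (s in seq_len(params$n_steps)) {
    informed <- step_informed(informed, A, params$T, params$L,
                              params$listening_model)
    counts[s] <- sum(informed)
    if (counts[s] == n) {  # saturated: remaining steps are constant
      if (s < params$n_steps) counts[(s + 1L):params$n_steps] <- n
      break
    }
  }
  new_trajectory(counts, n, params)
}

new_trajectory <- function(counts, n, params) {
  counts <- as.integer(counts)
  structure(list(counts = counts,
                 auc = sum(counts),
                 node_count = as.integer(n),
                 n_steps = length(counts),
                 params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d steps over %d individuals: %d -> %d informed, AUC = %d\n",
    x$n_steps, x$node_count, x$counts[1], x$counts[x$n_steps], x$auc))
  invisible(x)
}

#' Area under the cumulative informed-count curve
#'
#' The rate-of-information-flow statistic: the discrete (rectangle-rule) sum
#' of the end-of-step informed counts, bounded above by
#' `n_steps * node_count`.
#'
#' @param trajectory a `trajectory` from [run_diffusion()], or a bare integer
#'   vector of per-step counts.
#' @return integer AUC.
#' @export
compute_auc <- function(trajectory) {
  counts <- if (inherits(trajectory, "trajectory")) trajectory$counts
            else as.integer(trajectory)
  sum(counts)
}
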
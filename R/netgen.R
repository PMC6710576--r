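#' Degree-skew presets for community structure
#'
#' Communities differ principally in how their direct social contacts
#' (degrees) are distributed: from nearly even (`light`) towards the
#' star-graph extreme in which a handful of individuals hold most contacts
#' (`high`). Degrees are drawn from a discretised lognormal with a fixed mean
#' degree; the preset sets the lognormal sigma, so higher sigma gives a
#' heavier right tail and a more hub-dominated community. The presets are
#' configuration values: both the mean degree and sigma can be overridden.
#'
#' @return named list of presets, each with `mean_degree` and `sigma`.
#' @export
skew_presets <- function() {
  list(
    light    = list(mean_degree = 4, sigma = 0.2),
    moderate = list(mean_degree = 4, sigma = 0.6),
    high     = list(mean_degree = 4, sigma = 1.2)
  )
}

#' Draw a degree sequence for a skewed community
#'
#' Degrees are drawn i.i.d. from a lognormal with mean `mean_degree` and
#' log-scale standard deviation `sigma`, rounded to integers and truncated to
#' `[1, n - 1]`. An odd-sum sequence is repaired by incrementing the smallest
#' degree (decrementing the largest if the smallest is already `n - 1`), the
#' minimal perturbation that restores the handshake parity.
#'
#' @param n number of individuals (`n >= 2`).
#' @param preset skew preset name (see [skew_presets()]); ignored when both
#'   `mean_degree` and `sigma` are supplied.
#' @param mean_degree,sigma lognormal parameters overriding the preset.
#' @return integer vector of `n` degrees, each in `[1, n - 1]`, with even sum.
#' @examples
#' set.seed(1)
#' d <- generate_degree_sequence(40, "high")
#' max(d) > stats::median(d)  # hub-dominated
#' @export
generate_degree_sequence <- function(n, preset = c("light", "moderate", "high"),
                                     mean_degree = NULL, sigma = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be at least 2")
  if (is.null(mean_degree) || is.null(sigma)) {
    preset <- match.arg(preset)
    p <- skew_presets()[[preset]]
    if (is.null(mean_degree)) mean_degree <- p$mean_degree
    if (is.null(sigma)) sigma <- p$sigma
  }
  if (mean_degree <= 0 || sigma < 0) stop("invalid degree-distribution parameters")
  mu <- log(mean_degree) - sigma^2 / 2
  d <- as.integer(round(stats::rlnorm(n, meanlog = mu, sdlog = sigma)))
  d <- pmin(pmax(d, 1L), n - 1L)
  if (sum(d) %% 2L == 1L) {
    i <- which.min(d)
    if (d[i] < n - 1L) d[i] <- d[i] + 1L else {
      j <- which.max(d)
      d[j] <- d[j] - 1L
    }
  }
  d
}

#' Realise a social network from a target degree sequence
#'
#' Wires a simple graph whose degrees equal the target sequence exactly.
#' When `enforce_connected` is set (the default) the Viger–Latapy sampler
#' ([igraph::sample_degseq()] method `"vl"`) draws a connected simple
#' realisation; otherwise the degree-preserving edge-switching sampler is
#' used. If the primary sampler fails, the wiring falls back to
#' edge-switching followed by degree-preserving double-edge swaps that join
#' components, retrying up to `max_attempts` times. Both samplers draw from
#' R's RNG, so realisations are reproducible under `set.seed()`.
#'
#' @param degrees integer vector; even sum, each entry in `[0, n - 1]`,
#'   graphical (and connected-realisable when `enforce_connected`).
#' @param enforce_connected require a single connected component (default).
#' @param max_attempts wiring restarts before giving up.
#' @param structure_label,generator_seed provenance recorded on the result.
#' @return a [social_network] whose degree sequence equals `degrees`.
#' @export
realize_network <- function(degrees, enforce_connected = TRUE,
                            max_attempts = 100,
                            structure_label = "custom",
                            generator_seed = NA_integer_) {
  degrees <- as.integer(degrees)
  n <- length(degrees)
  if (n < 2L) stop("need at least 2 nodes")
  if (any(degrees < 0L) || any(degrees > n - 1L))
    stop("degrees must lie in [0, n - 1]")
  if (sum(degrees) %% 2L != 0L)
    stop("degree sequence must have even sum")
  if (!igraph::is_graphical(degrees))
    stop(sprintf(paste0(
      "degree sequence is not graphical (no simple graph realises it): ",
      "sum %d, max %d, n %d"), sum(degrees), max(degrees), n))
  if (enforce_connected && sum(degrees) / 2 < n - 1)
    stop("too few edges for a connected graph on ", n, " nodes")
  as_network <- function(g)
    social_network(edge_matrix_of(g), n, structure_label = structure_label,
                   generator_seed = generator_seed)
  method <- if (enforce_connected) "vl" else "edge.switching.simple"
  # near-unique realisations make the samplers warn that they cannot shuffle;
  # the returned graph is still a valid realisation
  g <- tryCatch(suppressWarnings(igraph::sample_degseq(degrees, method = method)),
                error = function(e) NULL)
  if (!is.null(g) && (!enforce_connected || igraph::is_connected(g)))
    return(as_network(g))
  # fallback: simple realisation, then swap components together
  for (attempt in seq_len(max_attempts)) {
    g <- tryCatch(
      suppressWarnings(
        igraph::sample_degseq(degrees, method = "edge.switching.simple")),
      error = function(e) NULL)
    if (is.null(g)) next
    if (!enforce_connected || igraph::is_connected(g))
      return(as_network(g))
    edges <- connect_components(edge_matrix_of(g), n)
    if (!is.null(edges))
      return(social_network(edges, n, structure_label = structure_label,
                            generator_seed = generator_seed))
  }
  stop(sprintf(paste0(
    "failed to realise a simple%s graph for the degree sequence ",
    "(sum %d, max %d) within %d attempts"),
    if (enforce_connected) " connected" else "",
    sum(degrees), max(degrees), max_attempts))
}

edge_matrix_of <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el
}

# degree-preserving swaps joining components until connected; NULL on failure
connect_components <- function(edges, n, max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n)
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)
    if (comp$no == 1L) return(edges)
    if (any(comp$csize == 1L)) return(NULL)  # isolated node: unfixable by swaps
    giant <- which.max(comp$csize)
    memb <- comp$membership
    in_giant <- memb[edges[, 1]] == giant  # edges never straddle components
    small_edges <- which(!in_giant)
    giant_edges <- which(in_giant)
    i <- small_edges[sample.int(length(small_edges), 1L)]
    j <- giant_edges[sample.int(length(giant_edges), 1L)]
    a <- edges[i, 1]; b <- edges[i, 2]
    c <- edges[j, 1]; d <- edges[j, 2]
    e1 <- c(a, c); e2 <- c(b, d)
    key <- edge_key(edges, n)
    k1 <- edge_key(matrix(e1, ncol = 2), n)
    k2 <- edge_key(matrix(e2, ncol = 2), n)
    rest <- key[-c(i, j)]
    if (e1[1] == e1[2] || e2[1] == e2[2] || k1 == k2 ||
        k1 %in% rest || k2 %in% rest) next
    edges[i, ] <- e1
    edges[j, ] <- e2
  }
  NULL
}

#' Generate a skewed community network
#'
#' Composition of [generate_degree_sequence()] and [realize_network()]:
#' draws degrees from the preset's discretised lognormal and wires a simple
#' (by default connected) graph realising them exactly.
#'
#' @inheritParams generate_degree_sequence
#' @inheritParams realize_network
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so that identical `(n, preset, seed)` reproduce identical networks.
#' @return a [social_network] labelled with the preset and seed.
#' @examples
#' net <- generate_network(40, "high", seed = 7)
#' net
#' @export
generate_network <- function(n, preset = c("light", "moderate", "high"),
                             seed = NULL, mean_degree = NULL, sigma = NULL,
                             enforce_connected = TRUE, max_attempts = 100) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(as.integer(seed))
  # heavy-tailed presets occasionally draw a sequence no (connected) simple
  # graph can realise — non-graphical (e.g. two saturated hubs alongside
  # degree-1 nodes) or with fewer than n - 1 edges; the draw is conditioned
  # on realisability by redrawing within the retry budget
  for (attempt in seq_len(max_attempts)) {
    d <- generate_degree_sequence(n, preset, mean_degree = mean_degree,
                                  sigma = sigma)
    if (igraph::is_graphical(d) &&
        (!enforce_connected || sum(d) / 2 >= n - 1)) break
    d <- NULL
  }
  if (is.null(d))
    stop("could not draw a realisable degree sequence within ", max_attempts,
         " attempts")
  realize_network(d, enforce_connected = enforce_connected,
                  max_attempts = max_attempts,
                  structure_label = preset,
                  generator_seed = if (is.null(seed)) NA_integer_
                                   else as.integer(seed))
}

#' Star network: the theoretical extreme of skew
#'
#' One hub connected to every other individual, no other ties: degrees
#' `c(n - 1, 1, ..., 1)`.
#'
#' @param n number of individuals (`n >= 2`); node 1 is the hub.
#' @return a [social_network] with `n - 1` edges.
#' @export
star_network <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("a star network needs at least 2 nodes")
  social_network(cbind(1L, 2:n), n, structure_label = "custom")
}

#' Sample skewness of the degree distribution
#'
#' Bias-corrected sample skewness (the third standardised moment with the
#' \eqn{\sqrt{n(n-1)}/(n-2)} correction) of the per-node degrees, the
#' statistic used to rank communities from even to hub-dominated
#' connectedness. Undefined for fewer than 3 nodes or a zero-variance
#' (regular) degree sequence; those cases return `NA_real_` rather than
#' erroring, so callers can flag them.
#'
#' @param net a [social_network], or a bare numeric degree vector.
#' @return the bias-corrected sample skewness, or `NA_real_` when undefined.
#' @examples
#' degree_skewness(star_network(5))  # [4,1,1,1,1] -> 1.5 * sqrt(20) / 3
#' @export
degree_skewness <- function(net) {
  d <- if (is_social_network(net)) degree_sequence(net) else as.numeric(net)
  n <- length(d)
  if (n < 3L) return(NA_real_)
  m <- mean(d)
  m2 <- mean((d - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((d - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
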
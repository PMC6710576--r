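#' Configuration of the factorial simulation experiment
#'
#' The full factorial design: community structures x listening threshold `T`
#' x listening probability `L` x patrol effort `E`, with a number of
#' replicates per cell. The defaults reproduce the reference design: three
#' structures, `T` in \{1, 2\}, ten `L` values (0.1 to 1.0), six `E` values
#' (0.05 to 0.30) — 120 `(T, L, E)` combinations — and 100 replicates per
#' cell on 40-individual networks over 50 time-steps, a fresh network per
#' replicate (12,000 generated networks per structure, 36,000 rows in all).
#'
#' @param structures character vector of skew presets.
#' @param T_values,L_values,E_values grids of the diffusion parameters.
#' @param replicates replicates per cell (a fresh network each).
#' @param n community size.
#' @param n_steps time-steps per simulation.
#' @param strategy seeding strategy, see [seed_knowledge()].
#' @param base_seed integer master seed; every run's seed derives from it.
#' @param enforce_connected require connected networks (default).
#' @param listening_model see [diffusion_params()].
#' @return an object of class `grid_config`.
#' @export
grid_config <- function(structures = c("light", "moderate", "high"),
                        T_values = c(1L, 2L),
                        L_values = seq(0.1, 1, by = 0.1),
                        E_values = seq(0.05, 0.30, by = 0.05),
                        replicates = 100L,
                        n = 40L,
                        n_steps = 50L,
                        strategy = "least_connected",
                        base_seed = 1L,
                        enforce_connected = TRUE,
                        listening_model = "per_node") {
  structures <- as.character(structures)
  known <- names(skew_presets())
  if (length(structures) == 0L || !all(structures %in% known))
    stop("'structures' must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  T_values <- as.integer(T_values)
  if (length(T_values) == 0L || anyNA(T_values) || any(T_values < 1L))
    stop("'T_values' must be positive integers")
  if (length(L_values) == 0L || any(L_values < 0) || any(L_values > 1))
    stop("'L_values' must lie in [0, 1]")
  if (length(E_values) == 0L || any(E_values < 0) || any(E_values > 1))
    stop("'E_values' must lie in [0, 1]")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("'replicates' must be >= 1")
  n <- as.integer(n); n_steps <- as.integer(n_steps)
  if (is.na(n) || n < 2L) stop("'n' must be >= 2")
  if (is.na(n_steps) || n_steps < 1L) stop("'n_steps' must be >= 1")
  strategy <- match.arg(strategy, c("least_connected", "best_connected"))
  listening_model <- match.arg(listening_model, c("per_node", "per_edge"))
  structure(list(structures = structures, T_values = T_values,
                 L_values = as.numeric(L_values),
                 E_values = as.numeric(E_values),
                 replicates = replicates, n = n, n_steps = n_steps,
                 strategy = strategy, base_seed = as.integer(base_seed),
                 enforce_connected = enforce_connected,
                 listening_model = listening_model),
            class = "grid_config")
}

#' @export
print.grid_config <- function(x, ...) {
  cells <- length(x$structures) * length(x$T_values) *
    length(x$L_values) * length(x$E_values)
  cat(sprintf(paste0(
    "<grid_config> %d structures x %d T x %d L x %d E = %d cells, ",
    "%d replicates each (%d runs)\n"),
    length(x$structures), length(x$T_values), length(x$L_values),
    length(x$E_values), cells, x$replicates, cells * x$replicates))
  cat(sprintf("  n = %d, n_steps = %d, strategy = %s, base_seed = %d\n",
              x$n, x$n_steps, x$strategy, x$base_seed))
  invisible(x)
}

# canonical run table: one row per (structure, T, L, E, replicate), with the
# run seed fixed by the row's position in the canonical factorial order so
# that execution order cannot affect results
grid_rows <- function(config) {
  g <- expand.grid(replicate = seq_len(config$replicates),
                   E = config$E_values,
                   L = config$L_values,
                   T = config$T_values,
                   structure = config$structures,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("structure", "T", "L", "E", "replicate")]
  g$network_seed <- derive_run_seeds(config$base_seed, nrow(g))
  g
}

# affine map of the canonical run index into [0, 2^31 - 2]; the multiplier is
# coprime with the prime modulus, so seeds are distinct within a run
derive_run_seeds <- function(base_seed, n_runs) {
  mod <- 2147483647
  idx <- seq_len(n_runs) - 1
  as.integer((as.numeric(base_seed) %% mod + idx * 2654435761) %% mod)
}

#' Run the factorial simulation experiment
#'
#' For every row of the factorial design a fresh network is generated and
#' one diffusion is simulated, yielding a tidy results table. Each run is
#' seeded from `base_seed` and the row's position in the canonical grid, so
#' the table is fully reproducible and independent of execution order.
#'
#' @param config a [grid_config].
#' @param verbose emit one log line per grid cell with its mean AUC.
#' @param execution_order optional permutation of the run indices; results
#'   are identical for any order (exposed for verification and for chunked
#'   execution).
#' @return a `results_table`: data.frame with columns `structure`, `T`, `L`,
#'   `E`, `replicate`, `network_seed`, `auc`, `final_count`, in canonical
#'   grid order.
#' @examples
#' cfg <- grid_config(structures = "light", T_values = 1, L_values = 0.5,
#'                    E_values = 0.25, replicates = 3, base_seed = 42)
#' run_grid(cfg)
#' @export
run_grid <- function(config, verbose = FALSE, execution_order = NULL) {
  stopifnot(inherits(config, "grid_config"))
  rows <- grid_rows(config)
  n_runs <- nrow(rows)
  if (is.null(execution_order)) {
    execution_order <- seq_len(n_runs)
  } else {
    execution_order <- as.integer(execution_order)
    if (!setequal(execution_order, seq_len(n_runs)))
      stop("'execution_order' must be a permutation of the run indices")
  }
  auc <- integer(n_runs)
  final_count <- integer(n_runs)
  for (i in execution_order) {
    net <- generate_network(config$n, rows$structure[i],
                            seed = rows$network_seed[i],
                            enforce_connected = config$enforce_connected)
    params <- diffusion_params(T = rows$T[i], L = rows$L[i], E = rows$E[i],
                               n_steps = config$n_steps,
                               listening_model = config$listening_model)
    traj <- run_diffusion(net, params, strategy = config$strategy)
    auc[i] <- traj$auc
    final_count[i] <- traj$counts[traj$n_steps]
  }
  rows$auc <- auc
  rows$final_count <- final_count
  if (verbose) {
    cells <- unique(rows[, c("structure", "T", "L", "E")])
    for (j in seq_len(nrow(cells))) {
      sel <- rows$structure == cells$structure[j] & rows$T == cells$T[j] &
        rows$L == cells$L[j] & rows$E == cells$E[j]
      message(sprintf("cell structure=%s T=%d L=%.2f E=%.2f mean_auc=%.1f",
                      cells$structure[j], cells$T[j], cells$L[j],
                      cells$E[j], mean(rows$auc[sel])))
    }
  }
  class(rows) <- c("results_table", "data.frame")
  rows
}

#' Per-cell summary of a results table
#'
#' Mean and standard deviation of the AUC for every
#' `(structure, T, L, E)` cell.
#'
#' @param table a `results_table` from [run_grid()] or [read_results()].
#' @return data.frame with one row per cell: `structure`, `T`, `L`, `E`,
#'   `n_replicates`, `mean_auc`, `sd_auc`.
#' @export
summarize_cells <- function(table) {
  validate_results(table)
  if (nrow(table) == 0L) stop("empty results table")
  key <- interaction(table$structure, table$T, table$L, table$E, drop = TRUE)
  first <- !duplicated(key)
  out <- table[first, c("structure", "T", "L", "E")]
  split_auc <- split(table$auc, key)[as.character(key[first])]
  out$n_replicates <- lengths(split_auc)
  out$mean_auc <- vapply(split_auc, mean, numeric(1))
  out$sd_auc <- vapply(split_auc, function(x)
    if (length(x) > 1) stats::sd(x) else 0, numeric(1))
  rownames(out) <- NULL
  out
}

results_columns <- c("structure", "T", "L", "E", "replicate",
                     "network_seed", "auc", "final_count")

validate_results <- function(table) {
  if (!is.data.frame(table)) stop("results must be a data.frame")
  missing <- setdiff(results_columns, names(table))
  if (length(missing) > 0)
    stop("results table is missing column(s): ", paste(missing, collapse = ", "))
  num <- c("T", "L", "E", "replicate", "auc", "final_count")
  for (col in num) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(table[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("results table row %d: non-numeric value in column '%s'",
                   bad[1], col))
  }
  if (any(table$L < 0 | table$L > 1) || any(table$E < 0 | table$E > 1))
    stop("results table: L and E must lie in [0, 1]")
  if (any(table$auc < 0))
    stop("results table: negative AUC")
  invisible(table)
}

#' Write or read a results table as CSV
#'
#' Lossless CSV round trip with a header row and stable column order; values
#' survive bit-for-bit in decimal text. `read_results()` validates the
#' columns and invariants and names the offending column or line on failure.
#'
#' @param table a `results_table`.
#' @param path CSV file path.
#' @return `write_results()`: `path`, invisibly. `read_results()`: a
#'   `results_table`.
#' @export
write_results <- function(table, path) {
  validate_results(table)
  utils::write.csv(as.data.frame(table)[, results_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_results(table)
  class(table) <- c("results_table", "data.frame")
  table
}
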
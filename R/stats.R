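#' Per-stratum regression of AUC on patrol effort and listening probability
#'
#' Within one stratum — a (community structure, listening threshold `T`)
#' slice of the experiment — fits the ordinary least squares model
#' `auc ~ E + L + E:L` over all replicate rows (replicates are pooled as
#' independent observations; predictors are on their natural scale). Reports
#' coefficients, standard errors, two-sided t-test p-values and the
#' sign/significance code of each term.
#'
#' @param table a `results_table`.
#' @param structure community-structure label of the stratum.
#' @param T listening threshold of the stratum.
#' @return object of class `auc_regression`: list with `structure`, `T` and
#'   a `coefficients` data.frame (`term`, `estimate`, `se`, `p_value`,
#'   `code`).
#' @export
fit_auc_regression <- function(table, structure, T) {
  validate_results(table)
  sub <- table[table$structure == structure & table$T == T, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no rows for stratum (structure = %s, T = %d)",
                 structure, as.integer(T)))
  if (length(unique(sub$L)) < 2L || length(unique(sub$E)) < 2L)
    stop(sprintf(paste0(
      "stratum (structure = %s, T = %d) needs at least 2 distinct L and ",
      "2 distinct E values to fit the interaction model"),
      structure, as.integer(T)))
  fit <- stats::lm(auc ~ E + L + E:L, data = sub)
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf),
                    estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"],
                    p_value = cf[, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  out$code <- sign_code(out$estimate, out$p_value)
  rownames(out) <- NULL
  res <- list(structure = structure, T = as.integer(T),
              coefficients = out, n_obs = nrow(sub))
  class(res) <- "auc_regression"
  res
}

#' @export
print.auc_regression <- function(x, ...) {
  cat(sprintf("<auc_regression> stratum: structure = %s, T = %d (%d rows)\n",
              x$structure, x$T, x$n_obs))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sign and significance code of a regression term
#'
#' The reporting convention for the sign matrix: `"+++"`/`"---"` for
#' `p <= 0.01`, `"+"`/`"-"` for `0.01 < p <= 0.05`, `"0"` otherwise, signed
#' by the coefficient. `p = 0.05` is coded as significant (`"+"`/`"-"`):
#' significance wins at the boundary.
#'
#' @param coefficient numeric coefficient(s).
#' @param p_value two-sided p-value(s) in `[0, 1]`.
#' @return character vector of codes.
#' @examples
#' sign_code(c(2.3, -1, 5), c(0.005, 0.03, 0.5))
#' @export
sign_code <- function(coefficient, p_value) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pos <- coefficient >= 0
  ifelse(p_value <= 0.01, ifelse(pos, "+++", "---"),
         ifelse(p_value <= 0.05, ifelse(pos, "+", "-"), "0"))
}

#' Sign matrix of the effects of E and L on information flow
#'
#' Fits [fit_auc_regression()] in all six strata (three community
#' structures x `T` in \{1, 2\} by default) and assembles the matrix of
#' sign/significance codes for the patrol-effort, listening-probability and
#' interaction terms.
#'
#' @param table a `results_table` containing every stratum.
#' @param structures,T_values the strata to report (defaults: the three
#'   presets and `T` in \{1, 2\}).
#' @return object of class `sign_matrix`: data.frame with one row per
#'   stratum (`structure`, `T`) and columns `E`, `L`, `E:L` holding codes,
#'   plus the fitted `auc_regression` objects in attribute `"fits"`.
#' @export
table1_report <- function(table,
                          structures = c("light", "moderate", "high"),
                          T_values = c(1L, 2L)) {
  validate_results(table)
  present <- unique(table[, c("structure", "T")])
  for (s in structures) for (Tv in T_values) {
    if (!any(present$structure == s & present$T == Tv))
      stop(sprintf("missing stratum: structure = %s, T = %d", s, as.integer(Tv)))
  }
  grid <- expand.grid(T = as.integer(T_values), structure = structures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("structure", "T")]
  fits <- vector("list", nrow(grid))
  codes <- matrix(NA_character_, nrow(grid), 3,
                  dimnames = list(NULL, c("E", "L", "E:L")))
  for (i in seq_len(nrow(grid))) {
    fit <- fit_auc_regression(table, grid$structure[i], grid$T[i])
    fits[[i]] <- fit
    cf <- fit$coefficients
    codes[i, ] <- cf$code[match(c("E", "L", "E:L"), cf$term)]
  }
  out <- cbind(grid, as.data.frame(codes, check.names = FALSE))
  attr(out, "fits") <- fits
  class(out) <- c("sign_matrix", "data.frame")
  out
}

#' @export
print.sign_matrix <- function(x, ...) {
  cat("Direction of the influence of E and L on information flow (AUC)\n")
  cat("(+++/--- p <= 0.01; +/- 0.01 < p <= 0.05; 0 otherwise)\n\n")
  cat(format_sign_matrix(x), sep = "\n")
  invisible(x)
}

# aligned text rendering, strata as rows grouped by structure
format_sign_matrix <- function(x) {
  df <- as.data.frame(x)[, c("structure", "T", "E", "L", "E:L")]
  df$T <- paste0("T=", df$T)
  header <- c("structure", "T", "E", "L", "E:L")
  cells <- rbind(header, as.matrix(df))
  widths <- apply(nchar(cells), 2, max)
  apply(cells, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
}

#' @rdname table1_report
#' @param x a `sign_matrix`.
#' @param path CSV file path.
#' @export
write_sign_matrix <- function(x, path) {
  stopifnot(inherits(x, "sign_matrix"))
  df <- as.data.frame(x)[, c("structure", "T", "E", "L", "E:L")]
  names(df) <- c("structure", "T", "E", "L", "E_L")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Long-format regression summary across all strata
#'
#' @param x a `sign_matrix` from [table1_report()].
#' @return data.frame with one row per stratum x term: `structure`, `T`,
#'   `term`, `estimate`, `se`, `p_value`, `code`.
#' @export
regression_summary_table <- function(x) {
  stopifnot(inherits(x, "sign_matrix"))
  fits <- attr(x, "fits")
  do.call(rbind, lapply(fits, function(f) {
    cbind(data.frame(structure = f$structure, T = f$T,
                     stringsAsFactors = FALSE),
          f$coefficients)
  }))
}
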
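#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` by least squares (via [stats::lm()]) and
#' reports the slope, intercept, coefficient of determination and slope
#' standard error. R^2 is the squared Pearson correlation; for a
#' zero-variance response it is undefined and reported as 0 with a warning.
#'
#' @param x Predictor values; must not be constant.
#' @param y Response values; same length as `x`.
#' @return An object of class `regression_result`: a list with `slope`,
#'   `intercept`, `r_squared`, `n`, `slope_se`.
#' @examples
#' fit_linear(0:2, c(1, 3, 5))  # slope 2, intercept 1, R^2 = 1
#' @export
fit_linear <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric", call. = FALSE)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate fit: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  if (stats::var(y) == 0) {
    warning("response has zero variance; R^2 reported as 0")
    r2 <- 0
  } else {
    r2 <- stats::cor(x, y)^2
  }
  # classic OLS slope standard error, sqrt(SSE / (n-2) / Sxx)
  slope_se <- if (n > 2L) {
    sqrt(sum(stats::residuals(fit)^2) / (n - 2L) / sum((x - mean(x))^2))
  } else {
    NA_real_
  }
  structure(
    list(slope = unname(co[["x"]]), intercept = unname(co[["(Intercept)"]]),
         r_squared = r2, n = n, slope_se = slope_se),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.6g x + %.6g, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Regression of log2 relative Pfr half-life on temperature
#'
#' Computes the relative Pfr dark-reversion half-life (reference 22 degC = 1)
#' at each growth temperature via [relative_half_life()], log-transforms
#' (base 2 by default, matching the conventional reporting scale), and fits a
#' line against temperature in degrees Celsius. Over the 4-37 degC
#' physiological range the relationship is almost perfectly log-linear:
#' log2(relative t_1/2) ~ -0.024 T + 0.54, R^2 > 0.998.
#'
#' @param temperatures_c Growth temperatures in degC; must include the 22
#'   degC reference.
#' @inheritParams spectral_energy_density
#' @param log_base Base of the logarithm applied before fitting (default 2).
#' @return A `regression_result`; the computed series is attached as
#'   attribute `series`, a data frame with columns `temperature_C`,
#'   `relative_half_life`, `log_value`.
#' @examples
#' half_life_regression()
#' @export
half_life_regression <- function(temperatures_c = default_temperatures_c(),
                                 constants = physical_constants(),
                                 log_base = 2) {
  if (!any(temperatures_c == reference_temperature_c())) {
    stop("temperatures must include the 22 degC reference", call. = FALSE)
  }
  rel <- relative_half_life(celsius_to_kelvin(temperatures_c),
                            constants = constants)
  logv <- log(rel, base = log_base)
  res <- fit_linear(temperatures_c, logv)
  attr(res, "series") <- data.frame(
    temperature_C = temperatures_c,
    relative_half_life = rel,
    log_value = logv
  )
  res
}

#' Per-genotype fit of hypocotyl length against relative R:IR ratio
#'
#' For each genotype in the dataset, regresses hypocotyl length on the
#' relative R:IR ratio r(22 degC, T). By default replicate lengths are
#' averaged per temperature before fitting (each growth condition contributes
#' one point, as when fitting condition means); per-seedling fitting is
#' available via `aggregate = FALSE`.
#'
#' @param dataset A hypocotyl dataset from [generate_hypocotyl_data()] or
#'   [read_hypocotyl_csv()]: a data frame with columns `genotype`,
#'   `temperature_C`, `relative_r`, `length_mm`.
#' @param aggregate Fit per-temperature mean lengths (default) or individual
#'   seedlings.
#' @return A named list of `regression_result` objects, one per genotype.
#' @examples
#' ds <- generate_hypocotyl_data(builtin_archetypes()[["YHB"]], seed = 1)
#' hypocotyl_response_fit(ds)
#' @export
hypocotyl_response_fit <- function(dataset, aggregate = TRUE) {
  required <- c("genotype", "temperature_C", "relative_r", "length_mm")
  missing_cols <- setdiff(required, names(dataset))
  if (length(missing_cols)) {
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  fits <- lapply(split(dataset, dataset$genotype), function(d) {
    if (length(unique(d$temperature_C)) < 2L) {
      stop("genotype '", d$genotype[1L],
           "' has fewer than 2 distinct temperatures", call. = FALSE)
    }
    if (length(unique(d$relative_r)) < 2L) {
      stop("degenerate fit for genotype '", d$genotype[1L],
           "': relative R:IR ratio is constant", call. = FALSE)
    }
    if (aggregate) {
      m <- stats::aggregate(length_mm ~ relative_r, data = d, FUN = mean)
      fit_linear(m$relative_r, m$length_mm)
    } else {
      fit_linear(d$relative_r, d$length_mm)
    }
  })
  fits
}

#' Rank genotypes by sensitivity to the R:IR ratio
#'
#' Orders genotypes by the magnitude of their fitted slope (mm per unit
#' relative R:IR ratio) and flags genotypes whose sensitivity has dropped
#' below a fraction of the most responsive (reference) genotype. The 0.5
#' threshold is a reporting convention, not a biological constant, and is
#' configurable.
#'
#' @param results A named list of `regression_result` objects (as returned by
#'   [hypocotyl_response_fit()]).
#' @param threshold Fraction of the reference |slope| below which a genotype
#'   is flagged as having reduced sensitivity.
#' @return A data frame ordered by decreasing |slope| with columns
#'   `genotype`, `slope`, `abs_slope`, `rank`, `reduced_sensitivity`.
#' @examples
#' fits <- list(
#'   `Col-0` = fit_linear(c(0.8, 1, 1.4), c(7, 4, -2)),
#'   YHB = fit_linear(c(0.8, 1, 1.4), c(1.7, 1.4, 0.8))
#' )
#' sensitivity_comparison(fits)
#' @export
sensitivity_comparison <- function(results, threshold = 0.5) {
  if (length(results) < 2L) stop("need at least 2 genotypes", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "regression_result")))
  slopes <- vapply(results, `[[`, numeric(1), "slope")
  abs_slope <- abs(slopes)
  ref <- max(abs_slope)
  out <- data.frame(
    genotype = names(slopes),
    slope = unname(slopes),
    abs_slope = unname(abs_slope)
  )
  out <- out[order(-out$abs_slope, out$genotype), , drop = FALSE]
  # rank on rounded magnitudes so float noise cannot break exact ties
  out$rank <- rank(-signif(out$abs_slope, 12), ties.method = "min")
  out$reduced_sensitivity <- ref > 0 & out$abs_slope < threshold * ref
  rownames(out) <- NULL
  out
}

#' Write per-genotype fit results
#'
#' @param results Named list of `regression_result` objects.
#' @param json_path Optional JSON output path.
#' @param csv_path Optional CSV output path.
#' @return A data frame with one row per genotype (`genotype`, `slope`,
#'   `intercept`, `r_squared`, `n`, `slope_se`), invisibly if a path was
#'   written.
#' @export
fit_report <- function(results, json_path = NULL, csv_path = NULL) {
  tab <- do.call(rbind, lapply(names(results), function(g) {
    r <- results[[g]]
    data.frame(genotype = g, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, n = r$n, slope_se = r$slope_se)
  }))
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (is.null(json_path) && is.null(csv_path)) tab else invisible(tab)
}
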
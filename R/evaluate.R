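#' Error metrics between manual and image-based counts
#'
#' For paired counts (`O` = manual, `E` = image analysis):
#' `RMSE = sqrt(mean((E - O)^2))`, `MAE = mean(|E - O|)`,
#' `MBE = mean(E - O)` (signed bias), and `MSE = mean((E - O)^2)`.
#' MSE is reported alongside MBE because the two are easily conflated in
#' agreement tables; `MSE = RMSE^2` always.
#'
#' @param O Numeric vector of manual counts.
#' @param E Numeric vector of image-analysis counts, same length (n >= 2).
#' @return A one-row tibble with columns `rmse`, `mae`, `mbe`, `mse`.
#' @examples
#' error_metrics(O = c(10, 20), E = c(11, 18))
#' @export
error_metrics <- function(O, E) {
  if (length(O) != length(E)) abort("O and E must have the same length")
  if (length(O) < 2L) abort("need at least 2 paired observations")
  if (anyNA(O) || anyNA(E)) abort("counts must not contain missing values")
  d <- E - O
  tibble(
    rmse = sqrt(mean(d^2)),
    mae = mean(abs(d)),
    mbe = mean(d),
    mse = mean(d^2)
  )
}

#' Coefficient of determination about the identity line
#'
#' `R^2 = 1 - sum((O - E)^2) / sum((O - mean(O))^2)`. Unlike the squared
#' Pearson correlation this penalises bias and miscalibration: it is 1 only
#' when `E` reproduces `O` exactly, and can be negative when `E` is worse than
#' predicting the mean of `O`.
#'
#' @inheritParams error_metrics
#' @return A single numeric value <= 1.
#' @examples
#' r_squared(O = c(1, 2, 3), E = c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(O, E) {
  if (length(O) != length(E)) abort("O and E must have the same length")
  ss_o <- sum((O - mean(O))^2)
  if (ss_o == 0) abort("undefined R-squared: O has zero variance")
  1 - sum((O - E)^2) / ss_o
}

#' Test the E-on-O regression against the identity line
#'
#' Ordinary least squares of `E` on `O`, with F tests (squared-t on 1 and
#' n - 2 degrees of freedom) of the slope against 1 and the intercept against
#' 0 — the standard check that an automatic counter agrees with manual counts
#' not just in correlation but in calibration. Pearson's r and its
#' significance are included. With zero residual variance (perfect agreement)
#' the p-values are set to 1 by convention and a message is emitted.
#'
#' @inheritParams error_metrics
#' @return A one-row tibble: `slope`, `intercept`, `p_slope_vs_1`,
#'   `p_intercept_vs_0`, `r`, `p_r`, `n`.
#' @export
identity_regression_test <- function(O, E) {
  if (length(O) != length(E)) abort("O and E must have the same length")
  n <- length(O)
  if (n < 3L) abort("need at least 3 paired observations")
  if (var(O) == 0) abort("degenerate regression: O has zero variance")
  fit <- lm(E ~ O)
  cf <- coef(fit)
  rss <- sum(fit$residuals^2)
  if (rss < 1e-12 * max(1, sum(E^2))) {
    inform("zero residual variance: regression p-values set to 1 by convention")
    return(tibble(
      slope = cf[[2]], intercept = cf[[1]],
      p_slope_vs_1 = 1, p_intercept_vs_0 = 1,
      r = if (var(E) > 0) cor(O, E) else NA_real_, p_r = 1, n = n
    ))
  }
  se <- sqrt(diag(vcov_ols(fit)))
  f_slope <- ((cf[[2]] - 1) / se[2])^2
  f_int <- (cf[[1]] / se[1])^2
  r <- cor(O, E)
  t_r <- r * sqrt((n - 2) / (1 - r^2))
  tibble(
    slope = cf[[2]],
    intercept = cf[[1]],
    p_slope_vs_1 = pf(f_slope, 1, n - 2, lower.tail = FALSE),
    p_intercept_vs_0 = pf(f_int, 1, n - 2, lower.tail = FALSE),
    r = r,
    p_r = 2 * pt(abs(t_r), n - 2, lower.tail = FALSE),
    n = n
  )
}

vcov_ols <- function(fit) {
  x <- stats::model.matrix(fit)
  s2 <- sum(fit$residuals^2) / fit$df.residual
  s2 * solve(crossprod(x))
}

#' Full method-agreement report
#'
#' Bundles [error_metrics()], [r_squared()] and [identity_regression_test()]
#' for a table of paired manual (`O`) and image-analysis (`E`) counts, the
#' complete accuracy panel for one species or dataset.
#'
#' @param data A data frame with the count columns.
#' @param truth,estimate Column names of the manual and estimated counts.
#' @return An object of class `agreement_report`; see [tidy.agreement_report()]
#'   and [glance.agreement_report()].
#' @export
agreement_report <- function(data, truth = "O", estimate = "E") {
  O <- data[[truth]]
  E <- data[[estimate]]
  if (is.null(O) || is.null(E)) abort("`data` must contain the truth and estimate columns")
  structure(
    list(
      data = tibble(O = O, E = E),
      n = length(O),
      metrics = error_metrics(O, E),
      r_squared = r_squared(O, E),
      regression = identity_regression_test(O, E)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<agreement_report> n = %d\n",
      "  r = %.3f (p = %.3g); slope = %.3f (p vs 1 = %.3g); ",
      "intercept = %.2f (p vs 0 = %.3g)\n",
      "  RMSE = %.2f, MAE = %.2f, MBE = %.2f, MSE = %.2f, R^2 = %.3f\n"
    ),
    x$n, x$regression$r, x$regression$p_r, x$regression$slope,
    x$regression$p_slope_vs_1, x$regression$intercept,
    x$regression$p_intercept_vs_0,
    x$metrics$rmse, x$metrics$mae, x$metrics$mbe, x$metrics$mse, x$r_squared
  ))
  invisible(x)
}

#' Tidy and summarise an agreement report
#'
#' `tidy()` returns one row per statistic; `glance()` one wide row mirroring
#' an accuracy table (r, slope and its p-value vs 1, intercept and its p-value
#' vs 0, RMSE, MAE, MBE, MSE, R^2).
#'
#' @param x An [agreement_report()].
#' @param ... Unused.
#' @export
tidy.agreement_report <- function(x, ...) {
  g <- glance.agreement_report(x)
  tibble(statistic = names(g), value = as.numeric(g[1, ]))
}

#' @rdname tidy.agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    n = x$n,
    r = x$regression$r,
    p_r = x$regression$p_r,
    slope = x$regression$slope,
    p_slope_vs_1 = x$regression$p_slope_vs_1,
    intercept = x$regression$intercept,
    p_intercept_vs_0 = x$regression$p_intercept_vs_0,
    rmse = x$metrics$rmse,
    mae = x$metrics$mae,
    mbe = x$metrics$mbe,
    mse = x$metrics$mse,
    r_squared = x$r_squared
  )
}

#' Write an agreement report to JSON or CSV
#'
#' @param report An [agreement_report()].
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return The path, invisibly.
#' @export
write_agreement <- function(report, path) {
  g <- glance(report)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(g), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.csv(g, path, row.names = FALSE)
  }
  invisible(path)
}
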
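#' Fit the saturating-exponential artifact model
#'
#' Motion-induced image error grows with the amount of motion during
#' acquisition but cannot grow without bound; empirically RMSE plateaus.
#' This heuristic two-parameter model captures that:
#' \deqn{RMSE = A (1 - e^{-R\, x})}
#' where `x` is a per-volume motion metric (M or M_PW, mm-equivalent), `A`
#' is the asymptotic artifact level (scaled intensity units) and `R` the
#' rate of approach (per mm-equivalent). Fitted by nonlinear least squares
#' (Levenberg-Marquardt), initialised at `A0 = max(rmse)`,
#' `R0 = 1/median(x)`, with positivity bounds on both parameters.
#'
#' @param x Nonnegative per-volume motion values (mm-equivalent).
#' @param rmse Per-volume RMSE values, same length.
#' @param predictor_label Label stored with the fit (`"M_PW"` or `"M"`).
#' @return An object of class `saturating_fit`: list with `A`, `rate_R`,
#'   `r2` (\eqn{1 - SS_{res}/SS_{tot}}), `n_points`, `predictor_label`,
#'   `converged`, `fitted` and `message`. Non-convergence is flagged, not
#'   silently replaced.
#' @export
fit_saturating <- function(x, rmse, predictor_label = "M_PW") {
  if (length(x) != length(rmse)) stop("x and rmse lengths differ")
  ok <- is.finite(x) & is.finite(rmse)
  x <- x[ok]; rmse <- rmse[ok]
  if (length(x) < 5) stop("need at least 5 points to fit")
  if (any(x < 0)) stop("predictor values must be nonnegative")
  if (all(x == 0) || max(x) - min(x) < 1e-12)
    stop("degenerate predictor: no spread in x, fit rejected")
  df <- data.frame(x = x, y = rmse)
  start <- list(A = max(rmse), R = 1 / max(stats::median(x), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-R * x)), data = df, start = start,
                      lower = c(A = 1e-12, R = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(A = NA_real_, rate_R = NA_real_, r2 = NA_real_,
                          n_points = length(x),
                          predictor_label = predictor_label,
                          converged = FALSE, fitted = NULL,
                          message = conditionMessage(fit)),
                     class = "saturating_fit"))
  }
  cf <- stats::coef(fit)
  pred <- cf["A"] * (1 - exp(-cf["R"] * x))
  ss_res <- sum((rmse - pred)^2)
  ss_tot <- sum((rmse - mean(rmse))^2)
  structure(list(A = unname(cf["A"]), rate_R = unname(cf["R"]),
                 r2 = 1 - ss_res / ss_tot, n_points = length(x),
                 predictor_label = predictor_label, converged = TRUE,
                 fitted = unname(pred), message = NULL),
            class = "saturating_fit")
}

#' @export
print.saturating_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<saturating_fit> NOT CONVERGED (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat("<saturating_fit> RMSE = A(1 - exp(-R ", x$predictor_label, ")):",
      " A = ", signif(x$A, 4), ", R = ", signif(x$rate_R, 4),
      " /mm, r2 = ", signif(x$r2, 4), " (n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Compare M and M_PW as artifact predictors
#'
#' Fits the saturating-exponential model to the same per-volume RMSE values
#' using both the plain integrated motion `M` and the partition-weighted
#' `M_PW` as predictors and reports both goodness-of-fit r-squared values.
#' A higher r-squared for M_PW indicates that weighting motion by the
#' k-space energy of the concurrently acquired partition improves artifact
#' prediction.
#'
#' @param M,M_PW Aligned per-volume motion metrics.
#' @param rmse Aligned per-volume RMSE values.
#' @return List with elements `M` and `M_PW`, each a `saturating_fit`.
#' @export
compare_predictors <- function(M, M_PW, rmse) {
  if (length(M) != length(rmse) || length(M_PW) != length(rmse))
    stop("inputs must be aligned per volume")
  list(M = fit_saturating(M, rmse, "M"),
       M_PW = fit_saturating(M_PW, rmse, "M_PW"))
}

#' Binned percent reduction in RMSE (PMC on vs off)
#'
#' Bins the per-volume RMSE values of a correction-off and a correction-on
#' condition on shared motion-metric bins (default 2.5 mm wide, starting at
#' zero), keeps only bins where both conditions contribute at least
#' `min_count` volumes, and reports per bin the mean RMSE of each
#' condition, the percent reduction
#' `(RMSE_off - RMSE_on) / RMSE_off * 100`, and its standard error by
#' first-order propagation of the per-bin standard errors of the means.
#'
#' @param mpw_off,rmse_off Per-volume metric and RMSE, correction off.
#' @param mpw_on,rmse_on Per-volume metric and RMSE, correction on.
#' @param bin_width Bin width in mm-equivalent (default 2.5).
#' @param min_count Minimum volumes per bin and condition (default 5).
#' @return An object of class `binned_summary`: data frame with
#'   `bin_low`, `bin_high`, `n_off`, `n_on`, `mean_rmse_off`,
#'   `mean_rmse_on`, `percent_reduction`, `se_percent`. Empty (with a
#'   warning) if no bin qualifies.
#' @export
binned_percent_reduction <- function(mpw_off, rmse_off, mpw_on, rmse_on,
                                     bin_width = 2.5, min_count = 5) {
  if (any(c(mpw_off, mpw_on) < 0)) stop("metric values must be nonnegative")
  top <- max(mpw_off, mpw_on)
  edges <- seq(0, top + bin_width, by = bin_width)
  b_off <- findInterval(mpw_off, edges, rightmost.closed = FALSE)
  b_on <- findInterval(mpw_on, edges, rightmost.closed = FALSE)
  rows <- list()
  for (b in seq_len(length(edges) - 1)) {
    i_off <- b_off == b; i_on <- b_on == b
    n_off <- sum(i_off); n_on <- sum(i_on)
    if (n_off < min_count || n_on < min_count) next
    m_off <- mean(rmse_off[i_off]); m_on <- mean(rmse_on[i_on])
    if (m_off <= 0) next
    se_off <- stats::sd(rmse_off[i_off]) / sqrt(n_off)
    se_on <- stats::sd(rmse_on[i_on]) / sqrt(n_on)
    pct <- (m_off - m_on) / m_off * 100
    se_pct <- 100 * sqrt((se_on / m_off)^2 + (m_on * se_off / m_off^2)^2)
    rows[[length(rows) + 1]] <-
      data.frame(bin_low = edges[b], bin_high = edges[b + 1],
                 n_off = n_off, n_on = n_on,
                 mean_rmse_off = m_off, mean_rmse_on = m_on,
                 percent_reduction = pct, se_percent = se_pct)
  }
  if (length(rows) == 0) {
    warning("no bin has at least ", min_count,
            " volumes in both conditions")
    out <- data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      n_off = integer(0), n_on = integer(0),
                      mean_rmse_off = numeric(0), mean_rmse_on = numeric(0),
                      percent_reduction = numeric(0),
                      se_percent = numeric(0))
  } else out <- do.call(rbind, rows)
  class(out) <- c("binned_summary", "data.frame")
  out
}
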
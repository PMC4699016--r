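## Time-series and association statistics for orientation observables:
## autocorrelation functions, Pearson correlation with the t-transform
## p-value, Fisher-z confidence intervals and the interval-overlap
## significance check.

#' Autocorrelation function of an orientation observable
#'
#' Biased (full-series-variance normalised) estimator
#' acf(tau) = sum_t (x_t - xbar)(x_{t+tau} - xbar) / sum_t (x_t - xbar)^2,
#' the standard choice in trajectory analysis, computed via
#' [stats::acf()]. acf(0) = 1 for any non-constant series.
#'
#' @param x numeric series, length >= 2.
#' @param maxLag largest lag in frames (< length(x)).
#' @param timeStepNs optional effective time per frame in ns; when given,
#'   the returned lag axis is also reported in ns.
#' @return data.frame with columns lag, acf and (optionally) lag_ns.
#' @export
acfSeries <- function(x, maxLag, timeStepNs = NULL) {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("series too short")
    if (maxLag >= length(x)) stop("maxLag must be < length(x)")
    if (sd(x) == 0) stop("constant series has no autocorrelation")
    a <- acf(x, lag.max = maxLag, plot = FALSE, demean = TRUE,
             type = "correlation")
    out <- data.frame(lag = as.integer(a$lag[, 1, 1]),
                      acf = as.numeric(a$acf[, 1, 1]))
    if (!is.null(timeStepNs)) out$lag_ns <- out$lag * timeStepNs
    out
}

#' Pearson correlation with t-transform p-value and Fisher-z CI
#'
#' Sample Pearson correlation of two equal-length series, the two-sided
#' p-value from t = rho sqrt((n-2)/(1-rho^2)) with n-2 degrees of
#' freedom, and the Fisher-z confidence interval at `ciLevel`.
#'
#' @param x,y numeric series of equal length >= 3.
#' @param ciLevel confidence level (default 0.95).
#' @return list with elements rho, n, p, ciLevel, ciLow, ciHigh.
#' @export
pearsonCorrelation <- function(x, y, ciLevel = 0.95) {
    x <- as.numeric(x); y <- as.numeric(y)
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 3L) stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input series")
    rho <- cor(x, y)
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    ci <- if (n >= 4 && abs(rho) < 1) fisherCI(rho, n, ciLevel)
          else c(rho, rho)
    list(rho = rho, n = n, p = p, ciLevel = ciLevel,
         ciLow = ci[1], ciHigh = ci[2])
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' z = atanh(rho) is approximately normal with standard error
#' 1/sqrt(n-3); the interval is tanh(z -/+ z_crit/sqrt(n-3)) with z_crit
#' the normal quantile at (1+level)/2.
#'
#' @param rho correlation, |rho| <= 1 (|rho| = 1 returns the degenerate
#'   interval {rho}).
#' @param n number of paired observations, >= 4.
#' @param level confidence level (default 0.95).
#' @return numeric c(ciLow, ciHigh).
#' @export
fisherCI <- function(rho, n, level = 0.95) {
    if (abs(rho) > 1) stop("|rho| must be <= 1")
    if (abs(rho) == 1) return(c(rho, rho))
    if (n < 4) stop("need n >= 4 for a Fisher-z interval")
    z <- atanh(rho)
    hw <- qnorm((1 + level) / 2) / sqrt(n - 3)
    c(tanh(z - hw), tanh(z + hw))
}

#' Do two confidence intervals overlap?
#'
#' Boundary touching counts as overlap (the conservative convention for
#' arguing a significant difference from non-overlap).
#'
#' @param a,b numeric length-2 ordered intervals.
#' @return TRUE iff max(lows) <= min(highs).
#' @export
ciOverlap <- function(a, b) {
    stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
    max(a[1], b[1]) <= min(a[2], b[2])
}
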
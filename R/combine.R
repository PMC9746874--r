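#' Fisher combination of component p-values
#'
#' Combines the valid component p-values of one gene into
#' `Q = -2 * sum(log(L))` (natural logarithm). Undefined components must be
#' dropped (or set to 1, which contributes nothing) by the caller before
#' combination.
#'
#' @param L Numeric vector of p-values in (0, 1].
#' @return The combined statistic Q (>= 0).
#' @examples
#' combine_fisher(c(0.05, 0.05, 0.05))
#' @export
combine_fisher <- function(L) {
  if (length(L) == 0) stop("at least one component p-value is required")
  if (any(L <= 0) || any(L > 1))
    stop("component p-values must lie in (0, 1]; clamp before combining")
  -2 * sum(log(L))
}

#' Calibrate the chi-square degrees of freedom of the combined statistic
#'
#' Under independence of the three components, Q would follow chi-square
#' with 6 degrees of freedom; in practice the components share the same
#' cells and are positively dependent, which shrinks the effective df.
#' This fits a single genome-wide df by maximising the chi-square
#' likelihood over df in \[2, 6\] on the observed Q values.
#'
#' By default the fit uses the central 90% of Q values (a trimmed,
#' properly truncated likelihood) so that the minority of genuinely DE
#' genes -- which inflate the upper tail -- do not drag the null
#' calibration. Fewer than 50 usable values triggers a fall back to the
#' independence value 6 with a warning.
#'
#' @param Q_values Numeric vector of combined statistics from genes whose
#'   three components were all computable.
#' @param method `"mle"` (default) or `"fixed6"` to bypass the fit.
#' @param trim Central fraction of the Q distribution used by the fit.
#' @param df_range Search interval for the df parameter.
#' @return The fitted degrees of freedom (scalar).
#' @examples
#' set.seed(1)
#' estimate_df(rchisq(5000, df = 4))
#' @export
estimate_df <- function(Q_values, method = c("mle", "fixed6"), trim = 0.90,
                        df_range = c(2, 6)) {
  method <- match.arg(method)
  if (method == "fixed6") return(6)
  Q_values <- Q_values[is.finite(Q_values)]
  if (length(Q_values) < 50) {
    warning("fewer than 50 usable Q values; falling back to df = 6")
    return(6)
  }
  tail_frac <- (1 - trim) / 2
  bounds <- quantile(Q_values, c(tail_frac, 1 - tail_frac), names = FALSE)
  keep <- Q_values >= bounds[1] & Q_values <= bounds[2]
  Qk <- pmax(Q_values[keep], .Machine$double.xmin)
  if (length(Qk) < 50 || bounds[1] >= bounds[2]) {
    warning("degenerate Q distribution; falling back to df = 6")
    return(6)
  }
  # truncated chi-square log-likelihood: trimming must enter the density
  # normalisation or the estimate would be biased toward small df
  negll <- function(df) {
    zmass <- pchisq(bounds[2], df) - pchisq(bounds[1], df)
    if (zmass <= 0) return(Inf)
    -(sum(dchisq(Qk, df, log = TRUE)) - length(Qk) * log(zmass))
  }
  optimize(negll, interval = df_range)$minimum
}

#' Convert a combined statistic to a p-value
#'
#' Upper-tail chi-square probability of Q at a (possibly non-integer)
#' degrees of freedom, floored at `1e-300`.
#'
#' @param Q Combined statistic(s), >= 0.
#' @param fitted_df Degrees of freedom (> 0); recycled against `Q`.
#' @return p-value(s) in (0, 1].
#' @examples
#' q_to_pvalue(12.59, 6)
#' @export
q_to_pvalue <- function(Q, fitted_df) {
  if (any(Q < 0)) stop("Q must be non-negative")
  if (any(fitted_df <= 0)) stop("fitted_df must be positive")
  .clamp_p(pchisq(Q, df = fitted_df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across genes; a thin wrapper around
#' [stats::p.adjust()] kept as an explicit step of the HEART pipeline.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}
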
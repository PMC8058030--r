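#' Paired TOST equivalence test
#'
#' Two one-sided t-tests of the per-patient paired differences (in percent)
#' against a symmetric equivalence interval (-margin, margin). The lower
#' test rejects H0: mean <= -margin with
#' \eqn{t_L = (\bar d + m) / (s/\sqrt{n})}; the upper test rejects
#' H0: mean >= margin with \eqn{t_U = (\bar d - m) / (s/\sqrt{n})};
#' both use n - 1 degrees of freedom. Equivalence is declared iff both
#' one-sided p-values fall below alpha. The conventional TOST interval at
#' alpha = 0.05 is the 90\% CI; both the 90\% and 95\% CIs are reported.
#'
#' @param differences numeric vector of paired relative differences (\%),
#'   n >= 3.
#' @param margin equivalence half-width in \% (default 1).
#' @param alpha one-sided significance level (default 0.05).
#' @return a [TOSTResult].
#' @examples
#' set.seed(1)
#' tostPaired(rnorm(44, 0, 0.2), margin = 1)
#' @export
tostPaired <- function(differences, margin = 1, alpha = 0.05) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 3L) stop("TOST needs at least 3 paired differences")
  if (margin <= 0) stop("margin must be positive")
  m <- mean(differences)
  s <- sd(differences)
  df <- n - 1L
  se <- s / sqrt(n)
  degenerate <- s == 0 && (m == margin || m == -margin)
  if (s == 0 && !degenerate) {
    # all differences identical strictly inside or outside the interval
    tL <- if (m > -margin) Inf else -Inf
    tU <- if (m < margin) -Inf else Inf
  } else if (degenerate) {
    tL <- NaN; tU <- NaN
  } else {
    tL <- (m + margin) / se
    tU <- (m - margin) / se
  }
  pL <- if (is.nan(tL)) NaN else pt(tL, df, lower.tail = FALSE)
  pU <- if (is.nan(tU)) NaN else pt(tU, df, lower.tail = TRUE)
  ciHalf <- function(level) {
    if (s == 0) 0 else qt(1 - (1 - level) / 2, df) * se
  }
  equivalent <- !degenerate && !is.nan(pL) && max(pL, pU) < alpha
  new("TOSTResult", n = as.integer(n), meanDiff = m, sdDiff = s,
      margin = margin, alpha = alpha,
      tLower = tL, tUpper = tU, pLower = pL, pUpper = pU,
      ci90 = m + c(-1, 1) * ciHalf(0.90),
      ci95 = m + c(-1, 1) * ciHalf(0.95),
      equivalent = equivalent, degenerate = degenerate)
}

#' @rdname TOSTResult-class
#' @export
setMethod("isEquivalent", "TOSTResult", function(x) x@equivalent)

setMethod("show", "TOSTResult", function(object) {
  cat(sprintf("TOST (margin +/-%g%%, alpha %.2f), n = %d\n",
              object@margin, object@alpha, object@n))
  cat(sprintf("  mean diff %.3f%% (sd %.3f), 90%% CI [%.3f, %.3f]\n",
              object@meanDiff, object@sdDiff, object@ci90[1], object@ci90[2]))
  if (object@degenerate) {
    cat("  degenerate: zero variance with mean on a margin; p undefined\n")
  } else {
    cat(sprintf("  p_lower %.3g, p_upper %.3g -> %s\n", object@pLower,
                object@pUpper,
                if (object@equivalent) "EQUIVALENT" else "not equivalent"))
  }
})

#' Flag outliers by the interquartile-range rule
#'
#' Values outside [Q1 - k IQR, Q3 + k IQR] are flagged (default k = 1.5,
#' the box-plot whisker rule). Quartiles use linear interpolation between
#' order statistics (type 7, the R default).
#'
#' @param values numeric vector, n >= 4.
#' @param k IQR multiplier (default 1.5).
#' @return logical vector of the same length; TRUE marks an outlier.
#' @export
flagOutliers <- function(values, k = 1.5) {
  if (k <= 0) stop("k must be positive")
  if (length(values) < 4L) stop("need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Cohort summary table of DVH-parameter differences
#'
#' Aggregates [comparePlans()] rows from several patients into one row per
#' structure/parameter: mean and sd of the relative (\%) and absolute (Gy)
#' differences over the included volumes.
#'
#' @param comparisons data.frame rbind-ed from [comparePlans()] outputs (one
#'   per patient), with included/excluded rows.
#' @return data.frame: structure, parameter, mean_rel_pct, sd_rel_pct,
#'   mean_abs_gy, sd_abs_gy, n_included.
#' @export
cohortTable <- function(comparisons) {
  inc <- comparisons[comparisons$included & !is.na(comparisons$parameter), ,
                     drop = FALSE]
  if (nrow(inc) == 0L)
    return(data.frame(structure = character(), parameter = character(),
                      mean_rel_pct = numeric(), sd_rel_pct = numeric(),
                      mean_abs_gy = numeric(), sd_abs_gy = numeric(),
                      n_included = integer(), stringsAsFactors = FALSE))
  key <- interaction(inc$structure, inc$parameter, drop = TRUE)
  rows <- lapply(split(inc, key), function(g) {
    data.frame(structure = g$structure[1], parameter = g$parameter[1],
               mean_rel_pct = mean(g$rel_diff_pct),
               sd_rel_pct = if (nrow(g) > 1) sd(g$rel_diff_pct) else 0,
               mean_abs_gy = mean(g$abs_diff_gy),
               sd_abs_gy = if (nrow(g) > 1) sd(g$abs_diff_gy) else 0,
               n_included = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$structure, out$parameter), ]
  rownames(out) <- NULL
  out
}
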
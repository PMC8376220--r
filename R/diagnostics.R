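# Weak-instrument and pleiotropy diagnostics: mean F statistic and its
# implied IVW dilution, I^2_GX and the implied Egger dilution, and the
# weak-instrument-robust "exact" Q heterogeneity statistic with per-SNP
# outlier flagging.

#' Mean F statistic of the first-stage associations
#'
#' \eqn{\bar F = k^{-1}\sum_j \hat\beta^2_{XGj}/\sigma^2_{XGj}}: the mean of
#' the per-SNP instrument-strength statistics.  Under weak instruments the
#' IVW collider-correction slope is diluted towards zero by the factor
#' \eqn{(\bar F - 1)/\bar F}.  The bare sum over SNPs is available as
#' [sum_f()].
#'
#' @param summary A `collider_summary` or `standard_summary`.
#' @return The mean F statistic (scalar).
#' @export
mean_f <- function(summary) {
  xy <- mr_xy(summary)
  if (any(xy$sx <= 0) || any(!is.finite(xy$sx))) {
    stop("first-stage standard errors must be positive and finite", call. = FALSE)
  }
  mean(xy$x^2 / xy$sx^2)
}

#' @rdname mean_f
#' @export
sum_f <- function(summary) {
  xy <- mr_xy(summary)
  if (any(xy$sx <= 0) || any(!is.finite(xy$sx))) {
    stop("first-stage standard errors must be positive and finite", call. = FALSE)
  }
  sum(xy$x^2 / xy$sx^2)
}

#' I-squared-GX statistic for MR-Egger dilution
#'
#' \eqn{I^2_{GX} = (Q_{GX} - (k-1))/Q_{GX}} with
#' \eqn{Q_{GX} = \sum_j (\hat\beta_{XGj} - \bar\beta_{XGj})^2 /
#' \sigma^2_{XGj}}, quantifying the heterogeneity of the first-stage
#' estimates about their inverse-variance-weighted mean.  The expected
#' dilution of the MR-Egger collider-correction slope under measurement
#' error in the SNP-exposure associations is the factor \eqn{I^2_{GX}}.
#' Negative values are floored at 0 (the raw value is returned in the
#' `"raw"` attribute).
#'
#' @param summary A `collider_summary` or `standard_summary`.
#' @param weighted_mean Center at the inverse-variance-weighted mean
#'   (default) or the unweighted mean.
#' @return \eqn{I^2_{GX}} in `[0, 1]`.
#' @export
isq_gx <- function(summary, weighted_mean = TRUE) {
  xy <- mr_xy(summary)
  if (xy$k < 2) stop("I2_GX requires at least 2 SNPs", call. = FALSE)
  if (any(xy$sx <= 0) || any(!is.finite(xy$sx))) {
    stop("first-stage standard errors must be positive and finite", call. = FALSE)
  }
  w <- 1 / xy$sx^2
  ctr <- if (weighted_mean) weighted.mean(xy$x, w) else mean(xy$x)
  qgx <- sum((xy$x - ctr)^2 * w)
  raw <- (qgx - (xy$k - 1)) / qgx
  structure(max(0, raw), raw = raw, qgx = qgx)
}

# Exact-Q objective: weighted sum of squared profile residuals at tau2 = 0.
# Shared verbatim with the LIML estimator (liml_raps_slope(z = 0)), whose
# minimized objective *is* the exact Q statistic.
exact_q_objective <- function(s, xy) sum(profile_resid(s, 0, xy)^2)

#' Exact Q statistic for pleiotropy with weak instruments
#'
#' The weighted heterogeneity statistic
#' \eqn{Q(s) = \sum_j (\hat\alpha^*_j - s\hat\beta_{XGj})^2 /
#' (s^2\sigma^2_{XGj} + \sigma^2_{\alpha^*_j})}, profile-minimized over the
#' slope `s` when none is supplied (the minimizing `s` is the LIML
#' estimate, and the minimized value follows a chi-squared distribution
#' with k - 1 degrees of freedom when no pleiotropy is present).  Because
#' the denominator carries the first-stage variance, the test keeps its
#' size under weak instruments.  Per-SNP contributions at the (supplied or
#' minimizing) slope support outlier detection via [flag_outliers()].
#'
#' @param summary A `collider_summary` (or `standard_summary`).
#' @param slope Optional slope at which to evaluate Q; default
#'   profile-minimized.
#' @return List of class `exact_q` with `q`, `df`, `p_value`, `slope`,
#'   `per_snp` (length-k contributions summing to `q`), `profiled`.
#' @export
exact_q <- function(summary, slope = NULL) {
  xy <- mr_xy(summary)
  if (xy$k < 2) stop("exact Q requires at least 2 SNPs", call. = FALSE)
  profiled <- is.null(slope)
  if (profiled) {
    fit <- liml_raps_slope(summary, z = 0)
    if (!fit$converged) {
      stop("profile minimization of the exact Q objective did not converge ",
           "inside the search bracket (IVW slope +/- 10 SE)", call. = FALSE)
    }
    slope <- fit$slope
  }
  contrib <- profile_resid(slope, 0, xy)^2
  q <- sum(contrib)
  df <- xy$k - 1L
  structure(list(q = q, df = df,
                 p_value = pchisq(q, df, lower.tail = FALSE),
                 slope = slope, per_snp = setNames(contrib, names_of(summary)),
                 profiled = profiled),
            class = "exact_q")
}

names_of <- function(summary) summary$snp_ids %||% paste0("g", seq_len(mr_xy(summary)$k))

#' @export
print.exact_q <- function(x, ...) {
  cat("<exact_q> Q =", signif(x$q, 5), " df =", x$df,
      " p =", signif(x$p_value, 3),
      if (x$profiled) " (profile-minimized)" else "", "\n")
  invisible(x)
}

#' Flag outlying SNPs from per-SNP Q contributions
#'
#' A SNP is flagged when its contribution to the exact Q statistic exceeds
#' the upper chi-squared(1) quantile at the Bonferroni-corrected level
#' `level / k`.
#'
#' @param per_snp_q Named vector of per-SNP contributions (from
#'   [exact_q()]).
#' @param k Number of SNPs tested (defaults to `length(per_snp_q)`).
#' @param level Family-wise level before correction (default 0.05).
#' @return Character vector of flagged SNP ids (possibly empty).
#' @export
flag_outliers <- function(per_snp_q, k = length(per_snp_q), level = 0.05) {
  if (is.null(names(per_snp_q))) {
    names(per_snp_q) <- paste0("g", seq_along(per_snp_q))
  }
  thr <- qchisq(level / k, df = 1, lower.tail = FALSE)
  names(per_snp_q)[per_snp_q > thr]
}

#' Predicted weak-instrument dilution factor
#'
#' Returns the factor by which the unadjusted collider-correction slope is
#' expected to be diluted towards zero: \eqn{(\bar F - 1)/\bar F} for IVW
#' (and approximately for LAD, which is somewhat more vulnerable), and
#' \eqn{I^2_{GX}} for MR-Egger.
#'
#' @param summary A `collider_summary` or `standard_summary`.
#' @param method `"ivw"`, `"lad"` or `"egger"`.
#' @return Dilution factor in `[0, 1]`.
#' @export
predicted_dilution <- function(summary, method = c("ivw", "lad", "egger")) {
  method <- match.arg(method)
  if (method == "egger") return(as.numeric(isq_gx(summary)))
  fbar <- mean_f(summary)
  if (fbar < 1) {
    warning("mean F below 1; returning a dilution factor of 0")
    return(0)
  }
  (fbar - 1) / fbar
}

#' Combined diagnostic report
#'
#' @param summary A `collider_summary`.
#' @param level Outlier flagging level before Bonferroni correction.
#' @return Object of class `diagnostic_report` with `mean_f`, `sum_f`,
#'   `i2gx`, the exact-Q results, flagged `outliers` and the predicted
#'   dilution factors.
#' @export
diagnostic_report <- function(summary, level = 0.05) {
  q <- exact_q(summary)
  i2 <- isq_gx(summary)
  structure(list(
    mean_f = mean_f(summary), sum_f = sum_f(summary),
    i2gx = as.numeric(i2), i2gx_raw = attr(i2, "raw"),
    q_exact = q$q, q_df = q$df, q_p = q$p_value, q_slope = q$slope,
    per_snp_q = q$per_snp,
    outliers = flag_outliers(q$per_snp, level = level),
    dilution_ivw = predicted_dilution(summary, "ivw"),
    dilution_egger = as.numeric(i2),
    k = mr_xy(summary)$k
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("<diagnostic_report>\n",
      " mean F     =", signif(x$mean_f, 4),
      " (IVW dilution factor ", signif(x$dilution_ivw, 3), ")\n",
      " I2_GX      =", signif(x$i2gx, 3),
      " (Egger dilution factor)\n",
      " exact Q    =", signif(x$q_exact, 5), " on", x$q_df, "df, p =",
      signif(x$q_p, 3), "\n",
      " outliers   =", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
                       else "none", "\n")
  invisible(x)
}
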
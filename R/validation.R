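# The method-agreement battery: Lin's concordance correlation, Bland-Altman
# bias and limits of agreement with a proportional-bias test, pure and
# percent error, the identity-line linearity test, paired comparison, and
# replicate reproducibility (TEM). Conventions: CCC uses population (1/n)
# moments (Lin 1989); Bland-Altman uses the sample (n-1) SD with a fixed
# 1.96 multiplier; all tests are two-sided.

check_paired <- function(x, y, min_n = 3L) {
  assert_that(is.numeric(x) && is.numeric(y), "inputs must be numeric vectors")
  assert_that(length(x) == length(y),
              sprintf("length mismatch: %d vs %d", length(x), length(y)))
  assert_that(length(x) >= min_n,
              sprintf("need at least %d pairs, got %d", min_n, length(x)))
  assert_that(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  invisible(TRUE)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (divide-by-n) moments. Symmetric in its arguments and bounded by the
#' Pearson correlation in absolute value.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return A scalar in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  check_paired(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  assert_that(denom > 0, "zero denominator: inputs have no variance or offset")
  2 * sxy / denom
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = pred - ref`: bias is `mean(d)`, the limits of agreement
#' are `bias +- 1.96 * sd(d)` (sample SD), and proportional bias is the OLS
#' slope of `d` on the pairwise means `(pred + ref) / 2` with its two-sided
#' p-value.
#'
#' @param pred,ref Paired numeric vectors (length >= 3).
#' @return A list: `bias`, `loa_low`, `loa_high`,
#'   `proportional_bias_slope`, `proportional_bias_p`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pred, ref) {
  check_paired(pred, ref)
  n <- length(pred)
  d <- pred - ref
  m <- (pred + ref) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  mm <- m - mean(m)
  sxx <- sum(mm^2)
  if (sxx > 0) {
    slope <- sum(mm * d) / sxx
    resid <- d - mean(d) - slope * mm
    df <- n - 2L
    s2 <- sum(resid^2) / df
    se <- sqrt(s2 / sxx)
    pval <- if (se > 0) 2 * stats::pt(-abs(slope / se), df) else as.numeric(slope == 0)
  } else {
    slope <- 0; pval <- NA_real_
  }
  list(bias = bias, loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       proportional_bias_slope = slope, proportional_bias_p = pval,
       sd_diff = sdd, n = n)
}

#' Pure error and percent error
#'
#' Group-level accuracy relative to the reference method. The default
#' (`mode = "group_mean"`) is the absolute difference of group means,
#' `|mean(pred) - mean(ref)|`; `mode = "rmse"` gives the paired
#' root-mean-square error. Percent error is the pure error as a percent of
#' the reference mean.
#'
#' @param pred,ref Paired numeric vectors; `ref` strictly positive.
#' @param mode `"group_mean"` or `"rmse"`.
#' @return A list: `ape` (kg), `percent_error` (%).
#' @export
error_metrics <- function(pred, ref, mode = c("group_mean", "rmse")) {
  mode <- match.arg(mode)
  check_paired(pred, ref, min_n = 1L)
  assert_that(all(ref > 0), "reference values must be positive")
  ape <- switch(mode,
                group_mean = abs(mean(pred) - mean(ref)),
                rmse = sqrt(mean((pred - ref)^2)))
  list(ape = ape, percent_error = 100 * ape / mean(ref))
}

#' Identity-line linearity test
#'
#' OLS regression of predictions on reference values, with t-tests of the
#' null hypotheses slope = 1 and intercept = 0 (n - 2 df), plus the
#' standard error of estimate (residual SD) and R-squared.
#'
#' @param pred,ref Paired numeric vectors (length >= 3); `ref` must vary.
#' @return A list: `slope`, `intercept`, `see`, `slope_eq1_p`,
#'   `intercept_eq0_p`, `r2`.
#' @export
linearity_test <- function(pred, ref) {
  check_paired(pred, ref)
  n <- length(pred)
  rc <- ref - mean(ref)
  sxx <- sum(rc^2)
  assert_that(sxx > 0, "reference values have no variance")
  slope <- sum(rc * pred) / sxx
  intercept <- mean(pred) - slope * mean(ref)
  resid <- pred - intercept - slope * ref
  df <- n - 2L
  s2 <- sum(resid^2) / df
  see <- sqrt(s2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mean(ref)^2 / sxx))
  slope_p <- if (se_slope > 0) 2 * stats::pt(-abs((slope - 1) / se_slope), df)
             else as.numeric(slope == 1)
  int_p <- if (se_int > 0) 2 * stats::pt(-abs(intercept / se_int), df)
           else as.numeric(intercept == 0)
  sst <- sum((pred - mean(pred))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
  list(slope = slope, intercept = intercept, see = see,
       slope_eq1_p = slope_p, intercept_eq0_p = int_p, r2 = r2)
}

#' Paired comparison of two measurement sets
#'
#' Standard paired t-test (two-sided, n - 1 df). When the differences have
#' zero variance the comparison is degenerate: `p` is 1 for exact equality
#' and 0 for a constant nonzero difference, with `degenerate = TRUE`.
#'
#' @param x,y Paired numeric vectors (length >= 2).
#' @return A list: `mean_diff`, `p`, `t`, `df`, `degenerate`.
#' @export
paired_comparison <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(mean_diff = md, p = as.numeric(md == 0), t = NA_real_,
                df = n - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(mean_diff = md, p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Replicate reproducibility (technical error of measurement)
#'
#' Precision of repeated measurements on repositioned subjects:
#' `TEM = sqrt(sum(d^2) / (2 n))` over paired replicates, the coefficient
#' of variation `100 * TEM / grand mean`, the mean difference and its SD,
#' and the replicate agreement (R-squared, concordance, paired p).
#'
#' @param test1,test2 Paired replicate measurements (length >= 3).
#' @return An object of class `reproducibility_report`.
#' @export
reproducibility <- function(test1, test2) {
  check_paired(test1, test2)
  n <- length(test1)
  d <- test1 - test2
  tem <- sqrt(sum(d^2) / (2 * n))
  grand <- mean(c(test1, test2))
  pc <- paired_comparison(test1, test2)
  varying <- stats::sd(test1) > 0 && stats::sd(test2) > 0
  structure(list(n = n, mean_test1 = mean(test1), mean_test2 = mean(test2),
                 mean_diff = mean(d), sd_diff = stats::sd(d),
                 cv_percent = 100 * tem / grand, tem = tem,
                 r2 = if (varying) stats::cor(test1, test2)^2 else NA_real_,
                 ccc = lin_ccc(test1, test2), p_diff = pc$p),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("<reproducibility_report> n = %d\n", x$n))
  cat(sprintf("  test1 %.2f, test2 %.2f kg; mean diff %.3f (SD %.3f), p = %.3f\n",
              x$mean_test1, x$mean_test2, x$mean_diff, x$sd_diff, x$p_diff))
  cat(sprintf("  TEM %.4f kg, CV %.3f%%, R2 %.4f, CCC %.4f\n",
              x$tem, x$cv_percent, x$r2, x$ccc))
  invisible(x)
}

#' Full agreement report between predicted and reference values
#'
#' Assembles the complete statistic battery: group means with a paired
#' t-test, R-squared and Lin's concordance, pure and percent error, the
#' identity-line regression with slope/intercept tests and SEE, and the
#' Bland-Altman bias, limits of agreement and proportional-bias test.
#'
#' @param pred,ref Paired numeric vectors (length >= 3).
#' @param ape_mode Pure-error definition, see [error_metrics()].
#' @return An object of class `agreement_report`.
#' @export
full_report <- function(pred, ref, ape_mode = c("group_mean", "rmse")) {
  ape_mode <- match.arg(ape_mode)
  check_paired(pred, ref)
  lt <- linearity_test(pred, ref)
  ba <- bland_altman(pred, ref)
  em <- error_metrics(pred, ref, mode = ape_mode)
  pc <- paired_comparison(pred, ref)
  structure(list(n = length(pred), mean_pred = mean(pred), mean_ref = mean(ref),
                 paired_t_p = pc$p, r2 = lt$r2, ccc = lin_ccc(pred, ref),
                 see = lt$see, ape = em$ape, percent_error = em$percent_error,
                 slope = lt$slope, intercept = lt$intercept,
                 slope_eq1_p = lt$slope_eq1_p, intercept_eq0_p = lt$intercept_eq0_p,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 proportional_bias_slope = ba$proportional_bias_slope,
                 proportional_bias_p = ba$proportional_bias_p),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  predicted %.2f vs reference %.2f kg (paired p = %.3f)\n",
              x$mean_pred, x$mean_ref, x$paired_t_p))
  cat(sprintf("  R2 %.3f, CCC %.3f, SEE %.2f kg, APE %.3f kg (%.2f%%)\n",
              x$r2, x$ccc, x$see, x$ape, x$percent_error))
  cat(sprintf("  slope %.3f (p vs 1 = %.3f), intercept %.2f (p vs 0 = %.3f)\n",
              x$slope, x$slope_eq1_p, x$intercept, x$intercept_eq0_p))
  cat(sprintf("  bias %.3f kg, LOA [%.2f, %.2f], proportional slope %.3f (p = %.3f)\n",
              x$bias, x$loa_low, x$loa_high, x$proportional_bias_slope,
              x$proportional_bias_p))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param pred,ref Paired numeric vectors.
#' @param main Plot title.
#' @return Invisibly, the [bland_altman()] list.
#' @export
plot_bland_altman <- function(pred, ref, main = "Bland-Altman") {
  ba <- bland_altman(pred, ref)
  m <- (pred + ref) / 2
  d <- pred - ref
  graphics::plot(m, d, pch = 19, col = "grey30",
                 xlab = "Mean of methods (kg)",
                 ylab = "Predicted - reference (kg)", main = main)
  graphics::abline(h = ba$bias, col = "blue", lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "red", lty = 2)
  graphics::abline(stats::lm(d ~ m), col = "darkgreen", lty = 3)
  invisible(ba)
}

#' Identity-line scatter plot
#'
#' @param pred,ref Paired numeric vectors.
#' @param main Plot title.
#' @return Invisibly, the [linearity_test()] list.
#' @export
plot_identity <- function(pred, ref, main = "Predicted vs reference") {
  lt <- linearity_test(pred, ref)
  rng <- range(c(pred, ref))
  graphics::plot(ref, pred, pch = 19, col = "grey30", xlim = rng, ylim = rng,
                 xlab = "Reference fat mass (kg)",
                 ylab = "Predicted fat mass (kg)", main = main)
  graphics::abline(0, 1, col = "grey60", lwd = 1)
  graphics::abline(lt$intercept, lt$slope, col = "blue", lwd = 2)
  invisible(lt)
}
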
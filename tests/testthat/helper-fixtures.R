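# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain two-pass formula evaluations, independent of
# the package implementations they check.

fixture_body <- function(gender = "female", fm_total = 22.8,
                         fm_abdominal = 2.45, stature = 163.6,
                         weight = 66.8, id = "FIX01") {
  body_params(id, gender, stature = stature, weight = weight,
              fm_total = fm_total, fm_abdominal = fm_abdominal)
}

small_spec <- function(mp = 0.5, jitter = 0, seed = 1L) {
  render_spec(megapixels = mp, pose_jitter = jitter, seed = seed)
}

# silhouette from a rendered image through the conditioning path
conditioned <- function(params, spec) {
  binarize(render_silhouette(params, spec)$image, threshold = 0.5,
           strict = FALSE)
}

# hand-built virtual frame for arithmetic fixtures
manual_frame <- function(top, bottom, left, right) {
  structure(list(top_row = top, bottom_row = bottom, left_col = left,
                 right_col = right, span = bottom - top),
            class = "virtual_frame")
}

# --- brute-force statistic oracles ---------------------------------------

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2
    sy2 <- sy2 + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  (2 * sxy / n) / (sx2 / n + sy2 / n + (mx - my)^2)
}

oracle_bland_altman <- function(pred, ref) {
  n <- length(pred)
  d <- pred - ref
  m <- (pred + ref) / 2
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  mbar <- sum(m) / n
  sxx <- sum((m - mbar)^2)
  slope <- sum((m - mbar) * (d - bias)) / sxx
  resid <- (d - bias) - slope * (m - mbar)
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  p <- 2 * stats::pt(-abs(slope / se), n - 2)
  list(bias = bias, loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       slope = slope, p = p)
}

oracle_linearity <- function(pred, ref) {
  n <- length(pred)
  mr <- sum(ref) / n; mp <- sum(pred) / n
  sxx <- sum((ref - mr)^2)
  slope <- sum((ref - mr) * (pred - mp)) / sxx
  intercept <- mp - slope * mr
  resid <- pred - intercept - slope * ref
  s2 <- sum(resid^2) / (n - 2)
  se_b <- sqrt(s2 / sxx)
  se_a <- sqrt(s2 * (1 / n + mr^2 / sxx))
  list(slope = slope, intercept = intercept, see = sqrt(s2),
       slope_p = 2 * stats::pt(-abs((slope - 1) / se_b), n - 2),
       int_p = 2 * stats::pt(-abs(intercept / se_a), n - 2),
       r2 = 1 - sum(resid^2) / sum((pred - mp)^2))
}

oracle_paired_p <- function(x, y) {
  d <- x - y
  n <- length(d)
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  tt <- md / (sdd / sqrt(n))
  2 * stats::pt(-abs(tt), n - 1)
}

oracle_tem <- function(t1, t2) {
  d <- t1 - t2
  sqrt(sum(d^2) / (2 * length(d)))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
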
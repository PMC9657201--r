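# Synthetic cohort generation: gender-specific anthropometric marginals with
# a Gaussian copula coupling fat mass, abdominal fat mass and body weight,
# plus a linear fat-mass -> sagittal-depth mapping that drives rendering.

#' Default cohort distribution parameters
#'
#' Per-gender marginals (mean, SD, observed min/max) for stature, weight,
#' total fat mass and abdominal (L2-5) fat mass, matching the validation
#' cohorts this package emulates. Fat masses follow truncated lognormal laws
#' (positive, right-skewed) coupled on the log scale; stature and weight are
#' truncated normal. All marginals are moment-matched after truncation.
#'
#' @param segment_noise_sd SD (cm) of the additive per-segment depth noise,
#'   i.e. inter-individual shape variation not explained by fat mass. The
#'   default 0.5 cm puts the single-site inverse prediction error on the
#'   2.3 kg standard-error-of-estimate scale typical of 2D photograph models.
#' @param fm_log_correlation Gaussian-copula correlation between total and
#'   abdominal fat mass.
#' @param weight_fm_correlation Copula correlation between body weight and
#'   total fat mass (weight is carried for realism but never modeled).
#' @return A list with components `female`, `male` (each a list of
#'   `stature`, `weight`, `fm_total`, `fm_abdominal` marginal vectors
#'   `c(mean, sd, min, max)`) and the correlation/noise settings.
#' @export
cohort_config <- function(segment_noise_sd = 0.5,
                          fm_log_correlation = 0.9,
                          weight_fm_correlation = 0.75) {
  assert_that(is_scalar(segment_noise_sd) && segment_noise_sd >= 0,
              "segment_noise_sd must be a nonnegative number")
  assert_that(is_scalar(fm_log_correlation) && abs(fm_log_correlation) < 1,
              "fm_log_correlation must be in (-1, 1)")
  assert_that(is_scalar(weight_fm_correlation) && abs(weight_fm_correlation) < 1,
              "weight_fm_correlation must be in (-1, 1)")
  list(
    female = list(
      stature      = c(mean = 163.6, sd = 6.7,  min = 151,  max = 183),
      weight       = c(mean = 66.8,  sd = 13.1, min = 42,   max = 103.6),
      fm_total     = c(mean = 22.8,  sd = 10.9, min = 8.6,  max = 59.2),
      fm_abdominal = c(mean = 2.45,  sd = 2.0,  min = 0.24, max = 6.9)
    ),
    male = list(
      stature      = c(mean = 178.8, sd = 7.0,  min = 163,  max = 199),
      weight       = c(mean = 80.1,  sd = 11.5, min = 63,   max = 109),
      fm_total     = c(mean = 17.0,  sd = 7.5,  min = 6.2,  max = 33),
      fm_abdominal = c(mean = 1.94,  sd = 1.41, min = 0.35, max = 5.0)
    ),
    fm_log_correlation = fm_log_correlation,
    weight_fm_correlation = weight_fm_correlation,
    segment_noise_sd = segment_noise_sd
  )
}

#' Alternative cohort marginals for the abdominal-model development sample
#'
#' Same structure as [cohort_config()] but with the fat-mass and
#' anthropometry marginals of the smaller abdominal-model cohort
#' (32 females / 31 males).
#'
#' @inheritParams cohort_config
#' @return See [cohort_config()].
#' @export
abdominal_cohort_config <- function(segment_noise_sd = 0.5,
                                    fm_log_correlation = 0.9,
                                    weight_fm_correlation = 0.75) {
  cfg <- cohort_config(segment_noise_sd, fm_log_correlation, weight_fm_correlation)
  cfg$female$stature  <- c(mean = 162.5, sd = 5.8,  min = 152, max = 174)
  cfg$female$weight   <- c(mean = 67.0,  sd = 15.7, min = 42,  max = 103)
  cfg$female$fm_total <- c(mean = 23.6,  sd = 12.8, min = 7.4, max = 52)
  cfg$male$stature    <- c(mean = 177.2, sd = 7.4,  min = 165, max = 193)
  cfg$male$weight     <- c(mean = 78.2,  sd = 12.2, min = 63,  max = 108)
  cfg$male$fm_total   <- c(mean = 17.0,  sd = 8.5,  min = 6.2, max = 35)
  cfg
}

# Segments, ordered head to ankle.
SEGMENTS <- c("head", "neck", "chest", "belly", "hip", "thigh", "calf", "ankle")

#' Deterministic fat-mass to sagittal-depth mapping
#'
#' Linear map from `(fm_total, fm_abdominal, stature)` to the sagittal depth
#' (cm) of each body segment. Belly and chest depths are strictly increasing
#' in both fat-mass arguments; all depths are floored at 2 cm.
#'
#' @param fm_total Total fat mass, kg.
#' @param fm_abdominal Abdominal (L2-5) fat mass, kg.
#' @param stature Standing height, cm.
#' @return Named numeric vector over
#'   `head, neck, chest, belly, hip, thigh, calf, ankle`.
#' @export
segment_depths <- function(fm_total, fm_abdominal, stature) {
  fm_total <- as.numeric(fm_total)
  fm_abdominal <- as.numeric(fm_abdominal)
  ds <- as.numeric(stature) - 170
  d <- c(
    head  = 18.5 + 0.03 * ds,
    neck  = 11.0 + 0.04 * fm_total + 0.02 * ds,
    chest = 21.0 + 0.18 * fm_total + 0.25 * fm_abdominal + 0.04 * ds,
    belly = 17.0 + 0.22 * fm_total + 0.85 * fm_abdominal + 0.02 * ds,
    hip   = 17.5 + 0.14 * fm_total + 0.03 * ds,
    thigh = 13.0 + 0.10 * fm_total + 0.03 * ds,
    calf  =  9.5 + 0.05 * fm_total + 0.03 * ds,
    ankle =  6.5 + 0.01 * fm_total
  )
  pmax(d, 2)
}

#' Construct a single subject record
#'
#' Computes segment sagittal depths from the deterministic mapping plus the
#' supplied per-segment noise, and validates all invariants.
#'
#' @param subject_id Identifier string.
#' @param gender `"female"` or `"male"`.
#' @param stature,weight,fm_total,fm_abdominal Anthropometry (cm, kg).
#' @param segment_noise Either a single 0 or a named length-8 numeric vector
#'   of additive depth perturbations (cm).
#' @return An object of class `body_params`.
#' @export
body_params <- function(subject_id, gender, stature, weight,
                        fm_total, fm_abdominal, segment_noise = 0) {
  gender <- match.arg(gender, c("female", "male"))
  assert_that(is_scalar(stature) && stature > 0, "stature must be positive")
  assert_that(is_scalar(weight) && weight > 0, "weight must be positive")
  assert_that(is_scalar(fm_total) && fm_total > 0, "fm_total must be positive")
  assert_that(is_scalar(fm_abdominal) && fm_abdominal > 0,
              "fm_abdominal must be positive")
  assert_that(fm_abdominal < fm_total, "fm_abdominal must be below fm_total")
  if (length(segment_noise) == 1L && segment_noise[1L] == 0) {
    segment_noise <- stats::setNames(numeric(length(SEGMENTS)), SEGMENTS)
  }
  assert_that(length(segment_noise) == length(SEGMENTS) &&
                all(SEGMENTS %in% names(segment_noise)),
              "segment_noise must be named over all body segments")
  depths <- pmax(segment_depths(fm_total, fm_abdominal, stature) +
                   segment_noise[SEGMENTS], 2)
  structure(list(subject_id = as.character(subject_id), gender = gender,
                 stature = stature, weight = weight, fm_total = fm_total,
                 fm_abdominal = fm_abdominal,
                 segment_thicknesses = depths,
                 segment_noise = stats::setNames(as.numeric(segment_noise[SEGMENTS]),
                                                 SEGMENTS)),
            class = "body_params")
}

#' @export
print.body_params <- function(x, ...) {
  cat(sprintf("<body_params> %s (%s): stature %.1f cm, weight %.1f kg, FM %.2f kg, abdominal FM %.2f kg\n",
              x$subject_id, x$gender, x$stature, x$weight, x$fm_total, x$fm_abdominal))
  invisible(x)
}

#' Sample a synthetic cohort
#'
#' Draws `n` subjects with the configured per-gender marginals. Total and
#' abdominal fat mass are coupled through a Gaussian copula (log-scale
#' correlation `fm_log_correlation`), weight is coupled to total fat mass,
#' and stature is independent. Marginals are moment-matched truncated laws,
#' so sample means and SDs converge to the configured table values.
#' Deterministic given `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param female_fraction Proportion of females in `[0, 1]`; the realized
#'   count is `round(n * female_fraction)`.
#' @param seed Integer seed.
#' @param config See [cohort_config()].
#' @return A list of [body_params()] objects, class `cohort`.
#' @export
sample_cohort <- function(n, female_fraction = 84 / 158, seed = 1L,
                          config = cohort_config()) {
  assert_that(is_count(n), "n must be a positive integer")
  assert_that(is_scalar(female_fraction) && female_fraction >= 0 &&
                female_fraction <= 1,
              "female_fraction must be in [0, 1]")
  n_f <- as.integer(round(n * female_fraction))
  genders <- c(rep("female", n_f), rep("male", n - n_f))
  with_seed(seed, {
    out <- vector("list", n)
    for (g in c("female", "male")) {
      idx <- which(genders == g)
      if (!length(idx)) next
      m <- config[[g]]
      ng <- length(idx)
      cal_fm  <- calibrate_marginal(m$fm_total["mean"], m$fm_total["sd"],
                                    m$fm_total["min"], m$fm_total["max"], "lognormal")
      cal_ab  <- calibrate_marginal(m$fm_abdominal["mean"], m$fm_abdominal["sd"],
                                    m$fm_abdominal["min"], m$fm_abdominal["max"], "lognormal")
      cal_wt  <- calibrate_marginal(m$weight["mean"], m$weight["sd"],
                                    m$weight["min"], m$weight["max"], "normal")
      cal_st  <- calibrate_marginal(m$stature["mean"], m$stature["sd"],
                                    m$stature["min"], m$stature["max"], "normal")
      z_fm <- stats::rnorm(ng)
      rho <- config$fm_log_correlation
      z_ab <- rho * z_fm + sqrt(1 - rho^2) * stats::rnorm(ng)
      rw <- config$weight_fm_correlation
      z_wt <- rw * z_fm + sqrt(1 - rw^2) * stats::rnorm(ng)
      fm <- qmarginal(z_fm, cal_fm)
      ab <- qmarginal(z_ab, cal_ab)
      wt <- qmarginal(z_wt, cal_wt)
      st <- qmarginal(stats::rnorm(ng), cal_st)
      # abdominal fat is a proper subset of total fat; the configured ranges
      # already guarantee this, but guard against pathological configs
      ab <- pmin(ab, 0.95 * fm)
      noise <- matrix(stats::rnorm(ng * length(SEGMENTS),
                                   sd = config$segment_noise_sd),
                      nrow = ng,
                      dimnames = list(NULL, SEGMENTS))
      for (k in seq_along(idx)) {
        i <- idx[k]
        out[[i]] <- body_params(
          subject_id = sprintf("S%04d_%s", i, toupper(substr(g, 1, 1))),
          gender = g, stature = st[k], weight = wt[k],
          fm_total = fm[k], fm_abdominal = ab[k],
          segment_noise = noise[k, ]
        )
      }
    }
    structure(out, class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  g <- vapply(x, `[[`, character(1), "gender")
  cat(sprintf("<cohort> %d subjects (%d female, %d male)\n",
              length(x), sum(g == "female"), sum(g == "male")))
  invisible(x)
}

#' Tabulate a cohort
#'
#' @param x A `cohort` (list of [body_params()]).
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame with one row per subject: `subject_id`, `gender`,
#'   `stature_cm`, `weight_kg`, `fm_total_kg`, `fm_abdominal_kg` and one
#'   `depth_<segment>_cm` column per body segment.
#' @export
as.data.frame.cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(
    subject_id = vapply(x, `[[`, character(1), "subject_id"),
    gender = vapply(x, `[[`, character(1), "gender"),
    stature_cm = vapply(x, `[[`, numeric(1), "stature"),
    weight_kg = vapply(x, `[[`, numeric(1), "weight"),
    fm_total_kg = vapply(x, `[[`, numeric(1), "fm_total"),
    fm_abdominal_kg = vapply(x, `[[`, numeric(1), "fm_abdominal"),
    stringsAsFactors = FALSE
  )
  depths <- t(vapply(x, `[[`, numeric(length(SEGMENTS)), "segment_thicknesses"))
  colnames(depths) <- paste0("depth_", SEGMENTS, "_cm")
  cbind(df, as.data.frame(depths))
}

#' Write the cohort table as CSV
#'
#' Columns: `subject_id, gender, stature_cm, weight_kg, fm_total_kg,
#' fm_abdominal_kg, image_path`.
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @param image_paths Optional character vector of per-subject image paths.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, image_paths = NULL) {
  df <- as.data.frame(cohort)
  df <- df[, c("subject_id", "gender", "stature_cm", "weight_kg",
               "fm_total_kg", "fm_abdominal_kg")]
  df$image_path <- image_paths %||% rep("", nrow(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
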
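# Gender-specific prediction models mapping occupancy features to total or
# abdominal fat mass. Ordinary least squares is the default family: it is
# the minimal family consistent with the reported identity-line behavior
# (slope ~ 1, intercept ~ 0) and it makes parameter recovery testable. An
# optional ridge penalty is available as a configuration hook.

MODEL_SCHEMA_VERSION <- 1L
BASE_FEATURES <- c("occupancy_ratio", "width_chest", "width_belly",
                   "width_thigh", "width_calf")

#' Model configuration
#'
#' @param use_stature Include stature (cm) as a covariate. Off by default:
#'   the models are kept exclusive of directly measured body size, in the
#'   spirit of excluding body weight.
#' @param ridge_lambda Nonnegative ridge penalty; 0 gives ordinary least
#'   squares.
#' @param min_prediction Floor (kg) applied to predictions; physically a
#'   fat mass cannot be near zero or negative.
#' @return A list of class `model_config`.
#' @export
model_config <- function(use_stature = FALSE, ridge_lambda = 0,
                         min_prediction = 0.5) {
  assert_that(is.logical(use_stature) && length(use_stature) == 1L,
              "use_stature must be TRUE or FALSE")
  assert_that(is_scalar(ridge_lambda) && ridge_lambda >= 0,
              "ridge_lambda must be nonnegative")
  assert_that(is_scalar(min_prediction) && min_prediction >= 0,
              "min_prediction must be nonnegative")
  structure(list(use_stature = use_stature, ridge_lambda = ridge_lambda,
                 min_prediction = min_prediction), class = "model_config")
}

feature_matrix <- function(features, feature_names) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "feature_vector"))) {
    features <- features_table(features)
  }
  assert_that(is.data.frame(features), "features must be a data frame or list of feature_vector")
  banned <- grepl("^weight(_kg)?$", names(features), ignore.case = TRUE)
  if (any(banned)) {
    stop_silfat(sprintf("feature table contains body weight column '%s': body weight is excluded by contract",
                        names(features)[banned][1L]), "silfat_contract_error")
  }
  missing <- setdiff(feature_names, names(features))
  if ("stature_cm" %in% missing && "stature" %in% names(features)) {
    features$stature_cm <- features$stature
    missing <- setdiff(feature_names, names(features))
  }
  assert_that(length(missing) == 0L,
              sprintf("missing feature(s): %s", paste(missing, collapse = ", ")),
              "silfat_contract_error")
  if (length(feature_names) == 0L) {
    return(matrix(numeric(0), nrow(features), 0L))
  }
  X <- as.matrix(features[, feature_names, drop = FALSE])
  assert_that(is.numeric(X) && all(is.finite(X)), "features must be finite numeric")
  X
}

#' Train a fat-mass prediction model
#'
#' Least-squares fit of the reference fat mass on the occupancy feature set
#' for one gender. Any column carrying body weight is refused: the models
#' are trained exclusive of body weight as an independent variable.
#'
#' @param features A data frame (see [features_table()]) or list of
#'   [extract_features()] results, all of the stated gender.
#' @param reference Positive reference fat-mass values (kg), e.g. from DXA.
#' @param target `"fm_total"` or `"fm_abdominal"`.
#' @param gender `"female"` or `"male"`.
#' @param config A [model_config()].
#' @return An object of class `bodycomp_model` with the fitted
#'   coefficients, intercept, standard error of estimate (residual SD on
#'   `n - p - 1` degrees of freedom) and training metadata.
#' @export
train_bodycomp_model <- function(features, reference,
                                 target = c("fm_total", "fm_abdominal"),
                                 gender = c("female", "male"),
                                 config = model_config()) {
  target <- match.arg(target)
  gender <- match.arg(gender)
  feature_names <- BASE_FEATURES
  if (config$use_stature) feature_names <- c(feature_names, "stature_cm")
  if (is.data.frame(features) && "gender" %in% names(features)) {
    assert_that(all(features$gender == gender),
                "training rows of the wrong gender: models are strictly gender-specific",
                "silfat_contract_error")
  }
  X <- feature_matrix(features, feature_names)
  n <- nrow(X); p <- ncol(X)
  assert_that(is.numeric(reference) && length(reference) == n &&
                all(is.finite(reference)),
              "reference must be a finite numeric vector matching the features")
  assert_that(all(reference > 0), "reference fat mass must be positive")
  if (n < 2 * (p + 1)) {
    stop_silfat(sprintf("need at least %d training records for %d features, got %d",
                        2 * (p + 1), p, n), "silfat_sample_size")
  }
  Xd <- cbind(`(intercept)` = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    aliased <- colnames(Xd)[qrd$pivot[(qrd$rank + 1):ncol(Xd)]]
    stop_silfat(sprintf("collinear design; offending feature(s): %s",
                        paste(aliased, collapse = ", ")),
                "silfat_collinearity")
  }
  if (config$ridge_lambda > 0) {
    # penalize slopes only, on centered/scaled features
    mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
    Z <- scale(X, mu, sdv)
    A <- crossprod(Z) + diag(config$ridge_lambda, p)
    b <- solve(A, crossprod(Z, reference - mean(reference)))
    coefs <- as.numeric(b / sdv)
    intercept <- mean(reference) - sum(coefs * mu)
  } else {
    fit <- qr.coef(qrd, reference)
    intercept <- fit[1L]
    coefs <- fit[-1L]
  }
  resid <- reference - (intercept + X %*% coefs)
  see <- sqrt(sum(resid^2) / (n - p - 1))
  structure(list(target = target, gender = gender,
                 coefficients = stats::setNames(as.numeric(coefs), feature_names),
                 intercept = as.numeric(intercept),
                 use_stature = config$use_stature,
                 training_n = n, training_see = see,
                 feature_names = feature_names,
                 min_prediction = config$min_prediction,
                 schema_version = MODEL_SCHEMA_VERSION),
            class = "bodycomp_model")
}

#' @export
print.bodycomp_model <- function(x, ...) {
  cat(sprintf("<bodycomp_model> %s, %s (n = %d, SEE = %.3f kg)\n",
              x$target, x$gender, x$training_n, x$training_see))
  cat(sprintf("  intercept %.3f + %s\n", x$intercept,
              paste(sprintf("%.3f*%s", x$coefficients, x$feature_names),
                    collapse = " + ")))
  invisible(x)
}

#' Predict fat mass from features
#'
#' @param object A `bodycomp_model`.
#' @param newdata A `feature_vector`, list of them, or feature data frame of
#'   the model's gender.
#' @param ... Unused.
#' @return Numeric vector of predictions in kg, floored at the model's
#'   minimum with a logical `truncated` attribute marking floored entries.
#' @export
predict.bodycomp_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_vector")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, logical(1), "feature_vector"))) {
    newdata <- features_table(newdata)
  }
  assert_that(is.data.frame(newdata), "newdata must carry feature columns")
  if ("gender" %in% names(newdata)) {
    if (!all(newdata$gender == object$gender)) {
      stop_silfat(sprintf("feature gender does not match the %s model: models are strictly gender-specific",
                          object$gender), "silfat_contract_error")
    }
  }
  X <- feature_matrix(newdata, object$feature_names)
  lin <- if (length(object$coefficients)) as.numeric(X %*% object$coefficients) else 0
  pred <- object$intercept + lin
  if (length(pred) == 1L && nrow(newdata) > 1L) pred <- rep(pred, nrow(newdata))
  floor_kg <- object$min_prediction %||% 0.5
  truncated <- pred < floor_kg
  pred[truncated] <- floor_kg
  attr(pred, "truncated") <- truncated
  pred
}

#' Serialize a model to versioned JSON
#'
#' @param model A `bodycomp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  assert_that(inherits(model, "bodycomp_model"), "model must be a bodycomp_model")
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model from JSON
#'
#' Refuses files of an unknown schema version or with missing fields.
#'
#' @param path Path to a file written by [write_model()] (or hand-written
#'   to the same schema).
#' @return A `bodycomp_model`.
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_silfat(sprintf("malformed model file: %s", conditionMessage(e)),
                                "silfat_parse_error")
                  })
  required <- c("schema_version", "target", "gender", "feature_names",
                "coefficients", "intercept")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop_silfat(sprintf("model file missing field(s): %s",
                        paste(missing, collapse = ", ")), "silfat_parse_error")
  }
  if (!identical(as.integer(obj$schema_version), MODEL_SCHEMA_VERSION)) {
    stop_silfat(sprintf("unsupported model schema version %s", obj$schema_version),
                "silfat_parse_error")
  }
  coefs <- unlist(obj$coefficients)
  feature_names <- as.character(obj$feature_names)
  if (!setequal(names(coefs), feature_names)) {
    stop_silfat("model coefficients do not match feature_names", "silfat_parse_error")
  }
  if (any(grepl("^weight(_kg)?$", feature_names, ignore.case = TRUE))) {
    stop_silfat("model file includes body weight as a feature", "silfat_contract_error")
  }
  structure(list(target = match.arg(obj$target, c("fm_total", "fm_abdominal")),
                 gender = match.arg(obj$gender, c("female", "male")),
                 coefficients = coefs[feature_names],
                 intercept = as.numeric(obj$intercept),
                 use_stature = isTRUE(obj$use_stature),
                 training_n = as.integer(obj$training_n %||% NA_integer_),
                 training_see = as.numeric(obj$training_see %||% NA_real_),
                 feature_names = feature_names,
                 min_prediction = as.numeric(obj$min_prediction %||% 0.5),
                 schema_version = MODEL_SCHEMA_VERSION),
            class = "bodycomp_model")
}
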
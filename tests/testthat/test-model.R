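# Prediction models: recovery, contracts, serialization.

sim_features <- function(n, seed) {
  features_table(true_cohort_features(sample_cohort(n, 1, seed = seed)))
}

TRUE_BETA <- c(occupancy_ratio = 80, width_chest = 50, width_belly = 250,
               width_thigh = 30, width_calf = 20)
TRUE_INTERCEPT <- -30

sim_reference <- function(X, noise_sd, seed) {
  lin <- TRUE_INTERCEPT + as.matrix(X[, names(TRUE_BETA)]) %*% TRUE_BETA
  set.seed(seed)
  pmax(as.numeric(lin) + rnorm(nrow(X), 0, noise_sd), 0.1)
}

test_that("training recovers generating coefficients exactly without noise", {
  X <- sim_features(100, seed = 9)
  y <- sim_reference(X, 0, seed = 1)
  m <- train_bodycomp_model(X, y, "fm_total", "female")
  expect_lt(max(abs(m$coefficients - TRUE_BETA) / abs(TRUE_BETA)), 1e-6)
  expect_lt(abs(m$intercept - TRUE_INTERCEPT), 1e-6)
  expect_lt(m$training_see, 1e-6)
  expect_lt(max(abs(predict(m, X) - y)), 1e-6)
})

test_that("fitted SEE tracks the injected residual noise", {
  X <- sim_features(200, seed = 10)
  y <- sim_reference(X, 2.3, seed = 2)
  m <- train_bodycomp_model(X, y, "fm_total", "female")
  expect_lt(abs(m$training_see / 2.3 - 1), 0.15)
  # held-out performance at the same noise scale
  X2 <- sim_features(60, seed = 11)
  y2 <- sim_reference(X2, 2.3, seed = 3)
  pred <- predict(m, X2)
  expect_gte(linearity_test(as.numeric(pred), y2)$r2, 0.85)
})

test_that("training refuses body weight, mixed genders and tiny samples", {
  X <- sim_features(40, seed = 12)
  y <- sim_reference(X, 1, seed = 4)
  Xw <- X
  Xw$weight_kg <- rnorm(40, 70, 10)
  expect_error(train_bodycomp_model(Xw, y, "fm_total", "female"),
               class = "silfat_contract_error")
  Xg <- X
  Xg$gender[3] <- "male"
  expect_error(train_bodycomp_model(Xg, y, "fm_total", "female"),
               class = "silfat_contract_error")
  expect_error(train_bodycomp_model(X[1:8, ], y[1:8], "fm_total", "female"),
               class = "silfat_sample_size")
})

test_that("collinear designs are refused with the offending feature named", {
  X <- sim_features(40, seed = 13)
  X$width_calf <- 2 * X$width_chest
  y <- sim_reference(X, 1, seed = 5)
  err <- tryCatch(train_bodycomp_model(X, y, "fm_total", "female"),
                  silfat_collinearity = function(e) conditionMessage(e))
  expect_match(err, "width_calf|width_chest")
})

test_that("prediction enforces gender matching and the physical floor", {
  X <- sim_features(40, seed = 14)
  y <- sim_reference(X, 1, seed = 6)
  m <- train_bodycomp_model(X, y, "fm_total", "female")
  Xm <- X
  Xm$gender <- "male"
  expect_error(predict(m, Xm), class = "silfat_contract_error")

  const <- m
  const$coefficients[] <- 0
  const$intercept <- 20
  expect_equal(unname(as.numeric(predict(const, X[1:3, ]))), rep(20, 3))
  low <- m
  low$coefficients[] <- 0
  low$intercept <- -4
  p <- predict(low, X[1:2, ])
  expect_equal(as.numeric(p), rep(0.5, 2))
  expect_true(all(attr(p, "truncated")))
})

test_that("models round-trip through JSON and refuse unknown versions", {
  X <- sim_features(40, seed = 15)
  y <- sim_reference(X, 1, seed = 7)
  m <- train_bodycomp_model(X, y, "fm_abdominal", "female", config = model_config())
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_equal(as.numeric(predict(back, X[1:5, ])),
               as.numeric(predict(m, X[1:5, ])))

  bad <- jsonlite::read_json(f)
  bad$schema_version <- 999
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(read_model(f2), class = "silfat_parse_error")
  writeLines("{not json", f2)
  expect_error(read_model(f2), class = "silfat_parse_error")
  unlink(c(f, f2))
})

test_that("a hand-written minimal model file predicts its constant intercept", {
  f <- tempfile(fileext = ".json")
  writeLines('{
    "schema_version": 1, "target": "fm_total", "gender": "female",
    "feature_names": [], "coefficients": {}, "intercept": 21.5
  }', f)
  m <- read_model(f)
  X <- sim_features(3, seed = 16)
  expect_equal(as.numeric(predict(m, X)), rep(21.5, 3))
  unlink(f)
})

test_that("coefficient estimates are unbiased over replicates", {
  est <- matrix(NA_real_, 8, length(TRUE_BETA))
  for (r in 1:8) {
    X <- sim_features(200, seed = 100 + r)
    y <- sim_reference(X, 2.3, seed = 200 + r)
    est[r, ] <- train_bodycomp_model(X, y, "fm_total", "female")$coefficients
  }
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  bias <- abs(colMeans(est) - TRUE_BETA)
  expect_true(all(bias <= 3 * se + 1e-8))
})
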
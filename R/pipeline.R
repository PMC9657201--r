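# Orchestration: simulate -> condition -> features -> train/predict ->
# validate, as seeded, logged, manifest-ed experiment runs. Derivation and
# validation cohorts come from disjoint seed streams, mirroring a prediction
# model derived in an independent sample.

#' Pipeline configuration
#'
#' @param seed Master integer seed; every stage derives its stream from it.
#' @param n_derivation,n_validation Named counts (`female`, `male`) for the
#'   model-derivation and validation cohorts. The validation default matches
#'   the emulated study (84 females / 74 males); the derivation sample size
#'   is a package choice (the original derivation sample is not described).
#' @param n_reproducibility Named counts for the repositioning-reproducibility
#'   trial (12 females / 15 males).
#' @param cohort A [cohort_config()].
#' @param render A [render_spec()]; per-subject seeds are derived from
#'   `seed`, and `pose_jitter` applies to every acquisition.
#' @param geometry A [geometry_config()].
#' @param qc A [qc_config()].
#' @param model A [model_config()].
#' @param target `"fm_total"` or `"fm_abdominal"`.
#' @param ape_mode Pure-error definition for reports, see [error_metrics()].
#' @param out_dir Run directory (created if missing).
#' @param save_images Write every rendered image to disk (off by default:
#'   images are large and features are computed in memory).
#' @param make_figures Write Bland-Altman and identity-line figures.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_derivation = c(female = 100, male = 100),
                            n_validation = c(female = 84, male = 74),
                            n_reproducibility = c(female = 12, male = 15),
                            cohort = cohort_config(),
                            render = render_spec(),
                            geometry = geometry_config(),
                            qc = qc_config(),
                            model = model_config(),
                            target = c("fm_total", "fm_abdominal"),
                            ape_mode = c("group_mean", "rmse"),
                            out_dir = tempfile("silfat_run_"),
                            save_images = FALSE,
                            make_figures = TRUE) {
  target <- match.arg(target)
  ape_mode <- match.arg(ape_mode)
  for (nn in list(n_derivation, n_validation, n_reproducibility)) {
    assert_that(all(c("female", "male") %in% names(nn)) && all(nn >= 0),
                "cohort sizes must be named counts for female and male")
  }
  assert_that(is_scalar(seed) && abs(seed) < 2^31 - 1e6, "seed must be a small integer")
  structure(list(seed = as.integer(seed), n_derivation = n_derivation,
                 n_validation = n_validation,
                 n_reproducibility = n_reproducibility,
                 cohort = cohort, render = render, geometry = geometry,
                 qc = qc, model = model, target = target, ape_mode = ape_mode,
                 out_dir = out_dir, save_images = save_images,
                 make_figures = make_figures),
            class = "pipeline_config")
}

log_line <- function(log, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", file = log, sep = "", append = TRUE)
  invisible(msg)
}

# Render, condition and featurize one gender's cohort; QC failures are
# excluded and counted, not fatal.
cohort_features <- function(cohort, config, seed_base, log, stage) {
  fvs <- list()
  kept <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    spec_i <- config$render
    spec_i$seed <- as.integer(seed_base + i)
    res <- tryCatch({
      rend <- render_silhouette(subj, spec_i, config$geometry)
      sil <- binarize(rend$image, threshold = 0.5, strict = FALSE)
      qc <- quality_check(sil, config$qc)
      if (!qc$passed) {
        log_line(log, "stage=%s subject=%s qc_failed=%s", stage,
                 subj$subject_id, paste(qc$failures, collapse = "|"))
        NULL
      } else {
        silhouette_features(sil, subj$gender, subject_id = subj$subject_id,
                            stature = subj$stature, config = config$geometry)
      }
    }, silfat_error = function(e) {
      log_line(log, "stage=%s subject=%s error=%s", stage, subj$subject_id,
               conditionMessage(e))
      stop_silfat(sprintf("stage %s failed at subject %s: %s", stage,
                          subj$subject_id, conditionMessage(e)),
                  class(e)[1L])
    })
    if (!is.null(res)) {
      fvs[[length(fvs) + 1L]] <- res
      kept[i] <- TRUE
    }
  }
  log_line(log, "stage=%s n=%d qc_excluded=%d", stage, length(cohort),
           sum(!kept))
  list(features = fvs, kept = kept)
}

reference_values <- function(cohort, target) {
  field <- if (target == "fm_total") "fm_total" else "fm_abdominal"
  vapply(cohort, `[[`, numeric(1), field)
}

write_manifest <- function(out_dir, config) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(package_version = as.character(utils::packageVersion("silfat")),
                   seed = config$seed, target = config$target,
                   files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

report_to_list <- function(rep) lapply(unclass(rep), function(v) unname(v))

#' Run the synthetic model-validation experiment
#'
#' Samples a derivation and an independent validation cohort, renders and
#' conditions every subject, trains per-gender models on the derivation
#' features and evaluates them on the validation cohort with the full
#' agreement battery. All outputs (cohort tables, features, models, per-
#' gender agreement reports, figures, structured log, hashed manifest) are
#' written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-gender `agreement_report`s, the
#'   trained models, and `run_dir`.
#' @export
run_validation_experiment <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "run.log")
  cat("", file = log)
  log_line(log, "stage=start experiment=validation seed=%d target=%s",
           config$seed, config$target)

  seeds <- config$seed + c(derivation = 101L, validation = 211L)
  cohorts <- list()
  for (role in c("derivation", "validation")) {
    nn <- if (role == "derivation") config$n_derivation else config$n_validation
    n <- sum(nn)
    cohorts[[role]] <- sample_cohort(n, female_fraction = nn[["female"]] / n,
                                     seed = seeds[[role]], config = config$cohort)
    write_cohort_csv(cohorts[[role]],
                     file.path(out, sprintf("cohort_%s.csv", role)))
    log_line(log, "stage=simulate role=%s n=%d", role, n)
  }

  feats <- list()
  for (role in c("derivation", "validation")) {
    feats[[role]] <- cohort_features(cohorts[[role]], config,
                                     seed_base = (seeds[[role]] %% 1000000L) * 1000L,
                                     log, stage = paste0("features_", role))
    utils::write.csv(features_table(feats[[role]]$features),
                     file.path(out, sprintf("features_%s.csv", role)),
                     row.names = FALSE, quote = FALSE)
  }

  reports <- list(); models <- list()
  genders <- c("female", "male")
  genders <- genders[config$n_derivation[genders] > 0 &
                       config$n_validation[genders] > 0]
  for (g in genders) {
    der_keep <- feats$derivation$kept &
      vapply(cohorts$derivation, `[[`, character(1), "gender") == g
    der_f <- feats$derivation$features[
      vapply(feats$derivation$features, `[[`, character(1), "gender") == g]
    der_ref <- reference_values(cohorts$derivation[der_keep], config$target)
    log_line(log, "stage=train gender=%s n=%d", g, length(der_ref))
    models[[g]] <- train_bodycomp_model(der_f, der_ref, target = config$target,
                                        gender = g, config = config$model)
    write_model(models[[g]], file.path(out, sprintf("model_%s_%s.json",
                                                    config$target, g)))

    val_keep <- feats$validation$kept &
      vapply(cohorts$validation, `[[`, character(1), "gender") == g
    val_f <- feats$validation$features[
      vapply(feats$validation$features, `[[`, character(1), "gender") == g]
    ref <- reference_values(cohorts$validation[val_keep], config$target)
    pred <- predict(models[[g]], val_f)
    preds_df <- data.frame(
      subject_id = vapply(val_f, function(f) as.character(f$subject_id), character(1)),
      predicted_kg = as.numeric(pred), reference_kg = ref)
    utils::write.csv(preds_df, file.path(out, sprintf("predictions_%s.csv", g)),
                     row.names = FALSE, quote = FALSE)
    reports[[g]] <- full_report(as.numeric(pred), ref, ape_mode = config$ape_mode)
    log_line(log, "stage=validate gender=%s n=%d ccc=%.4f", g, length(ref),
             reports[[g]]$ccc)
    if (config$make_figures && capabilities("png")) {
      fig <- file.path(out, sprintf("figures_%s.png", g))
      grDevices::png(fig, width = 1400, height = 700)
      op <- graphics::par(mfrow = c(1, 2))
      plot_identity(as.numeric(pred), ref,
                    main = sprintf("%s: predicted vs reference", g))
      plot_bland_altman(as.numeric(pred), ref,
                        main = sprintf("%s: Bland-Altman", g))
      graphics::par(op)
      grDevices::dev.off()
    }
  }

  jsonlite::write_json(lapply(reports, report_to_list),
                       file.path(out, "agreement_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log, "stage=done")
  write_manifest(out, config)
  invisible(list(reports = reports, models = models, run_dir = out))
}

#' Run the repositioning-reproducibility experiment
#'
#' Trains per-gender models on a derivation cohort, then renders each
#' reproducibility subject twice with independent pose jitter (emulating
#' consecutive photographs with repositioning), runs the full conditioning
#' and feature path on both acquisitions and compares the two fat-mass
#' estimates per subject.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-gender `reproducibility_report`s and
#'   `run_dir`.
#' @export
run_reproducibility_experiment <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "run.log")
  cat("", file = log)
  log_line(log, "stage=start experiment=reproducibility seed=%d", config$seed)

  seed_der <- config$seed + 101L
  seed_rep <- config$seed + 307L
  n_der <- sum(config$n_derivation)
  derivation <- sample_cohort(n_der,
                              female_fraction = config$n_derivation[["female"]] / n_der,
                              seed = seed_der, config = config$cohort)
  der <- cohort_features(derivation, config,
                         seed_base = (seed_der %% 1000000L) * 1000L,
                         log, stage = "features_derivation")

  n_rep <- sum(config$n_reproducibility)
  trial <- sample_cohort(n_rep,
                         female_fraction = config$n_reproducibility[["female"]] / n_rep,
                         seed = seed_rep, config = config$cohort)
  write_cohort_csv(trial, file.path(out, "cohort_reproducibility.csv"))

  reports <- list()
  rows <- list()
  genders <- c("female", "male")
  genders <- genders[config$n_derivation[genders] > 0 &
                       config$n_reproducibility[genders] > 0]
  for (g in genders) {
    der_keep <- der$kept &
      vapply(derivation, `[[`, character(1), "gender") == g
    der_f <- der$features[
      vapply(der$features, `[[`, character(1), "gender") == g]
    model <- train_bodycomp_model(der_f, reference_values(derivation[der_keep],
                                                          config$target),
                                  target = config$target, gender = g,
                                  config = config$model)
    subjects <- trial[vapply(trial, `[[`, character(1), "gender") == g]
    est <- matrix(NA_real_, length(subjects), 2L)
    for (i in seq_along(subjects)) {
      for (acq in 1:2) {
        spec_i <- config$render
        spec_i$seed <- as.integer((seed_rep %% 1000000L) * 1000L +
                                    1000L * (g == "male") + 2L * i + acq)
        rend <- render_silhouette(subjects[[i]], spec_i, config$geometry)
        sil <- binarize(rend$image, threshold = 0.5, strict = FALSE)
        fv <- silhouette_features(sil, g, subject_id = subjects[[i]]$subject_id,
                                  stature = subjects[[i]]$stature,
                                  config = config$geometry)
        est[i, acq] <- predict(model, fv)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects[[i]]$subject_id, gender = g,
        test1_kg = est[i, 1L], test2_kg = est[i, 2L])
    }
    reports[[g]] <- reproducibility(est[, 1L], est[, 2L])
    log_line(log, "stage=reproducibility gender=%s n=%d tem=%.4f ccc=%.5f",
             g, nrow(est), reports[[g]]$tem, reports[[g]]$ccc)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out, "replicate_estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(reports, report_to_list),
                       file.path(out, "reproducibility_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log, "stage=done")
  write_manifest(out, config)
  invisible(list(reports = reports, run_dir = out))
}
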
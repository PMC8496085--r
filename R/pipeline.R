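#' Configuration for an end-to-end pipeline run
#'
#' Validates all options up front; the configuration is persisted verbatim
#' into the output directory by [run_pipeline()].
#'
#' @param out_dir Output directory.
#' @param simulate Optional [synthetic_cohort_spec()]; when given, the
#'   cohort is generated rather than read.
#' @param input_dir Directory with per-case mesh files
#'   (`<id>_ED.vtk`, `<id>_ES.vtk`, `<id>_labels.csv`) and a
#'   `covariates.csv`, used when `simulate` is `NULL`.
#' @param var_threshold Cumulative variance fraction for mode retention.
#' @param n_modes Optional explicit retained mode count.
#' @param alpha Significance level for overall effects.
#' @param attribution_rule Passed to [variance_attributable()].
#' @param levels Short-axis level fractions for strain.
#' @param window Apical-angle sliding-window fraction.
#' @param thickness_stations Centerline stations for wall thickness.
#' @param prvi_values PRVI values (ml/m^2) at which regression-predicted
#'   shapes are reconstructed and written.
#' @param features,strain Compute the feature / strain stages (default
#'   `TRUE`).
#' @param seed Seed recorded in the log (the simulation uses the seed in
#'   its own spec).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, input_dir = NULL,
                            var_threshold = 0.90, n_modes = NULL,
                            alpha = 0.05,
                            attribution_rule = c("sr2", "pe2", "fsum"),
                            levels = strain_levels(), window = 0.30,
                            thickness_stations = 50,
                            prvi_values = c(5, 25.5, 40),
                            features = TRUE, strain = TRUE, seed = 1L) {
  attribution_rule <- match.arg(attribution_rule)
  if (is.null(simulate) && is.null(input_dir)) {
    stop_cs("config error: either simulate or input_dir is required", "config")
  }
  if (!is.null(simulate) && !inherits(simulate, "synthetic_cohort_spec")) {
    stop_cs("config error: simulate must be a synthetic_cohort_spec", "config")
  }
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    stop_cs("config error: alpha must be in [0, 1]", "config")
  }
  if (!is_scalar_number(var_threshold) || var_threshold <= 0 ||
      var_threshold > 1) {
    stop_cs("config error: var_threshold must be in (0, 1]", "config")
  }
  if (any(levels <= 0) || any(levels >= 1)) {
    stop_cs("config error: level fractions must be in (0, 1)", "config")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 input_dir = input_dir, var_threshold = var_threshold,
                 n_modes = n_modes, alpha = alpha,
                 attribution_rule = attribution_rule, levels = levels,
                 window = window, thickness_stations = thickness_stations,
                 prvi_values = prvi_values, features = features,
                 strain = strain, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a cohort directory of case meshes and covariates
#'
#' Expects `covariates.csv` plus, per case id, `<id>_ED.<ext>`,
#' `<id>_ES.<ext>` and `<id>_labels.csv` as written by [write_case()].
#'
#' @param dir Directory path.
#' @return List of validated [case_record()]s.
#' @export
read_cohort_dir <- function(dir) {
  cov_path <- file.path(dir, "covariates.csv")
  if (!file.exists(cov_path)) {
    stop_cs(sprintf("covariates.csv not found in %s", dir), "io")
  }
  covariates <- read_covariates(cov_path)
  lapply(covariates$case_id, function(id) {
    ed <- Sys.glob(file.path(dir, paste0(id, "_ED.*")))[1]
    es <- Sys.glob(file.path(dir, paste0(id, "_ES.*")))[1]
    lab <- file.path(dir, paste0(id, "_labels.csv"))
    if (is.na(ed) || is.na(es)) {
      stop_cs(sprintf("mesh files for case '%s' not found", id), "io")
    }
    read_case(ed, es, if (file.exists(lab)) lab else NULL,
              covariates = covariates[covariates$case_id == id,
                                      setdiff(names(covariates), "case_id")],
              case_id = id)
  })
}

#' Run the full shape-analysis pipeline
#'
#' Simulates or ingests a cohort, then: generalized Procrustes alignment,
#' ED+ES shape vectors, PCA atlas, morphometric scores, per-mode
#' covariate regression with significant-mode tables and per-predictor
#' variance attribution, remodeling features and geometric strains with
#' cohort summaries and univariate PRVI associations, and
#' regression-predicted shapes at the requested PRVI values. All tables
#' are written as CSV, the report as JSON, the reconstructed shapes as
#' VTK, and a log records the package version, seed, configuration hash
#' and output checksums. The run is a pure function of (inputs, config,
#' seed).
#'
#' @param config A [pipeline_config()].
#' @return The report, a list (invisibly also written to
#'   `report.json`): `variance` (per-mode table), `glance`,
#'   `significant` (per predictor), `attribution`, `feature_summary`,
#'   `feature_prvi`, `strain_summary`, `strain_prvi`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    sim <- generate_cohort(config$simulate)
    cases <- sim$cases
  } else {
    cases <- read_cohort_dir(config$input_dir)
  }
  covariates <- purrr::map_dfr(cases, function(cs) {
    dplyr::bind_cols(tibble::tibble(case_id = cs$case_id), cs$covariates)
  })
  fit <- build_atlas(cases, var_threshold = config$var_threshold,
                     n_modes = config$n_modes)
  atlas <- fit$atlas
  scores <- fit$scores
  mr <- fit_mode_regressions(scores, covariates)
  predictors <- mr$term_labels
  significant <- purrr::map(predictors, function(p) {
    significant_modes(mr, p, config$alpha)
  })
  names(significant) <- predictors
  attribution <- tibble::tibble(
    predictor = predictors,
    rule = config$attribution_rule,
    fraction = vapply(predictors, function(p) {
      suppressWarnings(variance_attributable(mr, atlas, p,
                                             config$attribution_rule,
                                             config$alpha))
    }, numeric(1)))
  report <- list(
    variance = tidy(atlas),
    glance = glance(atlas),
    regression = tidy(mr),
    significant = significant,
    attribution = attribution)
  out <- config$out_dir
  utils::write.csv(tidy(atlas), file.path(out, "atlas_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(scores), file.path(out, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tidy(mr)),
                   file.path(out, "regression_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(attribution),
                   file.path(out, "attribution.csv"), row.names = FALSE)
  if (config$features) {
    feats <- cohort_features(cases, window = config$window)
    fsum <- feature_summary(feats)
    fpr <- feature_prvi_regression(feats, covariates, config$alpha)
    report$feature_summary <- fsum
    report$feature_prvi <- fpr
    utils::write.csv(as.data.frame(feats), file.path(out, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fsum), file.path(out, "feature_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fpr), file.path(out, "feature_prvi.csv"),
                     row.names = FALSE)
  }
  if (config$strain) {
    strains <- cohort_strain(cases, config$levels,
                             m = config$thickness_stations)
    ssum <- strain_summary(strains)
    spr <- strain_prvi_regression(strains, covariates, config$alpha)
    report$strain_summary <- ssum
    report$strain_prvi <- spr
    utils::write.csv(as.data.frame(strains), file.path(out, "strain.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ssum), file.path(out, "strain_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(spr), file.path(out, "strain_prvi.csv"),
                     row.names = FALSE)
  }
  for (v in config$prvi_values) {
    shp <- shape_at_covariates(mr, atlas, list(prvi = v))
    write_mesh(shp$ed, file.path(out, sprintf("shape_prvi%g_ED.vtk", v)))
    write_mesh(shp$es, file.path(out, sprintf("shape_prvi%g_ES.vtk", v)))
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_persist <- config
  cfg_persist$simulate <- if (is.null(config$simulate)) NULL else
    unclass(config$simulate)
  jsonlite::write_json(purrr::discard(unclass(cfg_persist), is.function),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  files <- list.files(out, full.names = TRUE)
  sums <- tools::md5sum(files[!grepl("log[.]txt$", files)])
  log_lines <- c(
    sprintf("cardioshape %s", as.character(utils::packageVersion("cardioshape"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_cases: %d", length(cases)),
    sprintf("config md5: %s", unname(tools::md5sum(file.path(out, "config.json")))),
    "outputs:",
    sprintf("  %s  %s", unname(sums), basename(names(sums))))
  writeLines(log_lines, file.path(out, "log.txt"))
  invisible(report)
}

#' Coefficient plot for per-mode regressions
#'
#' @param object A `biv_modereg`.
#' @param alpha Significance level marking filled points.
#' @param ... Unused.
#' @return A ggplot of standardized parameter estimates by mode and
#'   predictor.
#' @export
autoplot.biv_modereg <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$predictor != "(Intercept)") |>
    dplyr::mutate(significant = .data$p_overall < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$estimate,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$std_error,
      ymax = .data$estimate + 2 * .data$std_error)) +
    ggplot2::facet_wrap(~term) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "mode", y = "standardized estimate (PE)",
                  colour = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
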
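scores_from <- function(md, z) {
  tibble::tibble(case_id = md$covariates$case_id, z1 = z)
}

test_that("standardized OLS agrees with a normal-equations oracle", {
  md <- generate_mode_data(60, effects = NULL, mode_sds = 1, seed = 2)
  set.seed(8)
  sc <- tibble::tibble(case_id = md$covariates$case_id,
                       z1 = rnorm(60), z2 = rnorm(60))
  mr <- fit_mode_regressions(sc, md$covariates)
  d <- shape_design(md$covariates)
  X <- stats::model.matrix(d$formula, d$frame)
  for (k in 1:2) {
    beta_oracle <- solve(crossprod(X), crossprod(X, sc[[paste0("z", k)]]))
    expect_equal(unname(mr$beta[, k]), as.numeric(beta_oracle),
                 tolerance = 1e-8)
  }
  # p-values agree with lm()/drop1 partial F tests
  df <- cbind(d$frame, y = sc$z1)
  fit <- stats::lm(y ~ prvi + height + weight + age + sex + tr_grade, df)
  dr <- stats::drop1(fit, test = "F")
  expect_equal(unname(mr$pvals[, 1]),
               unname(dr[["Pr(>F)"]][match(mr$term_labels, rownames(dr))]),
               tolerance = 1e-10)
  expect_equal(unname(mr$r2[1]), summary(fit)$r.squared, tolerance = 1e-10)
})

test_that("design matrix is standardized and rejects degenerate input", {
  cov <- generate_covariates(50, seed = 3)
  d <- shape_design(cov)
  for (v in d$continuous) {
    expect_lt(abs(mean(d$frame[[v]])), 1e-10)
    expect_equal(sd(d$frame[[v]]), 1, tolerance = 1e-12)
  }
  cov2 <- cov; cov2$prvi <- 25
  expect_error(shape_design(cov2), class = "cardioshape_error_degenerate")
  cov3 <- cov; cov3$age[2] <- NA
  expect_error(shape_design(cov3), class = "cardioshape_error_domain")
})

test_that("a planted standardized effect is recovered with significance", {
  md <- generate_mode_data(
    200, effects = matrix(0.5, 1, 1, dimnames = list(NULL, "prvi")),
    mode_sds = 1, seed = 10)
  mr <- fit_mode_regressions(scores_from(md, md$scores[, 1]), md$covariates)
  pe <- mr$beta["prvi", 1]
  se <- mr$se["prvi", 1]
  expect_lt(abs(pe - 0.5), 3 * se)
  expect_lt(mr$pvals["prvi", 1], 0.05)
})

test_that("duplicated predictors raise a collinearity error naming them", {
  cov <- generate_covariates(40, seed = 5)
  cov$weight <- cov$height  # duplicate column after standardization
  set.seed(1)
  sc <- tibble::tibble(case_id = cov$case_id, z1 = rnorm(40))
  err <- expect_error(fit_mode_regressions(sc, cov),
                      class = "cardioshape_error_collinearity")
  expect_match(conditionMessage(err), "weight")
})

test_that("significant-mode selection follows planted effects and alpha", {
  B <- matrix(0, 3, 1, dimnames = list(NULL, "prvi"))
  B[c(1, 3), 1] <- 0.6
  md <- generate_mode_data(400, effects = B, mode_sds = c(1, 1, 1), seed = 20)
  sc <- tibble::tibble(case_id = md$covariates$case_id,
                       z1 = md$scores[, 1], z2 = md$scores[, 2],
                       z3 = md$scores[, 3])
  mr <- fit_mode_regressions(sc, md$covariates)
  expect_identical(significant_modes(mr, "prvi", 0.05)$mode, c(1L, 3L))
  expect_identical(nrow(significant_modes(mr, "prvi", 0)), 0L)
  expect_identical(significant_modes(mr, "prvi", 1)$mode, 1:3)
  expect_error(significant_modes(mr, "bmi"), class = "cardioshape_error_key")
  # categorical overall effect is a block F-test (pe is NA per mode)
  sx <- significant_modes(mr, "tr_grade", 1)
  expect_true(all(is.na(sx$pe)))
})

test_that("Benjamini-Hochberg option adjusts across modes", {
  B <- matrix(c(0.5, 0, 0), 3, 1, dimnames = list(NULL, "prvi"))
  md <- generate_mode_data(150, effects = B, mode_sds = rep(1, 3), seed = 30)
  sc <- tibble::tibble(case_id = md$covariates$case_id,
                       z1 = md$scores[, 1], z2 = md$scores[, 2],
                       z3 = md$scores[, 3])
  raw <- fit_mode_regressions(sc, md$covariates)
  bh <- fit_mode_regressions(sc, md$covariates, p_adjust = "BH")
  expect_equal(unname(bh$pvals["prvi", ]),
               unname(stats::p.adjust(raw$pvals["prvi", ], "BH")),
               tolerance = 1e-12)
})

test_that("attribution reduces to f1 * PE^2 in the single-mode case", {
  md <- generate_mode_data(
    2000, effects = matrix(0.5, 1, 1, dimnames = list(NULL, "prvi")),
    mode_sds = 1, seed = 40)
  mr <- fit_mode_regressions(scores_from(md, md$scores[, 1]), md$covariates)
  atlas1 <- structure(list(frac = 1), class = "biv_atlas")
  pe <- mr$beta["prvi", 1]
  # pe2 rule is the analytic identity; sr2 matches it when the predictor
  # is (near) orthogonal to the other covariates
  expect_equal(variance_attributable(mr, atlas1, "prvi", rule = "pe2"),
               pe^2, tolerance = 1e-12)
  expect_equal(variance_attributable(mr, atlas1, "prvi", rule = "sr2"),
               pe^2, tolerance = 0.02)
  expect_equal(variance_attributable(mr, atlas1, "prvi", rule = "fsum"), 1)
})

test_that("attribution matches the sum f_k * sr2_k oracle on planted data", {
  B <- matrix(c(0.5, 0.3), 2, 1, dimnames = list(NULL, "prvi"))
  vals <- vapply(1:20, function(s) {
    md <- generate_mode_data(300, effects = B, mode_sds = c(2, 1), seed = s)
    sc <- tibble::tibble(case_id = md$covariates$case_id,
                         z1 = md$scores[, 1], z2 = md$scores[, 2])
    mr <- fit_mode_regressions(sc, md$covariates)
    atl <- structure(list(frac = c(0.8, 0.2)), class = "biv_atlas")
    got <- suppressWarnings(variance_attributable(mr, atl, "prvi"))
    # independent semi-partial oracle: sr2 = t^2 (1 - R2) / df_res per mode
    oracle <- sum(vapply(1:2, function(k) {
      if (mr$pvals["prvi", k] >= 0.05) return(0)
      tstat <- mr$beta["prvi", k] / mr$se["prvi", k]
      c(0.8, 0.2)[k] * tstat^2 * (1 - mr$r2[k]) / mr$df_res
    }, numeric(1)))
    c(got - oracle)
  }, numeric(1))
  expect_lt(max(abs(vals)), 1e-10)
})

test_that("attribution vanishes for a null predictor and grows with effect", {
  md <- generate_mode_data(500, effects = NULL, mode_sds = c(1, 1), seed = 50)
  sc <- tibble::tibble(case_id = md$covariates$case_id,
                       z1 = md$scores[, 1], z2 = md$scores[, 2])
  mr <- fit_mode_regressions(sc, md$covariates)
  atl <- structure(list(frac = c(0.7, 0.3)), class = "biv_atlas")
  att0 <- suppressWarnings(variance_attributable(mr, atl, "prvi"))
  expect_lt(att0, 0.01)
  # monotone non-decreasing in the planted effect size
  atts <- vapply(c(0.2, 0.4, 0.6), function(b) {
    mdb <- generate_mode_data(
      500, effects = matrix(b, 1, 1, dimnames = list(NULL, "prvi")),
      mode_sds = 1, seed = 60)
    mrb <- fit_mode_regressions(scores_from(mdb, mdb$scores[, 1]),
                                mdb$covariates)
    suppressWarnings(variance_attributable(
      mrb, structure(list(frac = 1), class = "biv_atlas"), "prvi"))
  }, numeric(1))
  expect_true(all(diff(atts) > 0))
})

test_that("replacing height+weight by BSA keeps the PRVI pattern", {
  md <- generate_mode_data(
    250, effects = matrix(0.6, 1, 1, dimnames = list(NULL, "prvi")),
    mode_sds = 1, seed = 70)
  sc <- scores_from(md, md$scores[, 1])
  m1 <- fit_mode_regressions(sc, md$covariates)
  m2 <- fit_mode_regressions(sc, md$covariates, use_bsa = TRUE)
  expect_identical(sign(m1$beta["prvi", 1]), sign(m2$beta["prvi", 1]))
  expect_lt(m1$pvals["prvi", 1], 0.05)
  expect_lt(m2$pvals["prvi", 1], 0.05)
  expect_true("bsa" %in% m2$term_labels)
})

test_that("regression-predicted shapes behave linearly about the mean", {
  fit <- get_atlas_fit()
  truth <- get_cohort()$truth
  mr <- fit_mode_regressions(fit$scores, truth$covariates)
  atl <- fit$atlas
  # all covariates at training means -> the atlas mean shape exactly
  at_mean <- shape_at_covariates(mr, atl, list())
  expect_equal(at_mean$vector, atl$mu, tolerance = 1e-8)
  expect_equal(at_mean$ed$points,
               split_shape_vector(atl, atl$mu)$ed$points, tolerance = 1e-8)
  sc <- mr$design$scaling$prvi
  hi <- shape_at_covariates(mr, atl, list(prvi = sc$mean + sc$sd))
  lo <- shape_at_covariates(mr, atl, list(prvi = sc$mean - sc$sd))
  expect_equal((hi$vector + lo$vector) / 2, atl$mu, tolerance = 1e-8)
  # algebraic oracle: shape change per SD of prvi along each mode
  dz <- hi$scores - at_mean$scores
  expect_equal(dz, unname(mr$beta["prvi", ]), tolerance = 1e-10)
  expected_dx <- as.numeric(atl$modes[, seq_along(dz), drop = FALSE] %*%
                              (dz * sqrt(atl$lambda[seq_along(dz)])))
  expect_equal(hi$vector - at_mean$vector, expected_dx, tolerance = 1e-9)
  expect_warning(shape_at_covariates(mr, atl, list(prvi = sc$mean + 6 * sc$sd)),
                 class = "cardioshape_warning_extrapolation")
  expect_error(shape_at_covariates(mr, atl, list(bmi = 2)),
               class = "cardioshape_error_key")
  # significant-only variant zeroes the other modes
  sig <- significant_modes(mr, "prvi")$mode
  hi_sig <- shape_at_covariates(mr, atl, list(prvi = sc$mean + sc$sd),
                                modes = "significant", predictor = "prvi")
  expect_true(all(hi_sig$scores[setdiff(seq_along(dz), sig)] == 0))
})

test_that("displacement maps carry the outward-from-LV sign convention", {
  sph <- fixture_sphere(radius = 10, subdiv = 3)
  expect_true(all(displacement_map(sph, sph)$signed == 0))
  grown <- scale_mesh(sph, 1.1, about = c(0, 0, 0))
  dm <- displacement_map(sph, grown)
  expect_equal(dm$magnitude, rep(1, nrow(sph$points)), tolerance = 1e-9)
  expect_true(all(dm$signed > 0))
  shrunk <- scale_mesh(sph, 0.9, about = c(0, 0, 0))
  expect_true(all(displacement_map(sph, shrunk)$signed < 0))
  expect_error(displacement_map(sph, get_coarse_template()$ed),
               class = "cardioshape_error_correspondence")
  # ED -> ES motion on the template: endocardial contraction is inward
  tpl <- get_coarse_template()
  dm2 <- displacement_map(tpl$ed, tpl$es)
  lv <- dm2$label == "LV_ENDO"
  expect_gt(mean(dm2$signed[lv] < 0), 0.8)
})

test_that("null cohorts preserve the nominal type-I error rate", {
  hits <- vapply(1:400, function(s) {
    md <- generate_mode_data(120, effects = NULL, mode_sds = 1, seed = 5000 + s)
    mr <- fit_mode_regressions(scores_from(md, md$scores[, 1]), md$covariates)
    mr$pvals["prvi", 1] < 0.05
  }, logical(1))
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})
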
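test_that("basal bulge recovers a planted height and clamps at zero", {
  fx <- fixture_bulge(height = 12, params = coarse_params(
    tricuspid_tilt = 0, rv_cut_height = 5))
  expect_equal(basal_bulge(fx), 12, tolerance = 1e-9)
  # entire free wall apical to the base plane: clamped at 0, signed < 0
  flat <- make_template(coarse_params(tricuspid_tilt = 0, rv_cut_height = 5),
                        validate = FALSE)$ed
  expect_identical(basal_bulge(flat), 0)
  expect_lt(basal_bulge(flat, signed = TRUE), 0)
  # rigid invariance
  tr <- rigid_pair(11)
  expect_equal(basal_bulge(transform_mesh(fx, tr$R, tr$t)), 12,
               tolerance = 1e-9)
})

test_that("tricuspid tilt recovers the constructed annulus angle", {
  for (ang in c(0, 30, 41.6)) {
    mesh <- make_template(coarse_params(tricuspid_tilt = ang))$ed
    expect_equal(tricuspid_tilt(mesh), ang, tolerance = 1e-6)
  }
  # noisy planar ring: recovered within 1 degree
  mesh <- make_template(coarse_params(tricuspid_tilt = 30))$ed
  set.seed(2)
  ring <- label_vertices(mesh, "TRICUSPID_RING")
  mesh$points[ring, ] <- mesh$points[ring, ] + matrix(rnorm(3 * length(ring),
                                                            0, 0.1), ncol = 3)
  expect_lt(abs(tricuspid_tilt(mesh) - 30), 1)
  # collinear ring is a degenerate fit
  bad <- make_template(coarse_params())$ed
  ring <- label_vertices(bad, "TRICUSPID_RING")
  bad$points[ring, ] <- outer(seq_along(ring), c(1, 0, 0)) + 50
  expect_error(tricuspid_tilt(bad), class = "cardioshape_error_degenerate")
})

test_that("apical angle matches straight-line constructions", {
  expect_equal(apical_angle(fixture_apical_angle(60)), 60, tolerance = 0.5)
  expect_equal(apical_angle(fixture_apical_angle(90)), 90, tolerance = 0.5)
  expect_equal(apical_angle(fixture_apical_angle(120)), 120, tolerance = 0.5)
  # window = 100% on an exactly straight free wall equals the global fit
  fx <- fixture_apical_angle(75)
  expect_equal(apical_angle(fx, window = 1), apical_angle(fx, window = 0.3),
               tolerance = 1e-6)
  # rigid invariance
  tr <- rigid_pair(13)
  expect_equal(apical_angle(transform_mesh(fx, tr$R, tr$t)),
               apical_angle(fx), tolerance = 1e-6)
})

test_that("mid-ventricular dimensions recover cylinder cross-sections", {
  circ <- fixture_walls(rx_endo = 20, ry_endo = 20, rx_epi = 45, ry_epi = 45,
                        rv = TRUE, rv_center = c(60, 0, 0))
  d <- midventricular_dimensions(circ)
  expect_equal(d$d1, 40, tolerance = 0.2)
  expect_equal(d$d4, 40, tolerance = 0.2)
  expect_equal(d$d3, 2 * 20, tolerance = 0.2)   # rv cup rx = 20
  expect_equal(d$d2, 2 * 35, tolerance = 0.2)   # rv cup ry = 35
  # ellipse oriented with the septal (anterior-posterior) direction
  ell <- fixture_walls(rx_endo = 20, ry_endo = 27, rx_epi = 45, ry_epi = 45,
                       rv = TRUE, rv_center = c(60, 0, 0))
  de <- midventricular_dimensions(ell)
  expect_equal(de$d1, 40, tolerance = 0.2)
  expect_equal(de$d4, 54, tolerance = 0.2)
  # rigid invariance
  tr <- rigid_pair(17)
  dt <- midventricular_dimensions(transform_mesh(ell, tr$R, tr$t))
  expect_equal(as.numeric(dt), as.numeric(de), tolerance = 1e-6)
})

test_that("features vary monotonically with their template parameter", {
  bulges <- vapply(c(0, 6, 12), function(b) {
    basal_bulge(make_template(coarse_params(
      tricuspid_tilt = 0, rv_cut_height = 8, bulge_mm = b),
      validate = FALSE)$ed, signed = TRUE)
  }, numeric(1))
  expect_true(all(diff(bulges) > 0))
  tilts <- vapply(c(10, 25, 40), function(a) {
    tricuspid_tilt(make_template(coarse_params(tricuspid_tilt = a))$ed)
  }, numeric(1))
  expect_true(all(diff(tilts) > 0))
})

test_that("case features cover both phases and systole shrinks the LV", {
  feats <- case_features(get_coarse_template())
  expect_identical(feats$phase, c("ED", "ES"))
  expect_lt(feats$d1[feats$phase == "ES"], feats$d1[feats$phase == "ED"])
  expect_equal(feats$tricuspid_tilt[1], 40, tolerance = 0.5)
  sm <- feature_summary(dplyr::bind_rows(feats, feats))
  expect_identical(sort(unique(sm$feature)),
                   sort(c("basal_bulge", "tricuspid_tilt", "apical_angle",
                          "d1", "d2", "d3", "d4")))
  expect_true(all(sm$n == 2))
})

test_that("feature regressions recover a planted slope on PRVI", {
  cov <- generate_covariates(200, seed = 91)
  set.seed(92)
  x <- as.numeric(scale(cov$prvi))
  feats <- tibble::tibble(case_id = cov$case_id, phase = "ED",
                          basal_bulge = 16 + 4 * (0.3 * x +
                                                    sqrt(1 - 0.09) * rnorm(200)))
  out <- feature_prvi_regression(feats, cov)
  se <- sqrt((1 - out$pe^2) / (200 - 2))
  expect_lt(abs(out$pe - 0.3), 3 * se)
  expect_lt(out$p, 0.05)
  expect_false(is.na(out$pe_reported))
  # non-significant associations are withheld from the reported column
  feats$noise <- rnorm(200)
  out2 <- feature_prvi_regression(feats, cov)
  expect_true(is.na(out2$pe_reported[out2$measure == "noise"]) ||
                out2$p[out2$measure == "noise"] < 0.05)
  # constant feature is degenerate
  feats$flat <- 1
  expect_error(feature_prvi_regression(feats, cov),
               class = "cardioshape_error_degenerate")
})

test_that("permuted PRVI yields uniform univariate p-values", {
  cov <- generate_covariates(80, seed = 93)
  set.seed(94)
  y <- rnorm(80)
  ps <- vapply(1:200, function(i) {
    cov2 <- cov
    cov2$prvi <- sample(cov2$prvi)
    feats <- tibble::tibble(case_id = cov2$case_id, phase = "ED", f = y)
    feature_prvi_regression(feats, cov2)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
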
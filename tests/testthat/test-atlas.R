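make_cases <- function(meshes_ed, meshes_es = meshes_ed, ids = NULL) {
  ids <- ids %||% sprintf("c%02d", seq_along(meshes_ed))
  Map(function(ed, es, id) {
    ed$case_id <- id; es$case_id <- id; es$phase <- "ES"
    case_record(id, ed, es)
  }, meshes_ed, meshes_es, ids)
}

test_that("alignment of identical meshes leaves residuals at zero", {
  tpl <- get_coarse_template()$ed
  cases <- make_cases(rep(list(tpl), 4))
  al <- procrustes_align(cases)
  expect_true(al$converged)
  for (cs in al$cases) {
    expect_lt(max(abs(cs$ed$points - al$mean_points)), 1e-10)
  }
  expect_error(procrustes_align(cases[1]), class = "cardioshape_error_cohort")
})

test_that("a rigidly moved copy aligns back exactly", {
  tpl <- get_coarse_template()$ed
  tr <- rigid_pair(3)
  moved <- transform_mesh(tpl, tr$R, tr$t)
  al <- procrustes_align(make_cases(list(tpl, moved)))
  rmsd <- sqrt(mean((al$cases[[1]]$ed$points - al$cases[[2]]$ed$points)^2))
  expect_lt(rmsd, 1e-8)
})

test_that("random rigid perturbations collapse onto the template", {
  tpl <- get_coarse_template()$ed
  set.seed(42)
  meshes <- lapply(1:10, function(i) {
    transform_mesh(tpl, random_rotation(), runif(3, -30, 30))
  })
  al <- procrustes_align(make_cases(meshes))
  # every aligned case matches the consensus to floating precision
  for (cs in al$cases) {
    expect_lt(sqrt(mean((cs$ed$points - al$mean_points)^2)), 1e-6)
  }
  # and the consensus is the template up to one global rigid transform:
  # closed-form Kabsch as the independent per-pair oracle
  fit <- kabsch(al$mean_points, tpl$points)
  resid <- apply_rigid(al$mean_points, fit$R, fit$t) - tpl$points
  expect_lt(max(abs(resid)), 1e-6)
  # objective is non-increasing across iterations
  expect_true(all(diff(al$objective) <= 1e-10))
})

test_that("ES meshes receive the ED transform unchanged", {
  tpl <- get_coarse_template()
  tr <- rigid_pair(9)
  moved <- transform_case(tpl, tr$R, tr$t)
  moved$ed$case_id <- moved$es$case_id <- "m"
  moved <- case_record("m", moved$ed, moved$es)
  al <- procrustes_align(list(
    case_record("a", tpl$ed, tpl$es), moved))
  # aligned ED equal => aligned ES must also be equal (same transform)
  expect_lt(max(abs(al$cases[[1]]$es$points - al$cases[[2]]$es$points)), 1e-7)
})

test_that("shape vectors concatenate ED then ES in template order", {
  tpl <- get_coarse_template()
  n <- nrow(tpl$ed$points)
  cases <- list(case_record("a", tpl$ed, tpl$es),
                case_record("b", tpl$ed, tpl$ed))  # ED == ES
  X <- build_shape_vectors(cases)
  expect_equal(dim(X), c(2L, 6L * n))
  expect_equal(X["b", seq_len(3 * n)], X["b", 3 * n + seq_len(3 * n)],
               ignore_attr = TRUE)
  expect_equal(X["a", seq_len(3 * n)], as.vector(t(tpl$ed$points)),
               ignore_attr = TRUE)
  # permuted-vertex input is rejected by correspondence validation
  perm <- tpl$ed
  a <- which(perm$labels == "LV_ENDO")[1]
  b <- which(perm$labels == "MITRAL_RING")[1]
  i <- seq_len(n); i[c(a, b)] <- c(b, a)
  perm$points <- perm$points[i, ]
  perm$labels <- perm$labels[i]
  expect_error(build_shape_vectors(list(cases[[1]],
                                        case_record("c", perm, perm))),
               class = "cardioshape_error_correspondence")
})

test_that("an identical-shape cohort yields a zero-mode atlas", {
  tpl <- get_coarse_template()
  X <- build_shape_vectors(make_cases(rep(list(tpl$ed), 3),
                                      rep(list(tpl$es), 3)))
  expect_warning(atl <- fit_shape_atlas(X),
                 class = "cardioshape_warning_degenerate")
  expect_identical(atl$K, 0L)
  expect_length(atl$lambda, 0)
})

test_that("PCA recovers planted orthogonal modes and their variances", {
  sim <- generate_cohort(synthetic_cohort_spec(
    n_cases = 200, params = coarse_params(), mode_sds = c(2, 1),
    noise_sd = 0, effects = NULL, rigid_jitter = c(0, 0), seed = 11))
  X <- build_shape_vectors(sim$cases)
  atl <- fit_shape_atlas(X)
  # variance fractions 0.8 / 0.2 within 3 standard errors
  se_f <- 0.8 * 0.2 * sqrt(2 / 200 + 2 / 200)
  expect_lt(abs(atl$frac[1] - 0.8), 3 * se_f)
  expect_lt(abs(atl$frac[2] - 0.2), 3 * se_f)
  expect_identical(length(atl$lambda), 2L)  # exact rank
  # principal angles between planted and recovered subspaces < 2 degrees
  sv <- svd(crossprod(sim$truth$modes, atl$modes[, 1:2]))$d
  expect_lt(max(acos(pmin(sv, 1))) * 180 / pi, 2)
  # eigenvalues equal those of the planted-coordinate sample covariance
  expect_equal(atl$lambda, eigen(stats::cov(sim$truth$coords))$values,
               tolerance = 1e-8)
})

test_that("training shapes reconstruct exactly from all modes", {
  fit <- get_atlas_fit()
  atl <- fit$atlas
  all_scores <- score_shapes(atl, fit$X, modes = seq_along(atl$lambda))
  for (i in c(1, nrow(fit$X))) {
    z <- as.numeric(all_scores[i, -1])
    x <- reconstruct_shape(atl, z, as_mesh = FALSE)
    expect_lt(max(abs(x - fit$X[i, ])), 1e-6)
  }
})

test_that("morphometric scores are standardized projections", {
  fit <- get_atlas_fit()
  atl <- fit$atlas
  expect_equal(as.numeric(score_shapes(atl, atl$mu)[1, -1]),
               rep(0, atl$K), tolerance = 1e-10)
  x1 <- atl$mu + sqrt(atl$lambda[1]) * atl$modes[, 1]
  z <- as.numeric(score_shapes(atl, x1)[1, -1])
  expect_equal(z, c(1, rep(0, atl$K - 1)), tolerance = 1e-8)
  # unit sample variance over the training cohort
  expect_equal(unname(apply(as.matrix(fit$scores[, -1]), 2, var)),
               rep(1, atl$K), tolerance = 1e-6)
  # raw projections differ by the sqrt(lambda) factor
  raw <- score_shapes(atl, x1, standardize = FALSE)
  expect_equal(raw$raw1, sqrt(atl$lambda[1]), tolerance = 1e-8)
})

test_that("reconstruction is linear and round-trips scores", {
  fit <- get_atlas_fit()
  atl <- fit$atlas
  expect_equal(reconstruct_shape(atl, numeric(0), as_mesh = FALSE), atl$mu)
  up <- reconstruct_shape(atl, c(2, rep(0, atl$K - 1)), as_mesh = FALSE)
  dn <- reconstruct_shape(atl, c(-2, rep(0, atl$K - 1)), as_mesh = FALSE)
  expect_equal((up + dn) / 2, atl$mu, tolerance = 1e-9)
  set.seed(1)
  z <- rnorm(atl$K)
  back <- score_shapes(atl, reconstruct_shape(atl, z, as_mesh = FALSE))
  expect_equal(as.numeric(back[1, -1]), z, tolerance = 1e-8)
  # meshes split on template connectivity
  rec <- reconstruct_shape(atl, z)
  expect_s3_class(rec$ed, "biv_mesh")
  expect_identical(rec$ed$faces, atl$template$faces)
})

test_that("retained-mode selection reproduces hand computation", {
  expect_identical(n_modes_for_fraction(c(4, 3, 2, 1), 0.90), 3L)
  expect_identical(n_modes_for_fraction(c(4, 3, 2, 1), 0.95), 4L)
  expect_identical(n_modes_for_fraction(c(4, 3, 2, 1), 0.40), 1L)
  expect_identical(n_modes_for_fraction(c(4, 3, 2, 1), 1.00), 4L)
  expect_error(n_modes_for_fraction(c(1, 1), 1.2),
               class = "cardioshape_error_domain")
  fit <- get_atlas_fit()
  atl <- fit$atlas
  expect_identical(atl$K, n_modes_for_fraction(atl$lambda, atl$var_threshold))
  # variance fractions sum to one; cumulative fraction non-decreasing
  expect_equal(sum(atl$frac), 1, tolerance = 1e-12)
  expect_true(all(diff(atl$cumfrac) >= -1e-15))
  expect_true(all(diff(atl$lambda) <= 1e-9))
})

test_that("atlas spectrum is invariant to rigid pre-transformation", {
  cohort <- get_cohort()$cases[1:10]
  set.seed(5)
  moved <- lapply(cohort, function(cs) {
    transform_case(cs, random_rotation(), runif(3, -25, 25))
  })
  a1 <- build_atlas(cohort)$atlas
  a2 <- build_atlas(moved)$atlas
  k <- seq_len(min(8, length(a1$lambda), length(a2$lambda)))
  expect_equal(a1$lambda[k], a2$lambda[k], tolerance = 1e-6)
})

test_that("recovered leading eigenvalue matches planted + noise variance", {
  lam1 <- vapply(1:20, function(s) {
    sim <- suppressWarnings(generate_cohort(synthetic_cohort_spec(
      n_cases = 40, params = coarse_params(), mode_kinds = "size",
      mode_sds = 3, noise_sd = 0.3, effects = NULL,
      rigid_jitter = c(0, 0), seed = s)))
    X <- build_shape_vectors(sim$cases)
    fit_shape_atlas(X)$lambda[1]
  }, numeric(1))
  npts6 <- 6 * nrow(get_coarse_template()$ed$points)
  expected <- (3 * sqrt(npts6))^2 + 0.3^2
  # mean over seeds within 3 SEs of sigma^2_planted + sigma^2_noise
  se <- expected * sqrt(2 / 39) / sqrt(20)
  expect_lt(abs(mean(lam1) - expected), 3 * se)
})

test_that("atlas tidiers and scree plot expose the variance table", {
  atl <- get_atlas_fit()$atlas
  td <- tidy(atl)
  expect_identical(names(td), c("mode", "variance", "frac", "cumfrac",
                                "retained"))
  expect_identical(sum(td$retained), atl$K)
  gl <- glance(atl)
  expect_identical(gl$K, atl$K)
  p <- ggplot2::autoplot(atl)
  expect_s3_class(p, "ggplot")
})
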
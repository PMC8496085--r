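scaled_case <- function(s, params = coarse_params()) {
  tpl <- make_template(params)
  es <- tpl$ed
  es$phase <- "ES"
  es <- scale_mesh(es, s, about = colMeans(tpl$ed$points))
  case_record("scaled", tpl$ed, es)
}

test_that("Cauchy strain is elementary arithmetic with a guarded domain", {
  expect_identical(cauchy_strain(10, 10), 0)
  expect_equal(cauchy_strain(8, 10), -0.2)
  expect_equal(cauchy_strain(c(12, 9), c(10, 10)), c(0.2, -0.1))
  expect_error(cauchy_strain(5, 0), class = "cardioshape_error_domain")
  expect_error(cauchy_strain(5, -1), class = "cardioshape_error_domain")
})

test_that("circumferential arcs converge to 2*pi*r on a cylinder", {
  for (n_seg in c(64, 256)) {
    cup <- fixture_walls(rx_endo = 20, ry_endo = 20, n_seg = n_seg)
    fr <- reference_frame(cup)
    for (t in strain_levels()) {
      arc <- cardioshape:::circ_arc(cup, fr, "LV", t)
      expect_equal(arc, 2 * pi * 20,
                   tolerance = if (n_seg >= 256) 0.002 else 0.01)
    }
  }
})

test_that("a uniformly scaled ES gives CS = LS = s - 1 exactly", {
  cs <- scaled_case(0.9)
  circ <- circumferential_arcs(cs)
  expect_equal(cauchy_strain(circ$L, circ$L0), rep(-0.1, nrow(circ)),
               tolerance = 1e-9)
  long <- suppressWarnings(longitudinal_arcs(cs))
  ok <- !is.na(long$L0)
  expect_equal(cauchy_strain(long$L[ok], long$L0[ok]),
               rep(-0.1, sum(ok)), tolerance = 1e-9)
})

test_that("strains vanish for identical phases and under rigid motion", {
  tpl <- get_coarse_template()
  same <- case_record("same", tpl$ed, {
    es <- tpl$ed; es$phase <- "ES"; es
  })
  st <- suppressWarnings(case_strain(same, m = 24))
  expect_lt(max(abs(st$value)), 1e-8)
  tr <- rigid_pair(23)
  moved <- case_record("rigid", tpl$ed, {
    es <- transform_mesh(tpl$ed, tr$R, tr$t); es$phase <- "ES"; es
  })
  st2 <- suppressWarnings(case_strain(moved, m = 24))
  expect_lt(max(abs(st2$value)), 1e-6)
})

test_that("strain computation commutes with rigid transforms of the case", {
  tpl <- get_coarse_template()
  st <- suppressWarnings(case_strain(tpl, m = 24))
  tr <- rigid_pair(29)
  st2 <- suppressWarnings(case_strain(transform_case(tpl, tr$R, tr$t), m = 24))
  expect_equal(st2$value, st$value, tolerance = 1e-6)
})

test_that("centerline thickness is exact on concentric circles", {
  cup <- fixture_walls(rx_endo = 30, ry_endo = 30, rx_epi = 40, ry_epi = 40)
  fr <- reference_frame(cup)
  expect_equal(wall_thickness(cup, fr, "LV", 0.5), 10, tolerance = 0.05)
  # identical surfaces give zero thickness
  flat <- fixture_walls(rx_endo = 30, ry_endo = 30, rx_epi = 30, ry_epi = 30)
  expect_lt(wall_thickness(flat, reference_frame(flat), "LV", 0.5), 1e-6)
  # crossed contours are a geometry error
  crossed <- fixture_walls(rx_endo = 42, ry_endo = 42, rx_epi = 40,
                           ry_epi = 40)
  expect_error(wall_thickness(crossed, reference_frame(crossed), "LV", 0.5),
               class = "cardioshape_error_geometry")
})

test_that("elliptical-wall thickness matches a dense 2D sampling oracle", {
  cup <- fixture_walls(rx_endo = 32, ry_endo = 26, rx_epi = 40, ry_epi = 34,
                       n_seg = 128)
  fr <- reference_frame(cup)
  got <- wall_thickness(cup, fr, "LV", 0.5, m = 50)
  # independent oracle: dense polygons, nearest-pair midpoints as the
  # centerline, thickness = endo->epi crossing distance along the local
  # centerline normal computed by brute-force segment intersection
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  endo <- cbind(32 * cos(th), 26 * sin(th))
  epi <- cbind(40 * cos(th), 34 * sin(th))
  mids <- t(vapply(seq(1, 4000, by = 80), function(i) {
    d2 <- (epi[, 1] - endo[i, 1])^2 + (epi[, 2] - endo[i, 2])^2
    (endo[i, ] + epi[which.min(d2), ]) / 2
  }, numeric(2)))
  m <- nrow(mids)
  oracle <- vapply(seq_len(m), function(k) {
    kp <- if (k < m) k + 1 else 1
    km <- if (k > 1) k - 1 else m
    tang <- mids[kp, ] - mids[km, ]
    u <- c(-tang[2], tang[1]); u <- u / sqrt(sum(u^2))
    cross_d <- function(P) {
      tt <- cardioshape:::line_polyline_crossings(P, mids[k, ], u)
      tt[which.min(abs(tt))]
    }
    abs(cross_d(epi) - cross_d(endo))
  }, numeric(1))
  expect_equal(got, mean(oracle), tolerance = 0.01)
})

test_that("radial strain reproduces planted wall thickening", {
  ed <- fixture_walls(rx_endo = 30, ry_endo = 30, rx_epi = 40, ry_epi = 40)
  es <- fixture_walls(rx_endo = 30, ry_endo = 30, rx_epi = 42, ry_epi = 42)
  es$phase <- "ES"
  cs <- case_record("thick", ed, es)
  rs <- radial_strain(cs, m = 40, chambers = "LV")
  lv <- rs[rs$chamber == "LV", ]
  expect_equal(lv$rs, rep(0.2, 3), tolerance = 0.02)
  # arithmetic identity: thickness 10 -> 12 means +20 percent
  expect_equal(cauchy_strain(12, 10), 0.2)
})

test_that("template strain set carries the planted contraction", {
  tpl <- get_coarse_template()
  st <- suppressWarnings(case_strain(tpl, m = 30))
  cs_lv <- st$value[st$chamber == "LV" & st$kind == "CS" &
                      st$component == "global"]
  expect_equal(cs_lv, -18, tolerance = 1e-6)  # endocardial map plants -cr
  rv_rs <- st$value[st$chamber == "RV" & st$kind == "RS" &
                      st$component == "global"]
  expect_equal(rv_rs, 25, tolerance = 3)      # planted wall_thicken = 0.25
  # global values are the stated averages of their components
  for (ch in c("LV", "RV")) {
    for (kd in c("CS", "LS", "RS")) {
      comp <- st$value[st$chamber == ch & st$kind == kd &
                         st$component != "global"]
      glob <- st$value[st$chamber == ch & st$kind == kd &
                         st$component == "global"]
      expect_equal(glob, mean(comp), tolerance = 1e-9)
    }
  }
})

test_that("cohort strain table reports absolute CS/LS and signed RS", {
  tpl <- get_coarse_template()
  tab <- suppressWarnings(cohort_strain(list(tpl), m = 24))
  expect_gt(tab$lv_cs, 0)
  expect_gt(tab$lv_ls, 0)
  expect_gt(tab$rv_rs, 0)
  sm <- strain_summary(dplyr::bind_rows(tab, tab))
  expect_identical(sort(sm$measure),
                   sort(c("lv_ls", "lv_cs", "lv_rs", "rv_ls", "rv_cs",
                          "rv_rs")))
})

test_that("strain regressions recover planted slopes and reject constants", {
  cov <- generate_covariates(200, seed = 95)
  set.seed(96)
  x <- as.numeric(scale(cov$prvi))
  strains <- tibble::tibble(
    case_id = cov$case_id,
    rv_rs = 20 + 12 * (0.37 * x + sqrt(1 - 0.37^2) * rnorm(200)),
    lv_cs = 20 + 5 * rnorm(200))
  out <- strain_prvi_regression(strains, cov)
  pe <- out$pe[out$measure == "rv_rs"]
  expect_lt(abs(pe - 0.37), 3 * sqrt((1 - 0.37^2) / 198))
  expect_lt(out$p[out$measure == "rv_rs"], 0.05)
  # permutation null keeps type-I near alpha
  hits <- vapply(1:200, function(i) {
    cov2 <- cov
    cov2$prvi <- sample(cov2$prvi)
    strain_prvi_regression(strains["lv_cs" != "", c("case_id", "lv_cs")],
                           cov2)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  strains$flat <- 3
  expect_error(strain_prvi_regression(strains, cov),
               class = "cardioshape_error_degenerate")
})
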
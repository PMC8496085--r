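# Model-derived remodeling features: basal bulge, tricuspid tilt, apical
# angle and mid-ventricular cavity dimensions, plus their univariate
# associations with PRVI. All features are rigid-invariant because they are
# built from the mesh's own reference frame.

#' Basal bulge of the RV free wall
#'
#' Distance from the most basal RV free-wall point to its perpendicular
#' projection onto the base plane (perpendicular to the LV long axis
#' through the mitral centroid); equivalently the maximal signed height of
#' free-wall vertices above that plane, clamped at 0 when the whole free
#' wall lies apical to it (`signed = TRUE` returns the unclamped value).
#'
#' @param mesh A [biv_mesh()].
#' @param frame Its [reference_frame()] (recomputed when omitted).
#' @param signed Return the signed height instead of clamping at 0.
#' @return Bulge height in mm.
#' @export
basal_bulge <- function(mesh, frame = reference_frame(mesh), signed = FALSE) {
  fw <- label_vertices(mesh, "RV_FREEWALL_ENDO")
  if (length(fw) == 0) {
    stop_cs("labeling error: no RV_FREEWALL_ENDO vertices", "labeling")
  }
  h <- as.numeric(sweep(mesh$points[fw, , drop = FALSE], 2,
                        frame$base_plane$point) %*% frame$lv_long_axis)
  d <- max(h)
  if (!signed) d <- max(d, 0)
  d
}

#' Tricuspid annulus tilt
#'
#' Angle between the base plane and the total-least-squares plane fitted
#' to the tricuspid-ring vertices (acute angle between the plane normals,
#' degrees in `[0, 90]`).
#'
#' @inheritParams basal_bulge
#' @return Tilt angle in degrees.
#' @export
tricuspid_tilt <- function(mesh, frame = reference_frame(mesh)) {
  ring <- label_vertices(mesh, "TRICUSPID_RING")
  if (length(ring) < 3) {
    stop_cs("labeling error: need >= 3 TRICUSPID_RING vertices", "labeling")
  }
  fit <- fit_plane(mesh$points[ring, , drop = FALSE])
  angle_deg(fit$normal, frame$lv_long_axis, acute = TRUE)
}

four_chamber_plane <- function(mesh, frame = reference_frame(mesh)) {
  tric <- label_vertices(mesh, "TRICUSPID_RING")
  if (length(tric) == 0) {
    stop_cs("labeling error: no TRICUSPID_RING vertices", "labeling")
  }
  tc <- colMeans(mesh$points[tric, , drop = FALSE])
  a <- frame$mitral_centroid - frame$lv_apex
  b <- tc - frame$lv_apex
  n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  if (sqrt(sum(n^2)) < 1e-8) {
    stop_cs("degenerate four-chamber plane (collinear landmarks)", "degenerate")
  }
  list(point = frame$lv_apex, normal = n / sqrt(sum(n^2)))
}

#' Apical angle of the RV
#'
#' In the four-chamber section (plane through the LV apex, mitral centroid
#' and tricuspid centroid) the septal and free-wall endocardial curves are
#' extracted near the RV apex. The septal line is a total-least-squares
#' fit to the apical third of the septal curve; the free-wall line is the
#' best-fitting line over a sliding window (`window` fraction of the curve
#' length) chosen to minimise the fit residual, i.e. the most linear
#' free-wall portion. Both lines are oriented base-ward and the angle
#' between them is reported in degrees within (0, 180).
#'
#' @inheritParams basal_bulge
#' @param window Sliding-window fraction of the free-wall curve (default
#'   0.30).
#' @return Apical angle in degrees.
#' @export
apical_angle <- function(mesh, frame = reference_frame(mesh), window = 0.30) {
  pl <- four_chamber_plane(mesh, frame)
  basis <- plane_basis(pl$normal)
  sep3 <- longest_polyline(plane_polylines(
    mesh$points, surface_faces(mesh, "RV_SEPTAL_ENDO"), pl$point, pl$normal))
  fw3 <- longest_polyline(plane_polylines(
    mesh$points, surface_faces(mesh, "RV_FREEWALL_ENDO"), pl$point, pl$normal))
  if (is.null(sep3) || is.null(fw3)) {
    stop_cs("section error: four-chamber plane misses the RV surfaces",
            "section")
  }
  axis <- frame$lv_long_axis
  # septal line: TLS fit over the apical third of the curve's axial extent
  hs <- as.numeric(sweep(sep3, 2, frame$lv_apex) %*% axis)
  keep <- hs <= min(hs) + diff(range(hs)) / 3
  if (sum(keep) < 3) keep <- order(hs)[seq_len(min(5, nrow(sep3)))]
  sep2 <- project_to_plane(sep3[keep, , drop = FALSE], pl$point, basis)
  sep_fit <- tls_line_2d(sep2)
  # free-wall line: minimal-residual sliding window over the curve
  fw_r <- resample_polyline(fw3, max(40, nrow(fw3)), closed = FALSE)
  fw2 <- project_to_plane(fw_r, pl$point, basis)
  m <- nrow(fw2)
  wlen <- max(3, round(window * m))
  best <- NULL
  for (s in seq_len(m - wlen + 1)) {
    fit <- tls_line_2d(fw2[s:(s + wlen - 1), , drop = FALSE])
    if (is.null(best) || fit$rms < best$rms) best <- fit
  }
  axis2 <- c(sum(axis * basis$e1), sum(axis * basis$e2))
  orient <- function(d) if (sum(d * axis2) < 0) -d else d
  angle_deg(orient(sep_fit$dir), orient(best$dir), acute = FALSE)
}

#' Mid-ventricular cavity dimensions D1-D4
#'
#' At the mid-ventricular short-axis plane (`level(0.5)`), the LV and RV
#' endocardial contours are extracted together with the septal contour
#' segment; the septal direction is the principal direction of that
#' segment in the section plane. The lateral-septal dimensions are the
#' contour extents perpendicular to the septal direction (`d1` LV, `d3`
#' RV) and the anterior-posterior dimensions the extents along it (`d4`
#' LV, `d2` RV).
#'
#' @inheritParams basal_bulge
#' @param level Level fraction of the apex-base axis (default 0.5).
#' @return Tibble with `d1`, `d2`, `d3`, `d4` (mm).
#' @export
midventricular_dimensions <- function(mesh, frame = reference_frame(mesh),
                                      level = 0.5) {
  pl <- frame$level(level)
  basis <- plane_basis(pl$normal)
  lv3 <- longest_polyline(plane_polylines(
    mesh$points, surface_faces(mesh, c("LV_ENDO", "MITRAL_RING", "AORTIC_RING")),
    pl$point, pl$normal), closed = TRUE)
  rv3 <- longest_polyline(plane_polylines(
    mesh$points,
    surface_faces(mesh, c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO",
                          "TRICUSPID_RING", "PULMONARY_RING")),
    pl$point, pl$normal), closed = TRUE)
  sep3 <- longest_polyline(plane_polylines(
    mesh$points, surface_faces(mesh, "RV_SEPTAL_ENDO"), pl$point, pl$normal))
  if (is.null(lv3) || is.null(rv3) || is.null(sep3)) {
    stop_cs("section error: open or missing contour at mid-ventricle",
            "section")
  }
  lv2 <- project_to_plane(lv3, pl$point, basis)
  rv2 <- project_to_plane(rv3, pl$point, basis)
  sep2 <- project_to_plane(sep3, pl$point, basis)
  septal_dir <- tls_line_2d(sep2)$dir
  perp <- c(-septal_dir[2], septal_dir[1])
  tibble::tibble(d1 = extent_along(lv2, perp),
                 d2 = extent_along(rv2, septal_dir),
                 d3 = extent_along(rv2, perp),
                 d4 = extent_along(lv2, septal_dir))
}

#' Remodeling features of one case at both phases
#'
#' @param case A [case_record()].
#' @param window Passed to [apical_angle()].
#' @return Tibble with `case_id`, `phase` and columns `basal_bulge` (mm),
#'   `tricuspid_tilt` (deg), `apical_angle` (deg), `d1`-`d4` (mm).
#' @export
case_features <- function(case, window = 0.30) {
  one <- function(mesh, phase) {
    frame <- reference_frame(mesh)
    dims <- midventricular_dimensions(mesh, frame)
    tibble::tibble(case_id = case$case_id, phase = phase,
                   basal_bulge = basal_bulge(mesh, frame),
                   tricuspid_tilt = tricuspid_tilt(mesh, frame),
                   apical_angle = apical_angle(mesh, frame, window),
                   d1 = dims$d1, d2 = dims$d2, d3 = dims$d3, d4 = dims$d4)
  }
  dplyr::bind_rows(one(case$ed, "ED"), one(case$es, "ES"))
}

#' @rdname case_features
#' @param cases List of [case_record()]s.
#' @export
cohort_features <- function(cases, window = 0.30) {
  purrr::map_dfr(cases, case_features, window = window)
}

#' Cohort summary of remodeling features (mean and SD per phase)
#'
#' @param features Tibble from [cohort_features()].
#' @return Long tibble with `feature`, `phase`, `mean`, `sd`, `n`.
#' @export
feature_summary <- function(features) {
  features |>
    tidyr::pivot_longer(-c("case_id", "phase"), names_to = "feature") |>
    dplyr::group_by(.data$feature, .data$phase) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

# univariate standardized OLS of each column on standardized PRVI
univariate_prvi <- function(values_by_case, covariates, alpha = 0.05) {
  stopifnot("case_id" %in% names(values_by_case))
  idx <- match(values_by_case$case_id, covariates$case_id)
  if (anyNA(idx)) stop_cs("unmatched case ids", "correspondence")
  if (nrow(values_by_case) < 3) {
    stop_cs("cohort error: univariate regression needs >= 3 cases", "cohort")
  }
  prvi <- covariates$prvi[idx]
  if (sd(prvi) == 0) stop_cs("degenerate predictor: constant PRVI", "degenerate")
  x <- as.numeric(scale(prvi))
  cols <- setdiff(names(values_by_case), c("case_id", "phase"))
  purrr::map_dfr(cols, function(v) {
    y <- values_by_case[[v]]
    if (sd(y) == 0) {
      stop_cs(sprintf("degenerate response: '%s' is constant", v), "degenerate")
    }
    fit <- stats::lm(scale(y) ~ x)
    sm <- summary(fit)$coefficients
    p <- sm["x", "Pr(>|t|)"]
    tibble::tibble(measure = v, pe = sm["x", "Estimate"], p = p,
                   pe_reported = ifelse(p < alpha, sm["x", "Estimate"],
                                        NA_real_))
  })
}

#' Univariate PRVI associations of remodeling features
#'
#' Standardized univariate regression of each feature on PRVI, per phase;
#' the reported parameter estimate is withheld (`NA`) when the association
#' is not significant at `alpha`, following the convention of reporting
#' only significant univariate correlations.
#'
#' @param features Tibble from [cohort_features()].
#' @param covariates Covariate tibble with `case_id` and `prvi`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `measure`, `phase`, `pe`, `p`, `pe_reported`.
#' @export
feature_prvi_regression <- function(features, covariates, alpha = 0.05) {
  features |>
    dplyr::group_by(.data$phase) |>
    dplyr::group_modify(function(df, key) {
      univariate_prvi(df, covariates, alpha)
    }) |>
    dplyr::ungroup()
}
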
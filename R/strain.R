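# Geometric systolic strain from the mesh pair: engineering (Cauchy)
# strain on circumferential and longitudinal arc lengths, and radial
# strain from centerline wall thickness, with base/mid/apex and
# four-chamber/RVOT averaging.

#' Engineering (Cauchy) strain
#'
#' `(L - L0) / L0` for a length changing from `L0` at end-diastole to `L`
#' at end-systole.
#'
#' @param l Length at ES.
#' @param l0 Length at ED (> 0).
#' @return Dimensionless strain (multiply by 100 for percent).
#' @export
cauchy_strain <- function(l, l0) {
  if (any(!is.finite(l0)) || any(l0 <= 0)) {
    stop_cs("reference length L0 must be positive", "domain")
  }
  (l - l0) / l0
}

#' Default short-axis level fractions
#'
#' Base, mid-ventricle and apex at fractions 0.75, 0.50 and 0.25 of the
#' apex-to-base axis.
#' @return Named numeric vector.
#' @export
strain_levels <- function() c(base = 0.75, mid = 0.50, apex = 0.25)

# arc length of the chamber contour in the level plane; LV uses the full
# endocardial contour (septum included), RV the free wall only
circ_arc <- function(mesh, frame, chamber, t) {
  pl <- frame$level(t)
  if (chamber == "LV") {
    # longest contour, closed when available: at the basal level the
    # section may pass through the aortic orifice and open the curve
    polys <- plane_polylines(
      mesh$points,
      surface_faces(mesh, c("LV_ENDO", "MITRAL_RING", "AORTIC_RING")),
      pl$point, pl$normal)
    poly <- longest_polyline(polys, closed = TRUE) %||%
      longest_polyline(polys)
  } else {
    poly <- longest_polyline(plane_polylines(
      mesh$points, surface_faces(mesh, "RV_FREEWALL_ENDO"),
      pl$point, pl$normal))
  }
  if (is.null(poly)) {
    stop_cs(sprintf("section error: no %s contour at level %.2f", chamber, t),
            "section")
  }
  polyline_length(poly)
}

#' Circumferential arc samples at base/mid/apex
#'
#' Polyline arc lengths of the short-axis plane intersections at the
#' [strain_levels()] fractions, for the full LV endocardial contour
#' (septum included) and the RV free wall, at both phases. Planes are
#' taken at the same fractions of each phase's own apex-base axis.
#'
#' @param case A [case_record()].
#' @param levels Named level fractions.
#' @param frame_phase `"each"` (default): levels from each phase's own
#'   frame; `"ed"`: reuse the ED frame for ES.
#' @return Tibble with `chamber`, `level`, `t`, `L0` (ED), `L` (ES) in mm.
#' @export
circumferential_arcs <- function(case, levels = strain_levels(),
                                 frame_phase = c("each", "ed")) {
  frame_phase <- match.arg(frame_phase)
  fr_ed <- reference_frame(case$ed)
  fr_es <- if (frame_phase == "each") reference_frame(case$es) else fr_ed
  purrr::map_dfr(c("LV", "RV"), function(ch) {
    purrr::map_dfr(names(levels), function(lv) {
      t <- levels[[lv]]
      tibble::tibble(chamber = ch, level = lv, t = t,
                     L0 = circ_arc(case$ed, fr_ed, ch, t),
                     L = circ_arc(case$es, fr_es, ch, t))
    })
  })
}

rvot_plane <- function(mesh) {
  pu <- label_vertices(mesh, "PULMONARY_RING")
  tr <- label_vertices(mesh, "TRICUSPID_RING")
  if (length(pu) == 0 || length(tr) == 0) {
    stop_cs("labeling error: RVOT view needs pulmonary and tricuspid rings",
            "labeling")
  }
  a <- colMeans(mesh$points[pu, , drop = FALSE])
  b <- colMeans(mesh$points[tr, , drop = FALSE])
  apex <- landmark_point(mesh, "RV_APEX")
  u <- a - apex; v <- b - apex
  n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(n^2)) < 1e-8) {
    stop_cs("degenerate RVOT plane", "degenerate")
  }
  list(point = apex, normal = n / sqrt(sum(n^2)))
}

long_arc <- function(mesh, pl, chamber) {
  labels <- if (chamber == "LV") {
    c("LV_ENDO", "MITRAL_RING", "AORTIC_RING")
  } else {
    c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO", "TRICUSPID_RING", "PULMONARY_RING")
  }
  poly <- longest_polyline(plane_polylines(
    mesh$points, surface_faces(mesh, labels), pl$point, pl$normal))
  if (is.null(poly)) return(NA_real_)
  polyline_length(poly)
}

#' Longitudinal arc samples in the 4-chamber and RVOT views
#'
#' The four-chamber plane passes through the LV apex and the mitral and
#' tricuspid centroids; the RVOT plane through the pulmonary and tricuspid
#' centroids and the RV apex. Each view's arc is the longest open
#' endocardial intersection polyline of the chamber (ring boundary to ring
#' boundary through the apex). A view that misses a chamber is excluded
#' with a warning; a chamber missing in both views is an error.
#'
#' @inheritParams circumferential_arcs
#' @return Tibble with `chamber`, `view`, `L0`, `L` (mm).
#' @export
longitudinal_arcs <- function(case, frame_phase = c("each", "ed")) {
  frame_phase <- match.arg(frame_phase)
  fr_ed <- reference_frame(case$ed)
  fr_es <- if (frame_phase == "each") reference_frame(case$es) else fr_ed
  planes <- list(
    fourchamber = list(ed = four_chamber_plane(case$ed, fr_ed),
                       es = four_chamber_plane(case$es, fr_es)),
    rvot = list(ed = rvot_plane(case$ed), es = rvot_plane(case$es)))
  out <- purrr::map_dfr(c("LV", "RV"), function(ch) {
    purrr::map_dfr(names(planes), function(vw) {
      tibble::tibble(chamber = ch, view = vw,
                     L0 = long_arc(case$ed, planes[[vw]]$ed, ch),
                     L = long_arc(case$es, planes[[vw]]$es, ch))
    })
  })
  for (ch in c("LV", "RV")) {
    sub <- out[out$chamber == ch, ]
    miss <- is.na(sub$L0) | is.na(sub$L)
    if (all(miss)) {
      stop_cs(sprintf("section error: no longitudinal view intersects the %s", ch),
              "section")
    }
    if (any(miss)) {
      warn_cs(sprintf("%s view misses the %s; longitudinal strain uses %s only",
                      sub$view[miss][1], ch, sub$view[!miss][1]), "view")
    }
  }
  out
}

#' Centerline wall thickness at a short-axis level
#'
#' The endocardial and outer-wall contours are intersected with the level
#' plane; the centerline is the midpoint curve between each of `m`
#' equally spaced endocardial stations and its nearest outer-wall point.
#' At every station a chord perpendicular to the local centerline tangent
#' is cast and the thickness is the distance between its endocardial and
#' outer-wall crossings; the returned thickness is the mean chord. The
#' LV outer wall is the epicardium, or the RV septal endocardium where the
#' chord meets it first (the septum is LV wall); the RV is measured across
#' the free wall to the epicardium only.
#'
#' @inheritParams basal_bulge
#' @param chamber `"LV"` or `"RV"`.
#' @param level Level fraction of the apex-base axis.
#' @param m Number of centerline stations (default 50).
#' @return Mean wall thickness in mm.
#' @export
wall_thickness <- function(mesh, frame = reference_frame(mesh),
                           chamber = c("LV", "RV"), level = 0.5, m = 50) {
  chamber <- match.arg(chamber)
  pl <- frame$level(level)
  basis <- plane_basis(pl$normal)
  get2d <- function(labels, closed = NULL) {
    poly <- longest_polyline(plane_polylines(
      mesh$points, surface_faces(mesh, labels), pl$point, pl$normal), closed)
    if (is.null(poly)) return(NULL)
    P <- project_to_plane(poly, pl$point, basis)
    attr(P, "closed") <- isTRUE(attr(poly, "closed"))
    P
  }
  epi2 <- get2d("EPI", closed = TRUE)
  if (is.null(epi2)) {
    stop_cs(sprintf("section error: no epicardial contour at level %.2f", level),
            "section")
  }
  if (chamber == "LV") {
    # the longest contour regardless of closure: near the base the aortic
    # orifice may open the section curve without invalidating the wall
    endo2 <- get2d(c("LV_ENDO", "MITRAL_RING", "AORTIC_RING"))
    outer <- list(epi2)
    rv2 <- if (any(mesh$labels %in% "RV_SEPTAL_ENDO")) {
      get2d(c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO",
              "TRICUSPID_RING", "PULMONARY_RING"), closed = TRUE)
    } else NULL
    if (!is.null(rv2)) outer <- c(outer, list(rv2))
  } else {
    endo2 <- get2d("RV_FREEWALL_ENDO")
    outer <- list(epi2)
  }
  if (is.null(endo2)) {
    stop_cs(sprintf("section error: no %s endocardial contour at level %.2f",
                    chamber, level), "section")
  }
  endo_closed <- isTRUE(attr(endo2, "closed"))
  # the endocardium must lie inside the epicardial contour; isolated
  # stations outside (noise-level interpenetration, or a coincident
  # zero-thickness wall) are tolerated and excluded, gross crossing is a
  # geometry error
  st0 <- resample_polyline(endo2, min(m, 25), closed = endo_closed)
  outside <- !apply(st0, 1, point_in_polygon, P2 = epi2)
  if (any(outside)) {
    epi_dense <- resample_polyline(epi2, 800, closed = TRUE)
    dmin <- vapply(which(outside), function(k) {
      sqrt(min((epi_dense[, 1] - st0[k, 1])^2 +
                 (epi_dense[, 2] - st0[k, 2])^2))
    }, numeric(1))
    if (sum(dmin > 1e-6) > 0.1 * nrow(st0)) {
      stop_cs("geometry error: endocardial contour crosses the epicardium",
              "geometry")
    }
  }
  stations <- resample_polyline(endo2, m, closed = endo_closed)
  dense_outer <- lapply(outer, function(P) {
    resample_polyline(P, 400, closed = isTRUE(attr(P, "closed")))
  })
  all_outer <- do.call(rbind, dense_outer)
  centerline <- matrix(0, m, 2)
  for (k in seq_len(m)) {
    d2 <- (all_outer[, 1] - stations[k, 1])^2 + (all_outer[, 2] - stations[k, 2])^2
    nearest <- all_outer[which.min(d2), ]
    centerline[k, ] <- (stations[k, ] + nearest) / 2
  }
  thick <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    kp <- if (k < m) k + 1 else if (endo_closed) 1 else k
    km <- if (k > 1) k - 1 else if (endo_closed) m else k
    tang <- centerline[kp, ] - centerline[km, ]
    if (sum(tang^2) < 1e-16) next
    u <- c(-tang[2], tang[1])
    t_endo <- line_polyline_crossings(endo2, centerline[k, ], u,
                                      closed = endo_closed)
    t_out <- unlist(lapply(outer, function(P) {
      line_polyline_crossings(P, centerline[k, ], u,
                              closed = isTRUE(attr(P, "closed")))
    }))
    if (length(t_endo) == 0 || length(t_out) == 0) next
    te <- t_endo[which.min(abs(t_endo))]
    to <- t_out[which.min(abs(t_out))]
    thick[k] <- abs(to - te)
  }
  if (all(is.na(thick))) {
    stop_cs("geometry error: no valid thickness chords", "geometry")
  }
  mean(thick, na.rm = TRUE)
}

#' Radial strain from systolic wall thickening
#'
#' Wall thickness at base/mid/apex in both phases; per-level radial strain
#' is the engineering strain of the thickness (positive = thickening), and
#' the chamber value is the mean over the three levels.
#'
#' @inheritParams circumferential_arcs
#' @param m Centerline stations per level.
#' @param chambers Chambers to measure (default both).
#' @return Tibble with `chamber`, `level`, `t0`, `t1` (mm), `rs`
#'   (fraction).
#' @export
radial_strain <- function(case, levels = strain_levels(), m = 50,
                          frame_phase = c("each", "ed"),
                          chambers = c("LV", "RV")) {
  frame_phase <- match.arg(frame_phase)
  fr_ed <- reference_frame(case$ed)
  fr_es <- if (frame_phase == "each") reference_frame(case$es) else fr_ed
  purrr::map_dfr(chambers, function(ch) {
    purrr::map_dfr(names(levels), function(lv) {
      t0 <- wall_thickness(case$ed, fr_ed, ch, levels[[lv]], m)
      t1 <- wall_thickness(case$es, fr_es, ch, levels[[lv]], m)
      if (t0 <= 0) {
        stop_cs("zero end-diastolic wall thickness", "domain")
      }
      tibble::tibble(chamber = ch, level = lv, t0 = t0, t1 = t1,
                     rs = cauchy_strain(t1, t0))
    })
  })
}

#' Full geometric strain set of one case
#'
#' Circumferential strain (CS) per level and longitudinal strain (LS) per
#' view via [cauchy_strain()] on arc lengths, radial strain (RS) per level
#' from centerline wall thickness; global chamber values are the means of
#' the components. All values are signed percent (systolic CS/LS are
#' negative for shortening).
#'
#' @inheritParams radial_strain
#' @return Long tibble with `case_id`, `chamber`, `kind` (CS/LS/RS),
#'   `component` (level, view or `"global"`) and `value` (%).
#' @export
case_strain <- function(case, levels = strain_levels(), m = 50,
                        frame_phase = "each") {
  circ <- circumferential_arcs(case, levels, frame_phase)
  circ$value <- 100 * cauchy_strain(circ$L, circ$L0)
  long <- longitudinal_arcs(case, frame_phase)
  long <- long[!is.na(long$L0) & !is.na(long$L), ]
  long$value <- 100 * cauchy_strain(long$L, long$L0)
  rad <- radial_strain(case, levels, m, frame_phase)
  parts <- dplyr::bind_rows(
    tibble::tibble(chamber = circ$chamber, kind = "CS",
                   component = circ$level, value = circ$value),
    tibble::tibble(chamber = long$chamber, kind = "LS",
                   component = long$view, value = long$value),
    tibble::tibble(chamber = rad$chamber, kind = "RS",
                   component = rad$level, value = 100 * rad$rs))
  globals <- parts |>
    dplyr::group_by(.data$chamber, .data$kind) |>
    dplyr::summarise(component = "global", value = mean(.data$value),
                     .groups = "drop")
  out <- dplyr::bind_rows(parts, globals)
  out$case_id <- case$case_id
  out[, c("case_id", "chamber", "kind", "component", "value")]
}

#' Global strain table for a cohort
#'
#' One row per case with the six global strains. Following the reporting
#' convention, CS and LS are given as absolute values and RS keeps its
#' sign (positive = systolic thickening).
#'
#' @param cases List of [case_record()]s.
#' @inheritParams radial_strain
#' @return Tibble with `case_id`, `lv_ls`, `lv_cs`, `lv_rs`, `rv_ls`,
#'   `rv_cs`, `rv_rs` (%).
#' @export
cohort_strain <- function(cases, levels = strain_levels(), m = 50,
                          frame_phase = "each") {
  view_warnings <- character(0)
  rows <- purrr::map_dfr(cases, function(cs) {
    st <- withCallingHandlers(
      case_strain(cs, levels, m, frame_phase),
      cardioshape_warning_view = function(w) {
        view_warnings <<- c(view_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    g <- st[st$component == "global", ]
    val <- function(ch, kd) g$value[g$chamber == ch & g$kind == kd]
    tibble::tibble(case_id = cs$case_id,
                   lv_ls = abs(val("LV", "LS")), lv_cs = abs(val("LV", "CS")),
                   lv_rs = val("LV", "RS"),
                   rv_ls = abs(val("RV", "LS")), rv_cs = abs(val("RV", "CS")),
                   rv_rs = val("RV", "RS"))
  })
  if (length(view_warnings) > 0) {
    warn_cs(sprintf("%d view exclusion(s), e.g.: %s", length(view_warnings),
                    view_warnings[1]), "view")
  }
  rows
}

#' Cohort strain summary (mean and SD per measure)
#'
#' @param strains Tibble from [cohort_strain()].
#' @return Tibble with `measure`, `mean`, `sd`, `n`.
#' @export
strain_summary <- function(strains) {
  strains |>
    tidyr::pivot_longer(-"case_id", names_to = "measure") |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Univariate PRVI associations of global strains
#'
#' Standardized univariate regression of each global strain (absolute
#' CS/LS, signed RS) on PRVI; the reported estimate is withheld when not
#' significant at `alpha`.
#'
#' @param strains Tibble from [cohort_strain()].
#' @param covariates Covariate tibble with `case_id` and `prvi`.
#' @param alpha Significance level.
#' @return Tibble with `measure`, `pe`, `p`, `pe_reported`.
#' @export
strain_prvi_regression <- function(strains, covariates, alpha = 0.05) {
  univariate_prvi(strains, covariates, alpha)
}
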
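#' Anatomical reference frame of a biventricular mesh
#'
#' The LV long axis runs from the LV apex landmark to the mitral valve
#' centroid (arithmetic mean of the mitral-ring vertices). The base plane
#' is perpendicular to this axis and passes through the mitral centroid;
#' `level(t)` gives the short-axis plane at fraction `t` of the apex-to-base
#' axis (`t = 0` at the apex, `t = 1` at the base).
#'
#' @param mesh A [biv_mesh()].
#' @return A list of class `biv_frame` with elements `lv_long_axis` (unit
#'   vector, apex to base), `mitral_centroid`, `lv_apex`, `base_plane`
#'   (list `point`, `normal`) and the function `level(t)`.
#' @export
reference_frame <- function(mesh) {
  ring <- label_vertices(mesh, "MITRAL_RING")
  if (length(ring) == 0) {
    stop_cs("labeling error: mesh has no MITRAL_RING vertices", "labeling")
  }
  centroid <- colMeans(mesh$points[ring, , drop = FALSE])
  apex <- landmark_point(mesh, "LV_APEX")
  axis <- centroid - apex
  len <- sqrt(sum(axis^2))
  if (len < 1e-8) {
    stop_cs("degenerate geometry: LV apex coincides with mitral centroid",
            "degenerate")
  }
  axis <- axis / len
  level <- function(t) {
    list(point = apex + t * len * axis, normal = axis)
  }
  structure(list(lv_long_axis = axis, mitral_centroid = centroid,
                 lv_apex = apex, axis_length = len,
                 base_plane = list(point = centroid, normal = axis),
                 level = level),
            class = "biv_frame")
}

#' Body surface area (m^2)
#'
#' Mosteller (default) or DuBois formula.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @param method `"mosteller"` or `"dubois"`.
#' @return BSA in m^2.
#' @export
#' @examples
#' bsa(180, 72)                      # sqrt(180*72/3600)
#' bsa(180, 72, method = "dubois")
bsa <- function(height_cm, weight_kg, method = c("mosteller", "dubois")) {
  method <- match.arg(method)
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop_cs("height and weight must be positive", "domain")
  }
  switch(method,
         mosteller = sqrt(height_cm * weight_kg / 3600),
         dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425)
}

chamber_surface <- function(mesh, chamber) {
  ch <- chamber_labels(chamber)
  f <- surface_faces(mesh, c(ch$endo, ch$rings))
  if (nrow(f) == 0) {
    stop_cs(sprintf("labeling error: mesh has no %s endocardial faces", chamber),
            "labeling")
  }
  loops <- boundary_loops(f)
  if (length(loops) > length(ch$rings)) {
    stop_cs(sprintf("open surface: %s endocardium has %d boundary loops",
                    chamber, length(loops)), "open_surface")
  }
  ring_present <- any(mesh$labels %in% ch$rings)
  for (loop in loops) {
    if (ring_present && !any(mesh$labels[loop] %in% ch$rings)) {
      stop_cs(sprintf("open surface: %s boundary loop is not a valve ring", chamber),
              "open_surface")
    }
  }
  if (!ring_present && length(loops) > 0) {
    stop_cs(sprintf("open surface: unlabeled hole in %s endocardium", chamber),
            "open_surface")
  }
  f
}

#' Cavity volume by mesh integration
#'
#' The chamber endocardial surface (plus its valve rings) is closed by fan
#' triangulation of each valve orifice to its ring centroid, and the volume
#' of the resulting watertight surface is integrated with the divergence
#' theorem (sum of signed tetrahedra).
#'
#' @param mesh A [biv_mesh()].
#' @param chamber `"LV"` or `"RV"`.
#' @return Cavity volume in ml.
#' @export
cavity_volume <- function(mesh, chamber = c("LV", "RV")) {
  chamber <- match.arg(chamber)
  f <- chamber_surface(mesh, chamber)
  enclosed_volume(mesh$points, f) / 1000
}

epicardial_volume <- function(mesh) {
  f <- surface_faces(mesh, "EPI")
  if (nrow(f) == 0) {
    stop_cs("labeling error: mesh has no EPI faces", "labeling")
  }
  loops <- boundary_loops(f)
  if (length(loops) > 1) {
    stop_cs("open surface: epicardium has more than one boundary loop",
            "open_surface")
  }
  enclosed_volume(mesh$points, f) / 1000
}

#' Myocardial mass by mesh integration
#'
#' Total wall volume is the capped epicardial compartment volume minus the
#' cavity volumes of the chambers present. The right-ventricular share is
#' the free-wall shell, integrated as per-vertex wall thickness (distance
#' from each RV free-wall vertex to the epicardium along the outward
#' normal) times the vertex area; the remainder, including the
#' interventricular septum, is assigned to the LV. Mass is wall volume
#' times the myocardial density.
#'
#' @param mesh A [biv_mesh()].
#' @param chamber `"LV"` or `"RV"`.
#' @param density Myocardial density in g/ml (default 1.05).
#' @return Mass in g.
#' @export
myocardial_mass <- function(mesh, chamber = c("LV", "RV"), density = 1.05) {
  chamber <- match.arg(chamber)
  v_epi <- epicardial_volume(mesh)
  cavities <- 0
  for (ch in c("LV", "RV")) {
    ch_lab <- chamber_labels(ch)
    if (any(mesh$labels %in% ch_lab$endo)) {
      cavities <- cavities + cavity_volume(mesh, ch)
    }
  }
  wall <- v_epi - cavities
  if (wall < -1e-9) {
    stop_cs(sprintf(
      "geometry error: negative wall volume (%.2f ml); epicardium inside endocardium?",
      wall), "geometry")
  }
  wall <- max(wall, 0)
  has_rv <- any(mesh$labels %in% "RV_FREEWALL_ENDO")
  if (!has_rv) {
    rv_wall <- 0
  } else {
    rv_wall <- rv_freewall_shell_volume(mesh)
    rv_wall <- min(rv_wall, wall)
  }
  vol <- if (chamber == "RV") rv_wall else wall - rv_wall
  vol * density
}

# RV free-wall shell volume (ml) as the surface integral of wall thickness:
# cast a ray from each free-wall vertex along its outward normal to the
# epicardium and weight the hit distance by the vertex area.
rv_freewall_shell_volume <- function(mesh) {
  fw <- label_vertices(mesh, "RV_FREEWALL_ENDO")
  f_rv <- surface_faces(mesh, c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO",
                                "TRICUSPID_RING", "PULMONARY_RING"))
  f_epi <- surface_faces(mesh, "EPI")
  if (nrow(f_epi) == 0) return(0)
  f_rv <- orient_faces(f_rv)
  nrm <- vertex_normals(mesh$points, f_rv)
  # orient outward: away from the RV cavity centroid
  cav_c <- colMeans(mesh$points[label_vertices(
    mesh, c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO")), , drop = FALSE])
  outward <- sweep(mesh$points, 2, cav_c)
  flip <- sum(rowSums(outward[fw, , drop = FALSE] * nrm[fw, , drop = FALSE])) < 0
  if (flip) nrm <- -nrm
  # per-vertex area: one third of adjacent free-wall face area
  areas <- tri_areas(mesh$points, f_rv)
  varea <- rep(0, nrow(mesh$points))
  for (j in 1:3) varea <- varea + tabulate2(f_rv[, j], areas / 3, nrow(mesh$points))
  d <- ray_mesh_distance(mesh$points, f_epi,
                         mesh$points[fw, , drop = FALSE],
                         nrm[fw, , drop = FALSE])
  ok <- is.finite(d)
  sum(d[ok] * varea[fw][ok]) / 1000
}

#' Ejection fraction from an EDV/ESV pair
#'
#' @param edv,esv End-diastolic and end-systolic volumes (same units).
#' @return EF in percent, `100 * (edv - esv) / edv`.
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop_cs("EDV must be positive", "domain")
  100 * (edv - esv) / edv
}

#' Volumes, masses and ejection fractions for one case
#'
#' Computes LV/RV end-diastolic and end-systolic cavity volumes, myocardial
#' masses, ejection fractions, and BSA-indexed variants (when covariates
#' with height and weight are available).
#'
#' @param case A [case_record()].
#' @param bsa_method Passed to [bsa()].
#' @param density Passed to [myocardial_mass()].
#' @return One-row tibble with columns `lv_edv`, `lv_esv`, `rv_edv`,
#'   `rv_esv` (ml), `lv_mass`, `rv_mass` (g), `lvef`, `rvef` (%), `bsa`
#'   (m^2) and `*_i` indexed columns (ml/m^2, g/m^2) when BSA is available.
#' @export
volumetric_measures <- function(case, bsa_method = "mosteller", density = 1.05) {
  out <- tibble::tibble(
    case_id = case$case_id,
    lv_edv = cavity_volume(case$ed, "LV"),
    lv_esv = cavity_volume(case$es, "LV"),
    rv_edv = cavity_volume(case$ed, "RV"),
    rv_esv = cavity_volume(case$es, "RV"),
    lv_mass = myocardial_mass(case$ed, "LV", density),
    rv_mass = myocardial_mass(case$ed, "RV", density))
  out$lvef <- ejection_fraction(out$lv_edv, out$lv_esv)
  out$rvef <- ejection_fraction(out$rv_edv, out$rv_esv)
  cov <- case$covariates
  if (!is.null(cov)) {
    out$bsa <- bsa(cov$height, cov$weight, bsa_method)
    for (v in c("lv_edv", "lv_esv", "rv_edv", "rv_esv", "lv_mass", "rv_mass")) {
      out[[paste0(v, "_i")]] <- out[[v]] / out$bsa
    }
  }
  out
}
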
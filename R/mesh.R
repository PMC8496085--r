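#' Anatomical vertex labels of a biventricular surface mesh
#'
#' The labelling scheme distinguishes the left-ventricular endocardium, the
#' septal and free-wall portions of the right-ventricular endocardium, the
#' shared epicardium, and the four valve annuli (mitral, tricuspid, aortic,
#' pulmonary) which form the open boundaries of the endocardial surfaces.
#'
#' @return Character vector of the eight recognised labels.
#' @export
biv_labels <- function() {
  c("LV_ENDO", "RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO", "EPI",
    "MITRAL_RING", "TRICUSPID_RING", "AORTIC_RING", "PULMONARY_RING")
}

ring_labels <- function() {
  c("MITRAL_RING", "TRICUSPID_RING", "AORTIC_RING", "PULMONARY_RING")
}

chamber_labels <- function(chamber) {
  switch(chamber,
    LV = list(endo = "LV_ENDO",
              rings = c("MITRAL_RING", "AORTIC_RING")),
    RV = list(endo = c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO"),
              rings = c("TRICUSPID_RING", "PULMONARY_RING")),
    stop_cs(sprintf("unknown chamber '%s' (use 'LV' or 'RV')", chamber), "key"))
}

#' Construct a labeled biventricular surface mesh
#'
#' A `biv_mesh` is a triangulated surface with per-vertex anatomical labels
#' (see [biv_labels()]) and two landmark vertices, the LV and RV apex. It is
#' the unit of geometry for the atlas, feature and strain computations; all
#' coordinates are millimetres in a right-handed patient frame.
#'
#' @param points Numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces Integer matrix of triangle vertex indices (1-based), one row
#'   per triangle.
#' @param labels Character vector (or factor) of per-vertex labels, one of
#'   [biv_labels()].
#' @param landmarks Named integer vector with elements `LV_APEX` and
#'   `RV_APEX` giving vertex indices.
#' @param case_id Case identifier string.
#' @param phase `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @param validate Run [validate_biv_mesh()] on the result (default `TRUE`).
#'
#' @return An object of class `biv_mesh`.
#' @export
biv_mesh <- function(points, faces, labels, landmarks,
                     case_id = "case", phase = c("ED", "ES"),
                     validate = TRUE) {
  phase <- match.arg(phase)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  labels <- as.character(labels)
  mesh <- structure(
    list(points = points, faces = faces, labels = labels,
         landmarks = landmarks, case_id = case_id, phase = phase),
    class = "biv_mesh")
  if (validate) validate_biv_mesh(mesh)
  mesh
}

#' Validate a biventricular mesh
#'
#' Checks structural invariants: finite coordinates, valid face indices,
#' exactly one recognised label per vertex, both apex landmarks present, no
#' (near) zero-area faces, and that each chamber surface is closable: its
#' boundary loops must be valve-ring loops (at most two per endocardial
#' surface, at most one basal rim for the epicardium).
#'
#' @param mesh A [biv_mesh()].
#' @param degenerate_tol Minimum allowed triangle area (mm^2).
#' @return The mesh, invisibly; errors of class `cardioshape_error_*`
#'   otherwise.
#' @export
validate_biv_mesh <- function(mesh, degenerate_tol = 1e-10) {
  p <- mesh$points
  f <- mesh$faces
  n <- nrow(p)
  if (ncol(p) != 3 || !all(is.finite(p))) {
    stop_cs("mesh points must be a finite n x 3 matrix", "geometry")
  }
  if (nrow(f) < 1 || ncol(f) != 3 || min(f) < 1 || max(f) > n) {
    stop_cs("face indices out of range", "geometry")
  }
  if (length(mesh$labels) != n) {
    stop_cs(sprintf(
      "labeling error: %d labels for %d vertices", length(mesh$labels), n),
      "labeling")
  }
  bad <- !(mesh$labels %in% biv_labels())
  if (any(bad)) {
    stop_cs(sprintf("labeling error: unknown label(s): %s",
                    paste(unique(mesh$labels[bad]), collapse = ", ")),
            "labeling")
  }
  lm <- mesh$landmarks
  if (is.null(lm) || !all(c("LV_APEX", "RV_APEX") %in% names(lm))) {
    stop_cs("labeling error: landmarks LV_APEX and RV_APEX are required",
            "labeling")
  }
  if (any(lm[c("LV_APEX", "RV_APEX")] < 1 | lm[c("LV_APEX", "RV_APEX")] > n)) {
    stop_cs("labeling error: landmark vertex index out of range", "labeling")
  }
  areas <- tri_areas(p, f)
  if (any(areas <= degenerate_tol)) {
    stop_cs(sprintf("%d degenerate (zero-area) faces", sum(areas <= degenerate_tol)),
            "geometry")
  }
  check_surface_closable(mesh, "LV")
  check_surface_closable(mesh, "RV")
  check_epi_closable(mesh)
  invisible(mesh)
}

surface_faces <- function(mesh, label_set) {
  keep <- matrix(mesh$labels[mesh$faces] %in% label_set, ncol = 3)
  mesh$faces[rowSums(keep) == 3L, , drop = FALSE]
}

check_surface_closable <- function(mesh, chamber) {
  ch <- chamber_labels(chamber)
  f <- surface_faces(mesh, c(ch$endo, ch$rings))
  if (nrow(f) == 0) return(invisible(NULL))
  loops <- boundary_loops(f)
  if (length(loops) > length(ch$rings)) {
    stop_cs(sprintf(
      "open surface: %s endocardium has %d boundary loops (at most %d valve-ring loops expected)",
      chamber, length(loops), length(ch$rings)), "open_surface")
  }
  for (loop in loops) {
    if (!any(mesh$labels[loop] %in% ch$rings)) {
      stop_cs(sprintf(
        "open surface: %s endocardial boundary loop contains no valve-ring vertices",
        chamber), "open_surface")
    }
  }
  invisible(NULL)
}

check_epi_closable <- function(mesh) {
  f <- surface_faces(mesh, "EPI")
  if (nrow(f) == 0) return(invisible(NULL))
  loops <- boundary_loops(f)
  if (length(loops) > 1) {
    stop_cs(sprintf("open surface: epicardium has %d boundary loops (at most 1 expected)",
                    length(loops)), "open_surface")
  }
  invisible(NULL)
}

#' @export
print.biv_mesh <- function(x, ...) {
  cat(sprintf("<biv_mesh> case '%s' phase %s: %d vertices, %d faces\n",
              x$case_id, x$phase, nrow(x$points), nrow(x$faces)))
  tab <- table(factor(x$labels, levels = biv_labels()))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

label_vertices <- function(mesh, labels) which(mesh$labels %in% labels)

landmark_point <- function(mesh, name) {
  idx <- mesh$landmarks[[name]]
  if (is.null(idx)) stop_cs(sprintf("landmark '%s' missing", name), "labeling")
  mesh$points[idx, ]
}

# same vertex count, connectivity, labels and landmarks
check_correspondence <- function(a, b, what = "meshes") {
  if (nrow(a$points) != nrow(b$points)) {
    stop_cs(sprintf("correspondence error: %s differ in vertex count (%d vs %d)",
                    what, nrow(a$points), nrow(b$points)), "correspondence")
  }
  if (!identical(a$faces, b$faces)) {
    stop_cs(sprintf("correspondence error: %s differ in connectivity", what),
            "correspondence")
  }
  if (!identical(a$labels, b$labels)) {
    stop_cs(sprintf("correspondence error: %s differ in vertex labels", what),
            "correspondence")
  }
  if (!identical(a$landmarks[c("LV_APEX", "RV_APEX")],
                 b$landmarks[c("LV_APEX", "RV_APEX")])) {
    stop_cs(sprintf("correspondence error: %s differ in landmarks", what),
            "correspondence")
  }
  invisible(TRUE)
}

#' Bundle an ED/ES mesh pair with clinical covariates
#'
#' @param case_id Case identifier.
#' @param ed,es [biv_mesh()] objects at end-diastole and end-systole; they
#'   must share vertex count, connectivity, labels and landmarks.
#' @param covariates Optional one-row data frame (or named list) with
#'   `age` (years), `sex` (`"F"`/`"M"`), `height` (cm), `weight` (kg),
#'   `prvi` (ml/m^2) and `tr_grade` (ordered: none-trace < mild <
#'   mild-to-moderate < moderate).
#'
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, ed, es, covariates = NULL) {
  stopifnot(inherits(ed, "biv_mesh"), inherits(es, "biv_mesh"))
  check_correspondence(ed, es, sprintf("ED and ES meshes of '%s'", case_id))
  if (!is.null(covariates)) covariates <- normalize_covariates(covariates)
  structure(list(case_id = case_id, ed = ed, es = es, covariates = covariates),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> '%s': %d vertices; covariates: %s\n",
              x$case_id, nrow(x$ed$points),
              if (is.null(x$covariates)) "none" else
                paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

tr_grade_levels <- function() {
  c("none-trace", "mild", "mild-to-moderate", "moderate")
}

normalize_covariates <- function(cov) {
  cov <- as.list(cov)
  req <- c("age", "sex", "height", "weight", "prvi", "tr_grade")
  missing <- setdiff(req, names(cov))
  if (length(missing) > 0) {
    stop_cs(paste("missing covariate(s):", paste(missing, collapse = ", ")),
            "domain")
  }
  sex <- as.character(cov$sex)
  if (!sex %in% c("F", "M")) stop_cs("sex must be 'F' or 'M'", "domain")
  tg <- as.character(cov$tr_grade)
  if (!tg %in% tr_grade_levels()) {
    stop_cs(sprintf("tr_grade must be one of %s",
                    paste(tr_grade_levels(), collapse = ", ")), "domain")
  }
  for (v in c("age", "height", "weight", "prvi")) {
    assert_scalar_number(cov[[v]], v)
  }
  tibble::tibble(age = cov$age, sex = factor(sex, c("F", "M")),
                 height = cov$height, weight = cov$weight, prvi = cov$prvi,
                 tr_grade = factor(tg, tr_grade_levels(), ordered = TRUE))
}
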
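# Synthetic biventricular cohorts with known ground truth. The template is
# an idealized biventricular geometry: the LV endocardium is a truncated
# ellipsoid, the RV endocardium an offset ellipsoid cut by a (tiltable)
# tricuspid plane and split into septal and free-wall regions, and the
# epicardium a single enclosing ellipsoid shell. Valve orifices are carved
# rectangular holes whose perimeters carry the ring labels. End-systole is
# built from end-diastole by a radial/longitudinal contraction map. Cohorts
# plant orthonormal deformation modes, covariate effects on mode
# coordinates, vertex noise and per-case rigid motion, all reproducible
# from a seed.

## ---- parametric surface patches ---------------------------------------

# Open ellipsoid patch: apex pole plus n_theta rows of n_phi vertices.
# `cut` is either list(type="flat", frac=) cutting at z_local = frac*c, or
# list(type="plane", normal=, height=) cutting where the local-coordinate
# plane through (0,0,height) with the given normal crosses the surface.
ellipsoid_patch <- function(center, axes, cut, n_theta, n_phi) {
  a <- axes[1]; b <- axes[2]; cc <- axes[3]
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  theta_rim <- rep(NA_real_, n_phi)
  if (cut$type == "flat") {
    theta_rim[] <- acos(-cut$frac)
  } else {
    nrm <- cut$normal / sqrt(sum(cut$normal^2))
    for (j in seq_len(n_phi)) {
      f <- function(th) {
        p <- c(a * sin(th) * cos(phi[j]), b * sin(th) * sin(phi[j]),
               -cc * cos(th))
        sum((p - c(0, 0, cut$height)) * nrm)
      }
      lo <- 1e-3; hi <- pi - 1e-3
      if (f(lo) > 0 || f(hi) < 0) {
        stop_cs("template error: cut plane misses the surface", "template")
      }
      theta_rim[j] <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    }
  }
  n_pts <- 1L + n_theta * n_phi
  pts <- matrix(0, n_pts, 3)
  pts[1, ] <- center + c(0, 0, -cc)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  for (i in seq_len(n_theta)) {
    th <- theta_rim * i / n_theta
    pts[idx(i, seq_len(n_phi)), ] <- cbind(
      center[1] + a * sin(th) * cos(phi),
      center[2] + b * sin(th) * sin(phi),
      center[3] - cc * cos(th))
  }
  faces <- matrix(0L, n_phi + 2L * (n_theta - 1L) * n_phi, 3)
  cell_i <- integer(nrow(faces)); cell_j <- integer(nrow(faces))
  r <- 1L
  for (j in seq_len(n_phi)) {  # apex fan
    faces[r, ] <- c(1L, idx(1, j + 1L), idx(1, j))
    cell_i[r] <- 0L; cell_j[r] <- j
    r <- r + 1L
  }
  for (i in seq_len(n_theta - 1L)) {
    for (j in seq_len(n_phi)) {
      A <- idx(i, j); B <- idx(i, j + 1L)
      C <- idx(i + 1L, j + 1L); D <- idx(i + 1L, j)
      faces[r, ] <- c(A, B, C); cell_i[r] <- i; cell_j[r] <- j; r <- r + 1L
      faces[r, ] <- c(A, C, D); cell_i[r] <- i; cell_j[r] <- j; r <- r + 1L
    }
  }
  list(points = pts, faces = faces, cell_i = cell_i, cell_j = cell_j,
       apex = 1L, ring = idx(n_theta, seq_len(n_phi)), idx = idx,
       phi = phi, n_theta = n_theta, n_phi = n_phi)
}

# Remove the faces of a one-row block of grid cells (row i0, columns
# j0..j0+w-1) to open a valve orifice; returns remaining faces plus the
# perimeter vertex indices (the new ring).
carve_hole <- function(patch, i0, j0, w) {
  if (i0 < 2 || i0 > patch$n_theta - 2L) {
    stop_cs("template error: orifice row out of range", "template")
  }
  cols <- ((j0 - 1L) + seq_len(w) - 1L) %% patch$n_phi + 1L
  drop <- patch$cell_i == i0 & patch$cell_j %in% cols
  perim <- c(patch$idx(i0, c(cols, cols[w] + 1L)),
             patch$idx(i0 + 1L, c(cols, cols[w] + 1L)))
  list(faces = patch$faces[!drop, , drop = FALSE],
       cell_i = patch$cell_i[!drop], cell_j = patch$cell_j[!drop],
       ring = unique(perim))
}

#' Default geometric parameters of the synthetic biventricular template
#'
#' Millimetre dimensions chosen to emulate a volume-loaded adolescent
#' ventricle pair: LV cavity about 120 ml, dilated RV, tricuspid annulus
#' tilted relative to the mitral base plane, and systolic contraction
#' fractions giving ejection fractions near 40 percent.
#'
#' @param ... Overrides for any default element.
#' @return Named list of template parameters.
#' @export
template_params <- function(...) {
  p <- list(
    lv_axes = c(24, 24, 68),       # LV endocardial semi-axes (mm)
    lv_cut_frac = 0.35,            # mitral plane at z = 0.35 * c
    rv_axes = c(20, 32, 66),       # RV endocardial semi-axes (mm)
    rv_center = c(48, 0, 4),
    rv_cut_height = 23,            # tricuspid plane height above RV centre
    tricuspid_tilt = 40,           # degrees between tricuspid and base plane
    epi_axes = c(52, 42, 82),
    epi_center = c(21, 0, 0),
    epi_cut_frac = 0.366,
    bulge_mm = 0,                  # extra basal free-wall bulge
    contraction = list(cr = 0.18, cl = 0.14, wall_thicken = 0.25),
    resolution = c(n_theta = 16, n_phi = 32))
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Build the synthetic ED/ES biventricular template
#'
#' Constructs a labeled, corresponded mesh pair from [template_params()].
#' The tricuspid ring lies exactly on a plane tilted by `tricuspid_tilt`
#' degrees about the anterior-posterior axis, so the tilt feature has a
#' closed-form ground truth; the mitral ring lies in the flat base plane.
#' End-systole shortens the endocardium by fraction `cr` radially (in the
#' short-axis plane) and `cl` longitudinally about the mitral centroid, so
#' the endocardial circumferential strain is exactly `-cr`; the epicardium
#' follows its nearest endocardial material point with its wall offset
#' stretched by `1 + wall_thicken`, planting systolic wall thickening.
#'
#' @param params List from [template_params()].
#' @param validate Validate the resulting meshes (default `TRUE`).
#' @return A [case_record()] (case id `"template"`, no covariates).
#' @export
make_template <- function(params = template_params(), validate = TRUE) {
  res <- params$resolution
  n_theta <- res[["n_theta"]]; n_phi <- res[["n_phi"]]
  if (any(c(params$lv_axes, params$rv_axes, params$epi_axes) <= 0)) {
    stop_cs("template error: non-positive semi-axis", "template")
  }
  ## LV endocardium (flat mitral cut, carved aortic orifice)
  lv <- ellipsoid_patch(c(0, 0, 0), params$lv_axes,
                        list(type = "flat", frac = params$lv_cut_frac),
                        n_theta, n_phi)
  ao <- carve_hole(lv, n_theta - 2L, round(n_phi / 4) - 1L, 3L)
  lv_labels <- rep("LV_ENDO", nrow(lv$points))
  lv_labels[lv$ring] <- "MITRAL_RING"
  lv_labels[ao$ring] <- "AORTIC_RING"
  ## RV endocardium (tilted tricuspid cut, carved pulmonary orifice)
  alpha <- params$tricuspid_tilt * pi / 180
  rv <- ellipsoid_patch(params$rv_center, params$rv_axes,
                        list(type = "plane",
                             normal = c(-sin(alpha), 0, cos(alpha)),
                             height = params$rv_cut_height),
                        n_theta, n_phi)
  pu <- carve_hole(rv, n_theta - 2L, round(n_phi / 8), 3L)
  septal <- cos(rv$phi) < 0
  rv_labels <- rep("RV_FREEWALL_ENDO", nrow(rv$points))
  for (i in seq_len(n_theta)) {
    rv_labels[rv$idx(i, which(septal))] <- "RV_SEPTAL_ENDO"
  }
  rv_labels[rv$apex] <- "RV_FREEWALL_ENDO"
  rv_labels[rv$ring] <- "TRICUSPID_RING"
  rv_labels[pu$ring] <- "PULMONARY_RING"
  ## epicardium
  epi <- ellipsoid_patch(params$epi_center, params$epi_axes,
                         list(type = "flat", frac = params$epi_cut_frac),
                         n_theta, n_phi)
  epi_labels <- rep("EPI", nrow(epi$points))
  ## optional basal free-wall bulge (towards the base, tapered)
  if (params$bulge_mm > 0) {
    for (i in (n_theta - 3L):(n_theta - 1L)) {
      cols <- which(!septal)
      wrow <- (i - (n_theta - 4L)) / 3
      wz <- params$bulge_mm * wrow * pmax(cos(rv$phi[cols]), 0)
      v <- rv$idx(i, cols)
      rv$points[v, 3] <- rv$points[v, 3] + wz
    }
  }
  ## containment: endocardial vertices must lie inside the epicardial
  ## ellipsoid, otherwise the parameter combination self-intersects
  inside_epi <- function(p) {
    rel <- sweep(p, 2, params$epi_center)
    rowSums(sweep(rel, 2, params$epi_axes, `/`)^2) < 1
  }
  if (!all(inside_epi(lv$points)) || !all(inside_epi(rv$points))) {
    stop_cs("template error: endocardium pierces the epicardium", "template")
  }
  ## assemble
  pts <- rbind(lv$points, rv$points, epi$points)
  off_rv <- nrow(lv$points)
  off_epi <- off_rv + nrow(rv$points)
  faces <- rbind(ao$faces, pu$faces + off_rv, epi$faces + off_epi)
  labels <- c(lv_labels, rv_labels, epi_labels)
  landmarks <- c(LV_APEX = lv$apex, RV_APEX = rv$apex + off_rv)
  keep <- drop_unreferenced(pts, faces, labels, landmarks)
  ed <- biv_mesh(keep$points, keep$faces, keep$labels, keep$landmarks,
                 case_id = "template", phase = "ED", validate = validate)
  es_points <- contract_points(keep$points, keep$labels, params)
  es <- biv_mesh(es_points, keep$faces, keep$labels, keep$landmarks,
                 case_id = "template", phase = "ES", validate = validate)
  case_record("template", ed, es)
}

drop_unreferenced <- function(points, faces, labels, landmarks) {
  used <- sort(unique(c(as.vector(faces), unname(landmarks))))
  remap <- integer(nrow(points))
  remap[used] <- seq_along(used)
  list(points = points[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3),
       labels = labels[used],
       landmarks = vapply(landmarks, function(i) remap[i], integer(1)))
}

# ES construction: the endocardium contracts affinely about the mitral
# centroid (radial fraction cr in the short-axis plane, longitudinal
# fraction cl), so endocardial circumferential strain is exactly -cr. Each
# epicardial vertex follows its nearest end-diastolic endocardial point and
# its wall-offset vector is stretched by (1 + wall_thicken), planting a
# transmural systolic thickening.
contract_points <- function(points, labels, params) {
  cn <- params$contraction
  mitral <- colMeans(points[labels == "MITRAL_RING", , drop = FALSE])
  scale_about <- function(p) {
    rel <- sweep(p, 2, mitral)
    rel[, 1] <- rel[, 1] * (1 - cn$cr)
    rel[, 2] <- rel[, 2] * (1 - cn$cr)
    rel[, 3] <- rel[, 3] * (1 - cn$cl)
    sweep(rel, 2, mitral, `+`)
  }
  out <- points
  endo <- labels != "EPI"
  out[endo, ] <- scale_about(points[endo, , drop = FALSE])
  if (any(!endo)) {
    p_endo <- points[endo, , drop = FALSE]
    p_epi <- points[!endo, , drop = FALSE]
    near <- apply(p_epi, 1, function(q) {
      which.min(colSums((t(p_endo) - q)^2))
    })
    offset <- p_epi - p_endo[near, , drop = FALSE]
    out[!endo, ] <- scale_about(p_endo[near, , drop = FALSE]) +
      (1 + (cn$wall_thicken %||% 0)) * offset
  }
  out
}

## ---- simple analytic fixtures ----------------------------------------

# icosphere: subdivided icosahedron projected onto an ellipsoid
icosphere <- function(subdiv = 3, axes = c(1, 1, 1), center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    env <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newf <- matrix(0L, 4 * nrow(f), 3)
    mid <- function(i, j) {
      k <- edge_key(i, j)
      if (is.null(env[[k]])) {
        m <- v[i, ] + v[j, ]
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        env[[k]] <- nrow(v)
      }
      env[[k]]
    }
    r <- 1L
    for (q in seq_len(nrow(f))) {
      a <- f[q, 1]; b <- f[q, 2]; cc <- f[q, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      newf[r, ] <- c(a, ab, ca); r <- r + 1L
      newf[r, ] <- c(b, bc, ab); r <- r + 1L
      newf[r, ] <- c(cc, ca, bc); r <- r + 1L
      newf[r, ] <- c(ab, bc, ca); r <- r + 1L
    }
    f <- newf
  }
  pts <- sweep(sweep(v, 2, axes, `*`), 2, center, `+`)
  dimnames(pts) <- NULL
  list(points = pts, faces = f)
}

#' Closed-surface fixtures with closed-form volumes
#'
#' `fixture_sphere()` and `fixture_ellipsoid()` return closed single-cavity
#' meshes (all vertices `LV_ENDO`) whose volume has a closed form;
#' `fixture_concentric()` nests an `LV_ENDO` surface inside an `EPI`
#' surface for mass checks. Apex landmarks are placed at the lowest and
#' highest vertices so the meshes pass structural validation.
#'
#' @param radius,axes,center Geometry (mm).
#' @param r_endo,r_epi Endo-/epicardial radii for the concentric fixture.
#' @param subdiv Icosphere subdivision level.
#' @return A [biv_mesh()] (or [case_record()]-free mesh pair for
#'   `fixture_concentric`, merged into one mesh).
#' @export
fixture_sphere <- function(radius = 1, subdiv = 4, center = c(0, 0, 0)) {
  fixture_ellipsoid(rep(radius, 3), subdiv, center)
}

#' @rdname fixture_sphere
#' @export
fixture_ellipsoid <- function(axes, subdiv = 4, center = c(0, 0, 0)) {
  ico <- icosphere(subdiv, axes, center)
  landmarks <- c(LV_APEX = which.min(ico$points[, 3]),
                 RV_APEX = which.max(ico$points[, 3]))
  biv_mesh(ico$points, ico$faces, rep("LV_ENDO", nrow(ico$points)),
           landmarks, case_id = "fixture", phase = "ED", validate = FALSE)
}

#' @rdname fixture_sphere
#' @export
fixture_concentric <- function(r_endo = 30, r_epi = 40, subdiv = 3) {
  endo <- icosphere(subdiv, rep(r_endo, 3))
  epi <- icosphere(subdiv, rep(r_epi, 3))
  pts <- rbind(endo$points, epi$points)
  faces <- rbind(endo$faces, epi$faces + nrow(endo$points))
  labels <- c(rep("LV_ENDO", nrow(endo$points)), rep("EPI", nrow(epi$points)))
  landmarks <- c(LV_APEX = which.min(endo$points[, 3]),
                 RV_APEX = which.max(endo$points[, 3]))
  biv_mesh(pts, faces, labels, landmarks, case_id = "fixture",
           phase = "ED", validate = FALSE)
}

# open elliptical "cup": cylinder wall of n_rows rings closed by a bottom
# cap fan to the axis point; the top ring is the open boundary.
elliptical_cup <- function(center, rx, ry, height, n_seg = 64, n_rows = 8) {
  z <- center[3] + height * seq(0, 1, length.out = n_rows)
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  pts <- matrix(0, 1 + n_rows * n_seg, 3)
  pts[1, ] <- center
  idx <- function(i, j) 1L + (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
  for (i in seq_len(n_rows)) {
    pts[idx(i, seq_len(n_seg)), ] <- cbind(center[1] + rx * cos(phi),
                                           center[2] + ry * sin(phi),
                                           z[i])
  }
  faces <- matrix(0L, n_seg + 2L * (n_rows - 1L) * n_seg, 3)
  r <- 1L
  for (j in seq_len(n_seg)) {
    faces[r, ] <- c(1L, idx(1, j + 1L), idx(1, j)); r <- r + 1L
  }
  for (i in seq_len(n_rows - 1L)) {
    for (j in seq_len(n_seg)) {
      A <- idx(i, j); B <- idx(i, j + 1L)
      C <- idx(i + 1L, j + 1L); D <- idx(i + 1L, j)
      faces[r, ] <- c(A, B, C); r <- r + 1L
      faces[r, ] <- c(A, C, D); r <- r + 1L
    }
  }
  list(points = pts, faces = faces, apex = 1L,
       ring = idx(n_rows, seq_len(n_seg)), idx = idx, phi = phi,
       n_rows = n_rows, n_seg = n_seg)
}

#' Cylindrical-wall fixture for thickness and dimension checks
#'
#' Two nested elliptical "cup" surfaces (cylinder walls with a capped
#' bottom): the inner one labeled as LV endocardium with a mitral ring at
#' its rim, the outer one as epicardium. Every short-axis section gives
#' exactly the specified ellipses, so mid-ventricular dimensions and
#' centerline wall thickness have closed forms. With `rv = TRUE` a second
#' inner cup is added to the side, labeled as RV endocardium (septal half
#' facing the LV) with a tricuspid ring, for dimension fixtures.
#'
#' @param rx_endo,ry_endo,rx_epi,ry_epi Ellipse semi-axes (mm).
#' @param height Cup height (mm).
#' @param n_seg Vertices per ring (multiple of 4 keeps axis extents exact).
#' @param rv Add an RV cup (default `FALSE`).
#' @param rv_center,rx_rv,ry_rv RV cup geometry.
#' @return A [biv_mesh()].
#' @export
fixture_walls <- function(rx_endo = 30, ry_endo = 30, rx_epi = 40,
                          ry_epi = 40, height = 80, n_seg = 64,
                          rv = FALSE, rv_center = c(rx_epi + 25, 0, 0),
                          rx_rv = 20, ry_rv = 35) {
  endo <- elliptical_cup(c(0, 0, 0), rx_endo, ry_endo, height, n_seg)
  epi <- elliptical_cup(c(0, 0, -5), rx_epi, ry_epi, height + 10, n_seg)
  pts <- rbind(endo$points, epi$points)
  faces <- rbind(endo$faces, epi$faces + nrow(endo$points))
  labels <- c(rep("LV_ENDO", nrow(endo$points)),
              rep("EPI", nrow(epi$points)))
  labels[endo$ring] <- "MITRAL_RING"
  landmarks <- c(LV_APEX = endo$apex, RV_APEX = endo$apex)
  if (rv) {
    cup <- elliptical_cup(rv_center, rx_rv, ry_rv, height, n_seg)
    off <- nrow(pts)
    septal <- cos(cup$phi) < 0
    rv_labels <- rep("RV_FREEWALL_ENDO", nrow(cup$points))
    for (i in seq_len(cup$n_rows)) {
      rv_labels[cup$idx(i, which(septal))] <- "RV_SEPTAL_ENDO"
    }
    rv_labels[cup$apex] <- "RV_FREEWALL_ENDO"
    rv_labels[cup$ring] <- "TRICUSPID_RING"
    pts <- rbind(pts, cup$points)
    faces <- rbind(faces, cup$faces + off)
    labels <- c(labels, rv_labels)
    landmarks[["RV_APEX"]] <- cup$apex + off
  }
  biv_mesh(pts, faces, labels, landmarks, case_id = "fixture",
           phase = "ED", validate = FALSE)
}

#' Apical-angle fixture with an exact construction angle
#'
#' Two planar strips meeting at the RV apex in the four-chamber plane
#' (y = 0), one labeled as the septal endocardium and one as the RV free
#' wall, each a straight line in that plane; their in-plane directions are
#' symmetric about the long axis and subtend exactly `angle_deg`. Minimal
#' mitral and tricuspid rings are included so the four-chamber plane is
#' constructible. Built for the apical-angle computation only (partial
#' geometry; not a closable ventricle).
#'
#' @param angle_deg Constructed apical angle in degrees.
#' @param strip_len Strip length (mm).
#' @return A [biv_mesh()] (unvalidated partial fixture).
#' @export
fixture_apical_angle <- function(angle_deg = 60, strip_len = 35) {
  apex_rv <- c(30, 0, -55)
  half <- angle_deg / 2 * pi / 180
  d_sep <- c(-sin(half), 0, cos(half))
  d_fw <- c(sin(half), 0, cos(half))
  strip <- function(origin, dir, width = 3) {
    s <- seq(0, strip_len, length.out = 12)
    top <- t(vapply(s, function(t) origin + t * dir + c(0, width, 0),
                    numeric(3)))
    bot <- t(vapply(s, function(t) origin + t * dir - c(0, width, 0),
                    numeric(3)))
    pts <- rbind(top, bot)
    n <- length(s)
    faces <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
      rbind(c(i, i + 1L, n + i + 1L), c(i, n + i + 1L, n + i))
    }))
    list(points = pts, faces = faces)
  }
  sep <- strip(apex_rv, d_sep)
  fw <- strip(apex_rv, d_fw)
  mitral <- cbind(10 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
                  10 * sin(seq(0, 2 * pi, length.out = 9)[-9]),
                  rep(20, 8))
  tric <- rbind(c(30, 1, 25), c(30, -1, 25), c(31, 0, 25))
  lv_apex_pt <- c(0, 0, -60)
  pts <- rbind(sep$points, fw$points, mitral, tric, lv_apex_pt)
  n_sep <- nrow(sep$points)
  n_fw <- nrow(fw$points)
  faces <- rbind(sep$faces, fw$faces + n_sep)
  labels <- c(rep("RV_SEPTAL_ENDO", n_sep), rep("RV_FREEWALL_ENDO", n_fw),
              rep("MITRAL_RING", 8), rep("TRICUSPID_RING", 3), "LV_ENDO")
  landmarks <- c(LV_APEX = nrow(pts), RV_APEX = 1L)
  biv_mesh(pts, faces, labels, landmarks, case_id = "fixture",
           phase = "ED", validate = FALSE)
}

#' Basal-bulge fixture with an exact bulge height
#'
#' Builds an untilted template whose free wall lies entirely below the base
#' plane, then displaces its most basal free-wall vertex to exactly
#' `height` mm above the base plane.
#'
#' @param height Planted bulge height (mm).
#' @param params Template parameters.
#' @return A [biv_mesh()].
#' @export
fixture_bulge <- function(height = 15, params = template_params(
                            tricuspid_tilt = 0, rv_cut_height = 5)) {
  tpl <- make_template(params, validate = FALSE)
  mesh <- tpl$ed
  frame <- reference_frame(mesh)
  fw <- label_vertices(mesh, "RV_FREEWALL_ENDO")
  h <- as.numeric(sweep(mesh$points[fw, , drop = FALSE], 2,
                        frame$base_plane$point) %*% frame$lv_long_axis)
  stopifnot(max(h) < 0)  # construction: free wall below the base plane
  v <- fw[which.max(h)]
  mesh$points[v, ] <- mesh$points[v, ] +
    (height - h[which.max(h)]) * frame$lv_long_axis
  mesh
}

## ---- cohort generation -------------------------------------------------

#' Planted orthonormal deformation modes over the template
#'
#' Builds smooth displacement fields over the concatenated ED+ES shape
#' vector and orthonormalizes them (QR), so the planted population modes
#' are exactly orthogonal unit fields. Available kinds:
#' `"size"` (isotropic scaling of both phases), `"septal"` (translation of
#' material near the interventricular septum along x, both phases),
#' `"apical"` (short-axis dilation weighted towards the apex), and
#' `"septal_systolic"` (septal x-shift of the ES block only: a motion
#' mode).
#'
#' @param template A [case_record()] from [make_template()].
#' @param kinds Character vector of mode kinds (in order).
#' @return Matrix (6N x length(kinds)) with orthonormal columns.
#' @export
planted_modes <- function(template, kinds = c("size", "septal")) {
  ped <- template$ed$points
  pes <- template$es$points
  n <- nrow(ped)
  x_sep <- mean(range(ped[, 1]))
  field <- function(kind) {
    f <- function(p) {
      switch(kind,
        size = sweep(p, 2, colMeans(p)),
        septal = cbind(exp(-((p[, 1] - x_sep) / 35)^2), 0, 0),
        apical = {
          t <- (p[, 3] - min(p[, 3])) / diff(range(p[, 3]))
          w <- (1 - t)^2
          cbind(w * (p[, 1] - mean(p[, 1])), w * (p[, 2] - mean(p[, 2])), 0)
        },
        stop_cs(sprintf("unknown mode kind '%s'", kind), "key"))
    }
    if (kind == "septal_systolic") {
      c(rep(0, 3 * n), as.vector(t(cbind(exp(-((pes[, 1] - x_sep) / 35)^2), 0, 0))))
    } else {
      c(as.vector(t(f(ped))), as.vector(t(f(pes))))
    }
  }
  Q <- vapply(kinds, field, numeric(6 * n))
  # project out the rigid-motion manifold (cohort translations/rotations
  # act on both phases jointly) so alignment cannot absorb planted modes
  ctr <- colMeans(rbind(ped, pes))
  gens <- list(matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE),
               matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE),
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE))
  rigid <- cbind(
    vapply(1:3, function(k) {
      e <- diag(3)[k, ]
      rep(c(as.vector(t(matrix(e, n, 3, byrow = TRUE)))), 2)
    }, numeric(6 * n)),
    vapply(gens, function(G) {
      c(as.vector(t(sweep(ped, 2, ctr) %*% t(G))),
        as.vector(t(sweep(pes, 2, ctr) %*% t(G))))
    }, numeric(6 * n)))
  Rb <- qr.Q(qr(rigid))
  Q <- Q - Rb %*% crossprod(Rb, Q)
  qr_ <- qr(Q)
  if (qr_$rank < length(kinds)) {
    stop_cs("planted mode fields are linearly dependent", "degenerate")
  }
  out <- qr.Q(qr_)
  # keep each mode positively aligned with its raw field
  for (j in seq_len(ncol(out))) {
    if (sum(out[, j] * Q[, j]) < 0) out[, j] <- -out[, j]
  }
  colnames(out) <- kinds
  out
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the covariate structure of a repaired tetralogy of
#' Fallot cohort: age lognormal (median 16 y, IQR 12-24), height and
#' weight growth-linked to age, 60 percent male, tricuspid regurgitation
#' grades with frequencies 0.65/0.20/0.07/0.08, and PRVI lognormal with
#' median 24 and IQR 14-33 ml/m^2. Two planted deformation modes with a
#' 2:1 SD ratio mirror the dominance of the size mode over the next mode.
#' `mode_sds[j]` is the root-mean-square per-coordinate displacement (mm)
#' of a one-SD excursion along mode `j` (the mode coordinate over the
#' unit-norm field is `mode_sds[j] * sqrt(6N)`). `effects` are
#' standardized coefficients (mode-coordinate SDs per predictor SD); the
#' residual mode variation is scaled so each mode's total SD equals
#' `mode_sds[j]`, making planted effects directly recoverable as
#' standardized regression coefficients.
#'
#' @param n_cases Number of cases (default 88).
#' @param params Template parameters.
#' @param mode_kinds Planted mode kinds, see [planted_modes()].
#' @param mode_sds Total SD (mm) of each planted mode coordinate.
#' @param effects Matrix (modes x predictors) of standardized effects;
#'   predictor columns among `prvi`, `height`, `weight`, `age`, `sexM`.
#' @param noise_sd Isotropic per-coordinate vertex noise SD (mm).
#' @param rigid_jitter Maximal per-case rotation (degrees) and translation
#'   (mm), length-2 numeric; `c(0, 0)` disables rigid motion.
#' @param seed Integer seed; all substreams derive from it.
#' @return Object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_cases = 88,
                                  params = template_params(),
                                  mode_kinds = c("size", "septal"),
                                  mode_sds = c(3, 1.5),
                                  effects = default_effects(length(mode_kinds)),
                                  noise_sd = 0.5,
                                  rigid_jitter = c(15, 10),
                                  seed = 1L) {
  if (n_cases < 2) stop_cs("cohort error: need at least 2 cases", "cohort")
  if (length(mode_sds) != length(mode_kinds) || any(mode_sds <= 0)) {
    stop_cs("mode_sds must be positive, one per mode kind", "domain")
  }
  if (!is.null(effects)) {
    effects <- as.matrix(effects)
    if (nrow(effects) != length(mode_kinds)) {
      stop_cs("effects must have one row per planted mode", "domain")
    }
    bad <- setdiff(colnames(effects), c("prvi", "height", "weight", "age", "sexM"))
    if (length(bad) > 0) {
      stop_cs(paste("unknown effect predictor(s):", paste(bad, collapse = ", ")),
              "key")
    }
  }
  structure(list(n_cases = as.integer(n_cases), params = params,
                 mode_kinds = mode_kinds, mode_sds = mode_sds,
                 effects = effects, noise_sd = noise_sd,
                 rigid_jitter = rigid_jitter, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' @rdname synthetic_cohort_spec
#' @param n_modes Number of planted modes.
#' @export
default_effects <- function(n_modes = 2) {
  B <- matrix(0, n_modes, 5,
              dimnames = list(NULL, c("prvi", "height", "weight", "age", "sexM")))
  B[1, ] <- c(-0.15, 0.35, 0.20, 0, 0.15)
  if (n_modes >= 2) B[2, "prvi"] <- 0.30
  B
}

#' Draw a cohort covariate table
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @return Tibble with `case_id`, `age`, `sex`, `height`, `weight`, `prvi`,
#'   `tr_grade`.
#' @export
generate_covariates <- function(n, seed = 1L) {
  set.seed(sub_seed(seed, "covariates"))
  age <- pmin(pmax(stats::rlnorm(n, log(16), 0.535), 5), 60)
  height <- 100 + 70 * (1 - exp(-age / 7)) + rnorm(n, 0, 6)
  bmi <- stats::rlnorm(n, log(22), 0.2)
  weight <- bmi * (height / 100)^2
  sex <- factor(ifelse(runif(n) < 53 / 88, "M", "F"), c("F", "M"))
  prvi <- pmin(stats::rlnorm(n, log(23.7), 0.632), 96)
  tr <- sample(tr_grade_levels(), n, replace = TRUE,
               prob = c(0.648, 0.205, 0.068, 0.080))
  tibble::tibble(
    case_id = sprintf("case%03d", seq_len(n)),
    age = age, sex = sex, height = height, weight = weight, prvi = prvi,
    tr_grade = factor(tr, tr_grade_levels(), ordered = TRUE))
}

# standardized predictor columns used by the planted-effect model
effect_design <- function(covariates) {
  cbind(prvi = as.numeric(scale(covariates$prvi)),
        height = as.numeric(scale(covariates$height)),
        weight = as.numeric(scale(covariates$weight)),
        age = as.numeric(scale(covariates$age)),
        sexM = as.numeric(covariates$sex == "M"))
}

#' Draw covariates and planted mode coordinates (no meshes)
#'
#' The statistical layer of [generate_cohort()]: covariates plus mode
#' coordinates `c[i,j] = mode_sds[j] * (sum_p effects[j,p] x[i,p] + eta)`
#' with the residual SD set so the total coordinate SD is `mode_sds[j]`.
#' Useful for fast regression simulations on score-like data.
#'
#' @inheritParams synthetic_cohort_spec
#' @return List with `covariates` (tibble), `coords` (n x J matrix, mm
#'   units) and `scores` (coords scaled to unit planted SD).
#' @export
generate_mode_data <- function(n_cases, effects = default_effects(),
                               mode_sds = c(6, 3), noise_sd = NULL,
                               seed = 1L) {
  covariates <- generate_covariates(n_cases, seed)
  X <- effect_design(covariates)
  J <- length(mode_sds)
  set.seed(sub_seed(seed, "modes"))
  U <- matrix(0, n_cases, J)
  MU <- matrix(0, n_cases, J)
  resid_sds <- numeric(J)
  for (j in seq_len(J)) {
    mu <- if (is.null(effects)) rep(0, n_cases) else
      as.numeric(X[, colnames(effects), drop = FALSE] %*% effects[j, ])
    s2 <- stats::var(mu)
    resid_sds[j] <- sqrt(max(1 - s2, 0.02))
    MU[, j] <- mu
    U[, j] <- mu + rnorm(n_cases, 0, resid_sds[j])
  }
  coords <- sweep(U, 2, mode_sds, `*`)
  list(covariates = covariates, coords = coords, scores = U,
       systematic = MU, resid_sds = resid_sds, mode_sds = mode_sds)
}

#' Generate a synthetic mesh cohort with ground truth
#'
#' Draws covariates and mode coordinates ([generate_mode_data()]), deforms
#' the ED+ES template shape vector by the planted orthonormal modes, adds
#' isotropic vertex noise and a per-case rigid motion, and returns the
#' cases together with the complete ground truth. Cases whose deformation
#' collapses a cavity (volume below a fifth of the template's) are redrawn
#' with fresh noise, with a warning.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List with `cases` (list of [case_record()]) and `truth` (list:
#'   `coords`, `scores`, `covariates`, `effects`, `mode_sds`, `modes`,
#'   `noise_sd`, `transforms`, `template`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  template <- make_template(spec$params)
  Q <- planted_modes(template, spec$mode_kinds)
  npts <- nrow(template$ed$points)
  # spec mode_sds are per-coordinate RMS (mm); the coordinate over the
  # unit-norm 6N field carries the sqrt(6N) factor
  md <- generate_mode_data(spec$n_cases, spec$effects,
                           spec$mode_sds * sqrt(6 * npts),
                           seed = spec$seed)
  n <- spec$n_cases
  x0 <- c(as.vector(t(template$ed$points)), as.vector(t(template$es$points)))
  vol_lv <- volume_cache(template$ed, "LV")
  vol_rv <- volume_cache(template$ed, "RV")
  v_lv0 <- cached_volume(template$ed$points, vol_lv)
  v_rv0 <- cached_volume(template$ed$points, vol_rv)
  set.seed(sub_seed(spec$seed, "noise"))
  noise <- lapply(seq_len(n), function(i) rnorm(6 * npts, 0, spec$noise_sd))
  set.seed(sub_seed(spec$seed, "rigid"))
  transforms <- lapply(seq_len(n), function(i) {
    if (all(spec$rigid_jitter == 0)) {
      list(R = diag(3), t = c(0, 0, 0))
    } else {
      ang <- runif(1, -spec$rigid_jitter[1], spec$rigid_jitter[1]) * pi / 180
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      list(R = R, t = runif(3, -spec$rigid_jitter[2], spec$rigid_jitter[2]))
    }
  })
  set.seed(sub_seed(spec$seed, "redraw"))
  n_redraw <- 0L
  cases <- vector("list", n)
  J <- length(spec$mode_sds)
  for (i in seq_len(n)) {
    eps <- noise[[i]]
    for (attempt in 1:4) {
      x <- x0 + as.numeric(Q %*% md$coords[i, ]) + eps
      ped <- matrix(x[seq_len(3 * npts)], ncol = 3, byrow = TRUE)
      pes <- matrix(x[3 * npts + seq_len(3 * npts)], ncol = 3, byrow = TRUE)
      ok <- cached_volume(ped, vol_lv) > 0.2 * v_lv0 &&
        cached_volume(ped, vol_rv) > 0.2 * v_rv0
      if (ok) break
      # a degenerate draw: resample the residual mode excursion (keeping
      # the covariate-driven part) and the vertex noise; ground truth is
      # updated accordingly
      n_redraw <- n_redraw + 1L
      md$scores[i, ] <- md$systematic[i, ] + rnorm(J, 0, md$resid_sds)
      md$coords[i, ] <- md$scores[i, ] * md$mode_sds
      eps <- rnorm(6 * npts, 0, spec$noise_sd)
    }
    tr <- transforms[[i]]
    ped <- apply_rigid(ped, tr$R, tr$t)
    pes <- apply_rigid(pes, tr$R, tr$t)
    id <- md$covariates$case_id[i]
    ed <- biv_mesh(ped, template$ed$faces, template$ed$labels,
                   template$ed$landmarks, case_id = id, phase = "ED",
                   validate = FALSE)
    es <- biv_mesh(pes, template$ed$faces, template$ed$labels,
                   template$ed$landmarks, case_id = id, phase = "ES",
                   validate = FALSE)
    cases[[i]] <- case_record(id, ed, es, md$covariates[i, -1])
  }
  if (n_redraw > 0) {
    warn_cs(sprintf("%d case draw(s) regenerated after cavity collapse",
                    n_redraw), "regenerate")
  }
  list(cases = cases,
       truth = list(coords = md$coords, scores = md$scores,
                    covariates = md$covariates, effects = spec$effects,
                    mode_sds = spec$mode_sds, modes = Q,
                    noise_sd = spec$noise_sd, transforms = transforms,
                    template = template, n_redrawn = n_redraw))
}

# precomputed capping/orientation topology for fast per-case volume checks
volume_cache <- function(mesh, chamber) {
  f <- chamber_surface(mesh, chamber)
  loops <- boundary_loops(f)
  npts <- nrow(mesh$points)
  faces <- f
  for (k in seq_along(loops)) {
    loop <- loops[[k]]
    ci <- npts + k
    nl <- length(loop)
    faces <- rbind(faces, cbind(loop, loop[c(2:nl, 1)], rep(ci, nl)))
  }
  list(faces = orient_faces(faces), loops = loops)
}

cached_volume <- function(points, cache) {
  extra <- do.call(rbind, lapply(cache$loops, function(l) {
    colMeans(points[l, , drop = FALSE])
  }))
  pts <- if (is.null(extra)) points else rbind(points, extra)
  abs(signed_volume(pts, cache$faces)) / 1000
}
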
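# Low-level computational geometry shared by the mesh, feature and strain
# modules: rigid registration, surface orientation and capping, enclosed
# volumes, plane-surface intersection contours and polyline utilities.
# All coordinates are in millimetres.

## ---- rigid transforms -------------------------------------------------

# Closed-form least-squares rigid alignment (Kabsch) of corresponded point
# rows X onto Y: returns R (3x3, det +1) and t with  Y ~ X %*% t(R) + t.
kabsch <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d < 0) {
    # proper rotation enforced: no reflections in anatomical alignment
    s$v[, 3] <- -s$v[, 3]
  }
  R <- s$v %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx), reflection = d < 0)
}

apply_rigid <- function(points, R, t) {
  sweep(points %*% t(R), 2, t, `+`)
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

## ---- faces / normals --------------------------------------------------

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_cross <- function(points, faces) {
  u <- points[faces[, 2], , drop = FALSE] - points[faces[, 1], , drop = FALSE]
  v <- points[faces[, 3], , drop = FALSE] - points[faces[, 1], , drop = FALSE]
  cross3(u, v)
}

tri_areas <- function(points, faces) {
  cr <- face_cross(points, faces)
  0.5 * sqrt(rowSums(cr^2))
}

# Area-weighted per-vertex normals (faces assumed consistently wound).
vertex_normals <- function(points, faces) {
  cr <- face_cross(points, faces)
  n <- matrix(0, nrow(points), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      n[, k] <- n[, k] + tabulate2(faces[, j], cr[, k], nrow(points))
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tabulate2 <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

## ---- boundary loops, orientation, capping -----------------------------

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")

# Ordered boundary loops of a triangulated surface. Boundary edges appear in
# exactly one face; with consistent winding each loop is traversed in the
# face direction. Returns a list of integer vertex cycles.
boundary_loops <- function(faces) {
  if (nrow(faces) == 0) return(list())
  e_from <- c(faces[, 1], faces[, 2], faces[, 3])
  e_to   <- c(faces[, 2], faces[, 3], faces[, 1])
  key <- edge_key(e_from, e_to)
  cnt <- table(key)
  bnd <- key %in% names(cnt)[cnt == 1]
  if (!any(bnd)) return(list())
  from <- e_from[bnd]
  to <- e_to[bnd]
  nxt <- setNames(to, as.character(from))
  loops <- list()
  used <- setNames(rep(FALSE, length(from)), as.character(from))
  for (s in as.character(from)) {
    if (used[[s]]) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (is.na(nxt[cur]) || isTRUE(used[[cur]])) break
      used[[cur]] <- TRUE
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == s) break
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# Make face windings consistent across each connected component (breadth
# first over shared edges). Needed before signed-volume integration when
# the input winding is untrusted.
orient_faces <- function(faces) {
  nf <- nrow(faces)
  if (nf == 0) return(faces)
  ekeys <- matrix(c(edge_key(faces[, 1], faces[, 2]),
                    edge_key(faces[, 2], faces[, 3]),
                    edge_key(faces[, 3], faces[, 1])), ncol = 3)
  face_of <- split(rep(seq_len(nf), 3), as.vector(ekeys))
  flipped <- rep(FALSE, nf)
  visited <- rep(FALSE, nf)
  dir_edges <- function(i) {
    f <- faces[i, ]
    if (flipped[i]) f <- f[c(1, 3, 2)]
    rbind(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))
  }
  for (root in seq_len(nf)) {
    if (visited[root]) next
    queue <- root
    visited[root] <- TRUE
    while (length(queue) > 0) {
      i <- queue[[1]]
      queue <- queue[-1]
      de_i <- dir_edges(i)
      for (r in 1:3) {
        k <- edge_key(de_i[r, 1], de_i[r, 2])
        for (j in face_of[[k]]) {
          if (j == i || visited[j]) next
          de_j <- dir_edges(j)
          same <- any(de_j[, 1] == de_i[r, 1] & de_j[, 2] == de_i[r, 2])
          if (same) flipped[j] <- TRUE
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  out <- faces
  out[flipped, ] <- out[flipped, c(1, 3, 2), drop = FALSE]
  out
}

# Cap each boundary loop by a triangle fan to the loop centroid; the fan is
# wound with the loop so a consistently oriented surface stays consistent.
cap_boundary_loops <- function(points, faces, loops = NULL) {
  if (is.null(loops)) loops <- boundary_loops(faces)
  for (loop in loops) {
    centroid <- colMeans(points[loop, , drop = FALSE])
    ci <- nrow(points) + 1L
    points <- rbind(points, centroid)
    nl <- length(loop)
    fan <- cbind(loop, loop[c(2:nl, 1)], rep(ci, nl))
    faces <- rbind(faces, fan)
  }
  list(points = points, faces = faces)
}

signed_volume <- function(points, faces) {
  p1 <- points[faces[, 1], , drop = FALSE]
  p2 <- points[faces[, 2], , drop = FALSE]
  p3 <- points[faces[, 3], , drop = FALSE]
  sum(rowSums(p1 * cross3(p2, p3))) / 6
}

# Volume (mm^3) enclosed by a surface after capping its boundary loops.
enclosed_volume <- function(points, faces, orient = TRUE) {
  capped <- cap_boundary_loops(points, faces)
  f <- capped$faces
  if (orient) f <- orient_faces(f)
  abs(signed_volume(capped$points, f))
}

## ---- planes and contours ----------------------------------------------

plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

# Intersection of a triangulated surface with the plane through p0 with
# normal n. Segments from individual triangles are chained through shared
# mesh edges into polylines. Returns a list of 3D point matrices, each with
# attribute "closed".
plane_polylines <- function(points, faces, p0, n) {
  n <- n / sqrt(sum(n^2))
  d <- as.numeric(sweep(points, 2, p0) %*% n)
  scale <- max(abs(d), 1)
  eps <- 1e-9 * scale
  d[abs(d) < eps] <- eps  # nudge on-plane vertices off the plane
  fs <- matrix(d[faces], ncol = 3)
  crossing <- rowSums(fs > 0) %in% c(1L, 2L)
  if (!any(crossing)) return(list())
  fc <- faces[crossing, , drop = FALSE]
  segs_a <- character(0); segs_b <- character(0)
  pts_env <- new.env(parent = emptyenv())
  edge_point <- function(i, j) {
    k <- edge_key(i, j)
    if (is.null(pts_env[[k]])) {
      t <- d[i] / (d[i] - d[j])
      pts_env[[k]] <- points[i, ] + t * (points[j, ] - points[i, ])
    }
    k
  }
  for (r in seq_len(nrow(fc))) {
    v <- fc[r, ]
    dv <- d[v]
    cross_edges <- list()
    pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))
    for (q in 1:3) {
      i <- v[pairs[q, 1]]; j <- v[pairs[q, 2]]
      if (d[i] * d[j] < 0) cross_edges[[length(cross_edges) + 1]] <- c(i, j)
    }
    if (length(cross_edges) != 2) next
    ka <- edge_point(cross_edges[[1]][1], cross_edges[[1]][2])
    kb <- edge_point(cross_edges[[2]][1], cross_edges[[2]][2])
    segs_a <- c(segs_a, ka); segs_b <- c(segs_b, kb)
  }
  if (length(segs_a) == 0) return(list())
  # chain segments: nodes are crossing edges, links are triangles
  nodes <- unique(c(segs_a, segs_b))
  adj <- new.env(parent = emptyenv())
  for (k in nodes) adj[[k]] <- character(0)
  for (r in seq_along(segs_a)) {
    adj[[segs_a[r]]] <- c(adj[[segs_a[r]]], segs_b[r])
    adj[[segs_b[r]]] <- c(adj[[segs_b[r]]], segs_a[r])
  }
  degree <- vapply(nodes, function(k) length(adj[[k]]), integer(1))
  visited <- new.env(parent = emptyenv())
  polylines <- list()
  walk <- function(start) {
    path <- start
    visited[[start]] <- TRUE
    cur <- start
    repeat {
      nb <- adj[[cur]]
      nb <- nb[vapply(nb, function(k) is.null(visited[[k]]), logical(1))]
      if (length(nb) == 0) break
      cur <- nb[[1]]
      visited[[cur]] <- TRUE
      path <- c(path, cur)
    }
    path
  }
  # open chains first (start at degree-1 nodes), then remaining cycles
  for (k in nodes[degree == 1]) {
    if (!is.null(visited[[k]])) next
    path <- walk(k)
    P <- do.call(rbind, lapply(path, function(q) pts_env[[q]]))
    attr(P, "closed") <- FALSE
    polylines[[length(polylines) + 1]] <- P
  }
  for (k in nodes) {
    if (!is.null(visited[[k]])) next
    path <- walk(k)
    if (length(path) < 3) next
    P <- do.call(rbind, lapply(path, function(q) pts_env[[q]]))
    attr(P, "closed") <- TRUE
    polylines[[length(polylines) + 1]] <- P
  }
  polylines
}

longest_polyline <- function(polys, closed = NULL) {
  if (length(polys) == 0) return(NULL)
  if (!is.null(closed)) {
    polys <- Filter(function(p) isTRUE(attr(p, "closed")) == closed, polys)
    if (length(polys) == 0) return(NULL)
  }
  lens <- vapply(polys, function(p) polyline_length(p, isTRUE(attr(p, "closed"))),
                 numeric(1))
  polys[[which.max(lens)]]
}

polyline_length <- function(P, closed = isTRUE(attr(P, "closed"))) {
  if (is.null(P) || nrow(P) < 2) return(0)
  Q <- if (closed) rbind(P, P[1, , drop = FALSE]) else P
  sum(sqrt(rowSums(diff(Q)^2)))
}

# Resample a polyline at m points equally spaced in arc length.
resample_polyline <- function(P, m, closed = isTRUE(attr(P, "closed"))) {
  Q <- if (closed) rbind(P, P[1, , drop = FALSE]) else P
  seg <- sqrt(rowSums(diff(Q)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  targets <- if (closed) seq(0, L, length.out = m + 1)[seq_len(m)] else
    seq(0, L, length.out = m)
  out <- matrix(0, length(targets), ncol(P))
  for (i in seq_along(targets)) {
    t <- targets[i]
    j <- findInterval(t, s, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(Q) - 1L)
    w <- if (seg[j] > 0) (t - s[j]) / seg[j] else 0
    out[i, ] <- Q[j, ] + w * (Q[j + 1, ] - Q[j, ])
  }
  attr(out, "closed") <- closed
  out
}

project_to_plane <- function(P, p0, basis) {
  rel <- sweep(P, 2, p0)
  cbind(as.numeric(rel %*% basis$e1), as.numeric(rel %*% basis$e2))
}

# Total-least-squares line fit in 2D: centroid + unit direction (first
# principal axis); also returns RMS orthogonal residual.
tls_line_2d <- function(P2) {
  c0 <- colMeans(P2)
  X <- sweep(P2, 2, c0)
  s <- svd(X, nu = 0)
  dir <- s$v[, 1]
  resid <- as.numeric(X %*% s$v[, 2])
  list(centroid = c0, dir = dir, rms = sqrt(mean(resid^2)),
       sv = s$d)
}

# Total-least-squares plane fit: centroid + unit normal (smallest principal
# direction). Errors on (near-)collinear input.
fit_plane <- function(P, tol = 1e-8) {
  c0 <- colMeans(P)
  X <- sweep(P, 2, c0)
  s <- svd(X, nu = 0)
  if (nrow(P) < 3 || s$d[2] <= tol * max(s$d[1], 1)) {
    stop_cs("plane fit is degenerate: points are collinear", "degenerate")
  }
  list(centroid = c0, normal = s$v[, 3], sv = s$d)
}

angle_deg <- function(u, v, acute = TRUE) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  if (acute) cu <- abs(cu)
  acos(pmin(pmax(cu, -1), 1)) * 180 / pi
}

extent_along <- function(P2, u) {
  p <- as.numeric(P2 %*% (u / sqrt(sum(u^2))))
  max(p) - min(p)
}

# Crossings of the infinite 2D line q + t*u with a polygon/polyline's
# segments; returns sorted signed parameters t.
line_polyline_crossings <- function(P2, q, u, closed = TRUE) {
  u <- u / sqrt(sum(u^2))
  nrm <- c(-u[2], u[1])
  Q <- if (closed) rbind(P2, P2[1, , drop = FALSE]) else P2
  a <- Q[-nrow(Q), , drop = FALSE]
  b <- Q[-1, , drop = FALSE]
  da <- as.numeric(sweep(a, 2, q) %*% nrm)
  db <- as.numeric(sweep(b, 2, q) %*% nrm)
  hit <- da * db <= 0 & (da != db)
  if (!any(hit)) return(numeric(0))
  w <- da[hit] / (da[hit] - db[hit])
  pts <- a[hit, , drop = FALSE] + w * (b[hit, , drop = FALSE] - a[hit, , drop = FALSE])
  sort(as.numeric(sweep(pts, 2, q) %*% u))
}

point_in_polygon <- function(pt, P2) {
  x <- P2[, 1]; y <- P2[, 2]
  n <- nrow(P2)
  j <- c(n, seq_len(n - 1))
  inter <- ((y > pt[2]) != (y[j] > pt[2])) &
    (pt[1] < (x[j] - x) * (pt[2] - y) / (y[j] - y) + x)
  sum(inter) %% 2 == 1
}

# First intersection of rays (origins O, unit directions D) with a triangle
# soup; Moller-Trumbore, vectorised over faces for each ray. Returns the
# hit distance (NA where the ray misses).
ray_mesh_distance <- function(points, faces, O, D, eps = 1e-9) {
  v0 <- points[faces[, 1], , drop = FALSE]
  e1 <- points[faces[, 2], , drop = FALSE] - v0
  e2 <- points[faces[, 3], , drop = FALSE] - v0
  out <- rep(NA_real_, nrow(O))
  for (i in seq_len(nrow(O))) {
    d <- D[i, ]
    h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
               d[3] * e2[, 1] - d[1] * e2[, 3],
               d[1] * e2[, 2] - d[2] * e2[, 1])
    a <- rowSums(e1 * h)
    ok <- abs(a) > eps
    s <- sweep(v0, 2, O[i, ], `-`) * -1  # O - v0
    u <- rowSums(s * h) / a
    q <- cross3(s, e1)
    v <- rowSums(sweep(q, 2, d, `*`)) / a
    t <- rowSums(e2 * q) / a
    hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t > eps
    if (any(hit)) out[i] <- min(t[hit])
  }
  out
}
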
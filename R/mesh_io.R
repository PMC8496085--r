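# Mesh and table I/O. Meshes are exchanged as ASCII PLY, Wavefront OBJ or
# legacy ASCII VTK polydata; vertex labels and landmarks travel in a sidecar
# CSV (columns vertex_index,label[,landmark], 1-based indices) or, for VTK,
# as an integer point-data array coding labels in biv_labels() order.

mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "obj", "vtk")) {
    stop_cs(sprintf("unsupported mesh format '.%s' (use .ply, .obj or .vtk)", ext),
            "io")
  }
  ext
}

#' Write a mesh to PLY, OBJ or VTK polydata (ASCII)
#'
#' The format is chosen from the file extension. VTK files additionally
#' carry the vertex labels as an integer point-data array (codes follow
#' [biv_labels()] order, 0-based); PLY and OBJ need the sidecar label table
#' written by [write_labels_csv()].
#'
#' @param mesh A [biv_mesh()].
#' @param path Output file path ending in `.ply`, `.obj` or `.vtk`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  fmt <- mesh_format(path)
  p <- mesh$points
  f <- mesh$faces
  lines <- switch(fmt,
    obj = c(sprintf("v %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
            sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(p)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
            sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
    vtk = {
      codes <- match(mesh$labels, biv_labels()) - 1L
      c("# vtk DataFile Version 3.0", "cardioshape biventricular surface",
        "ASCII", "DATASET POLYDATA",
        sprintf("POINTS %d double", nrow(p)),
        sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
        sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
        sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
        sprintf("POINT_DATA %d", nrow(p)),
        "SCALARS label int 1", "LOOKUP_TABLE default",
        sprintf("%d", codes))
    })
  writeLines(lines, path)
  invisible(path)
}

read_mesh_raw <- function(path) {
  if (!file.exists(path)) stop_cs(sprintf("file not found: %s", path), "io")
  fmt <- mesh_format(path)
  lines <- readLines(path, warn = FALSE)
  switch(fmt, obj = read_obj_lines(lines), ply = read_ply_lines(lines),
         vtk = read_vtk_lines(lines, path))
}

read_obj_lines <- function(lines) {
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0) stop_cs("malformed OBJ file", "io")
  pts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  fidx <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                function(x) as.integer(sub("/.*", "", x[1:3]))))
  list(points = pts, faces = fidx, labels = NULL)
}

read_ply_lines <- function(lines) {
  hd_end <- which(lines == "end_header")[1]
  if (is.na(hd_end)) stop_cs("malformed PLY file: no end_header", "io")
  header <- lines[seq_len(hd_end)]
  if (!any(grepl("^format ascii", header))) {
    stop_cs("only ASCII PLY is supported", "io")
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop_cs("malformed PLY header", "io")
  body <- lines[(hd_end + 1):length(lines)]
  vlines <- body[seq_len(nv)]
  flines <- body[nv + seq_len(nf)]
  pts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  fidx <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop_cs("non-triangular face in PLY file", "io")
    x[2:4] + 1L
  }))
  list(points = pts, faces = fidx, labels = NULL)
}

read_vtk_lines <- function(lines, path) {
  if (!any(grepl("^ASCII", lines))) stop_cs("only ASCII VTK is supported", "io")
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop_cs(sprintf("malformed VTK file: %s", path), "io")
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  # points may wrap across lines; take the first 3*nv numbers after POINTS
  pt_block <- scan(text = paste(lines[(ip + 1):(grep("^POLYGONS", lines)[1] - 1)],
                                collapse = " "), quiet = TRUE)
  if (length(pt_block) < 3 * nv) stop_cs("truncated VTK POINTS block", "io")
  pts <- matrix(pt_block[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(lines[ig], "\\s+")[[1]][2])
  end_poly <- length(lines)
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd) > 0) end_poly <- ipd[1] - 1
  poly_block <- scan(text = paste(lines[(ig + 1):end_poly], collapse = " "),
                     quiet = TRUE)
  fidx <- matrix(NA_integer_, nf, 3)
  pos <- 1
  for (i in seq_len(nf)) {
    k <- poly_block[pos]
    if (k != 3) stop_cs("non-triangular polygon in VTK file", "io")
    fidx[i, ] <- as.integer(poly_block[pos + 1:3]) + 1L
    pos <- pos + k + 1
  }
  labels <- NULL
  isc <- grep("^SCALARS label", lines)
  if (length(isc) > 0) {
    codes <- scan(text = paste(lines[(isc[1] + 2):length(lines)], collapse = " "),
                  quiet = TRUE)
    codes <- as.integer(codes[seq_len(nv)])
    labels <- biv_labels()[codes + 1L]
  }
  list(points = pts, faces = fidx, labels = labels)
}

#' Write / read the sidecar label table
#'
#' CSV with columns `vertex_index` (1-based), `label`, and `landmark`
#' (empty, `LV_APEX` or `RV_APEX`).
#'
#' @param mesh A [biv_mesh()].
#' @param path CSV path.
#' @return `path` (write) or a list with `labels` and `landmarks` (read).
#' @export
write_labels_csv <- function(mesh, path) {
  lmk <- rep("", nrow(mesh$points))
  lmk[mesh$landmarks[["LV_APEX"]]] <- "LV_APEX"
  lmk[mesh$landmarks[["RV_APEX"]]] <- "RV_APEX"
  df <- data.frame(vertex_index = seq_len(nrow(mesh$points)),
                   label = mesh$labels, landmark = lmk)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop_cs(sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "label") %in% names(df))) {
    stop_cs("label table needs columns vertex_index,label", "labeling")
  }
  n <- max(df$vertex_index)
  labels <- rep(NA_character_, n)
  labels[df$vertex_index] <- df$label
  landmarks <- integer(0)
  if ("landmark" %in% names(df)) {
    for (nm in c("LV_APEX", "RV_APEX")) {
      idx <- df$vertex_index[!is.na(df$landmark) & df$landmark == nm]
      if (length(idx) == 1) landmarks[[nm]] <- idx
    }
  }
  list(labels = labels, landmarks = landmarks)
}

#' Read one case (ED + ES meshes, labels, covariates)
#'
#' Reads the two phase meshes, attaches labels and landmarks (from the VTK
#' point-data array when present, otherwise from the sidecar CSV), validates
#' all mesh invariants and the ED/ES correspondence, and bundles an optional
#' covariate row into a [case_record()].
#'
#' @param ed_path,es_path Mesh files (`.ply`, `.obj` or `.vtk`).
#' @param labels_path Sidecar label CSV (see [read_labels_csv()]); required
#'   for PLY/OBJ, optional for VTK (landmarks still come from the sidecar if
#'   given).
#' @param covariates Optional covariate row (named list or one-row data
#'   frame), see [case_record()].
#' @param case_id Case identifier; defaults to the ED file stem.
#' @return A validated [case_record()].
#' @export
read_case <- function(ed_path, es_path, labels_path = NULL,
                      covariates = NULL, case_id = NULL) {
  case_id <- case_id %||% sub("_(ed|ES|ed)$", "",
                              tools::file_path_sans_ext(basename(ed_path)))
  ed_raw <- read_mesh_raw(ed_path)
  es_raw <- read_mesh_raw(es_path)
  labels <- ed_raw$labels
  landmarks <- NULL
  if (!is.null(labels_path)) {
    side <- read_labels_csv(labels_path)
    labels <- labels %||% side$labels
    landmarks <- side$landmarks
  }
  if (is.null(labels)) {
    stop_cs("labeling error: no vertex labels (VTK point data or sidecar CSV required)",
            "labeling")
  }
  if (anyNA(labels) || length(labels) != nrow(ed_raw$points)) {
    stop_cs("labeling error: label table does not cover all vertices", "labeling")
  }
  if (is.null(landmarks) || !all(c("LV_APEX", "RV_APEX") %in% names(landmarks))) {
    stop_cs("labeling error: landmarks LV_APEX and RV_APEX not found in label table",
            "labeling")
  }
  if (nrow(es_raw$points) != nrow(ed_raw$points)) {
    stop_cs(sprintf("correspondence error: ED has %d vertices, ES has %d",
                    nrow(ed_raw$points), nrow(es_raw$points)), "correspondence")
  }
  ed <- biv_mesh(ed_raw$points, ed_raw$faces, labels, landmarks,
                 case_id = case_id, phase = "ED")
  es <- biv_mesh(es_raw$points, es_raw$faces, labels, landmarks,
                 case_id = case_id, phase = "ES")
  case_record(case_id, ed, es, covariates)
}

#' Write a case to disk
#'
#' @param case A [case_record()].
#' @param dir Output directory (created if missing).
#' @param format `"vtk"`, `"ply"` or `"obj"`.
#' @return Named character vector of the files written.
#' @export
write_case <- function(case, dir, format = c("vtk", "ply", "obj")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ed_path <- file.path(dir, sprintf("%s_ED.%s", case$case_id, format))
  es_path <- file.path(dir, sprintf("%s_ES.%s", case$case_id, format))
  lab_path <- file.path(dir, sprintf("%s_labels.csv", case$case_id))
  write_mesh(case$ed, ed_path)
  write_mesh(case$es, es_path)
  write_labels_csv(case$ed, lab_path)
  invisible(c(ed = ed_path, es = es_path, labels = lab_path))
}

#' Read a cohort covariate table
#'
#' CSV with header `case_id,age,sex,height,weight,prvi,tr_grade`.
#'
#' @param path CSV path.
#' @return A tibble with typed columns (sex and tr_grade as factors).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_cs(sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("case_id", "age", "sex", "height", "weight", "prvi", "tr_grade")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop_cs(paste("covariate table missing column(s):",
                  paste(missing, collapse = ", ")), "io")
  }
  tibble::tibble(
    case_id = as.character(df$case_id),
    age = as.numeric(df$age),
    sex = factor(df$sex, c("F", "M")),
    height = as.numeric(df$height),
    weight = as.numeric(df$weight),
    prvi = as.numeric(df$prvi),
    tr_grade = factor(df$tr_grade, tr_grade_levels(), ordered = TRUE))
}

#' @rdname read_covariates
#' @param covariates Tibble as returned by [read_covariates()].
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(as.data.frame(covariates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
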
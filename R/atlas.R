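#' Generalized Procrustes alignment of a mesh cohort
#'
#' Iteratively aligns every case's ED point set to the evolving mean by
#' closed-form least-squares rigid registration (rotation + translation
#' only; no scaling, and reflections are projected back to proper
#' rotations). The mean is initialized from the first case in sorted
#' case-id order and updated until its RMS change falls below `tol`. Each
#' case's ED transform is recorded and applied unchanged to its ES mesh.
#'
#' @param cases List of [case_record()]s (at least 2) with corresponded
#'   meshes.
#' @param tol Convergence tolerance on the RMS mean change (mm).
#' @param max_iter Maximum number of mean updates.
#' @return List of class `biv_alignment`: `cases` (aligned case records, in
#'   sorted case-id order), `transforms` (per-case list of `R`, `t`),
#'   `mean_points` (consensus ED mean), `objective` (per-iteration mean of
#'   squared distances to the mean), `iterations`, `converged`.
#' @export
procrustes_align <- function(cases, tol = 1e-6, max_iter = 100) {
  if (length(cases) < 2) {
    stop_cs("cohort error: generalized Procrustes alignment needs >= 2 cases",
            "cohort")
  }
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  cases <- cases[order(ids)]
  ref <- cases[[1]]$ed
  for (cs in cases[-1]) {
    check_correspondence(ref, cs$ed,
                         sprintf("cases '%s' and '%s'", cases[[1]]$case_id,
                                 cs$case_id))
  }
  P <- lapply(cases, function(cs) cs$ed$points)
  n <- length(P)
  mean_pts <- P[[1]]
  objective <- numeric(0)
  converged <- FALSE
  transforms <- NULL
  aligned <- P
  it <- 0
  refl_count <- 0L
  while (it < max_iter) {
    it <- it + 1
    transforms <- lapply(P, function(X) kabsch(X, mean_pts))
    refl_count <- refl_count + sum(vapply(transforms, `[[`, logical(1),
                                          "reflection"))
    aligned <- Map(function(X, tr) apply_rigid(X, tr$R, tr$t), P, transforms)
    new_mean <- Reduce(`+`, aligned) / n
    objective <- c(objective, mean(vapply(aligned, function(A) {
      mean(rowSums((A - new_mean)^2))
    }, numeric(1))))
    delta <- sqrt(mean((new_mean - mean_pts)^2))
    mean_pts <- new_mean
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (refl_count > 0) {
    warn_cs(sprintf(
      "%d optimal fits required a reflection; projected to proper rotations",
      refl_count), "reflection")
  }
  out_cases <- Map(function(cs, tr) {
    ed <- cs$ed; es <- cs$es
    ed$points <- apply_rigid(ed$points, tr$R, tr$t)
    es$points <- apply_rigid(es$points, tr$R, tr$t)
    case_record(cs$case_id, ed, es, cs$covariates)
  }, cases, transforms)
  structure(list(cases = out_cases, transforms = transforms,
                 mean_points = mean_pts, objective = objective,
                 iterations = it, converged = converged),
            class = "biv_alignment")
}

#' Combined ED+ES shape vectors
#'
#' Flattens each aligned case into a single vector: the ED coordinates
#' (x, y, z per vertex in template order) followed by the ES coordinates,
#' giving vectors of length 6N so shape and systolic motion enter the
#' atlas jointly.
#'
#' @param alignment A `biv_alignment` from [procrustes_align()], or a plain
#'   list of aligned [case_record()]s.
#' @return Numeric matrix (cases x 6N) with case ids as row names.
#' @export
build_shape_vectors <- function(alignment) {
  cases <- if (inherits(alignment, "biv_alignment")) alignment$cases else alignment
  ref <- cases[[1]]$ed
  X <- t(vapply(cases, function(cs) {
    check_correspondence(ref, cs$ed, "cohort meshes")
    c(as.vector(t(cs$ed$points)), as.vector(t(cs$es$points)))
  }, numeric(6 * nrow(ref$points))))
  rownames(X) <- vapply(cases, function(cs) cs$case_id, character(1))
  if (!all(is.finite(X))) stop_cs("non-finite shape vector entries", "geometry")
  X
}

#' Fit a PCA shape atlas
#'
#' Principal component analysis of mean-centered combined shape vectors by
#' economy singular value decomposition. Mode variances are
#' `lambda_k = s_k^2 / (n - 1)`; modes are limited to the data rank and
#' carry a deterministic sign (largest-magnitude loading positive). The
#' retained mode count `K` is the smallest number of leading modes whose
#' cumulative variance fraction reaches `var_threshold` (or an explicit
#' `n_modes`).
#'
#' @param X Shape-vector matrix from [build_shape_vectors()].
#' @param var_threshold Cumulative variance fraction to retain (default
#'   0.90).
#' @param n_modes Optional explicit retained mode count (overrides the
#'   threshold).
#' @param template Optional template [biv_mesh()] (or [case_record()]) used
#'   to split reconstructed vectors back into ED/ES meshes.
#' @return Object of class `biv_atlas` with elements `mu` (mean shape,
#'   6N), `modes` (6N x K_max orthonormal columns), `lambda` (variances,
#'   mm^2), `frac`, `cumfrac`, `K`, `n_cases`, `template`.
#' @export
fit_shape_atlas <- function(X, var_threshold = 0.90, n_modes = NULL,
                            template = NULL) {
  if (nrow(X) < 2) stop_cs("cohort error: PCA needs >= 2 cases", "cohort")
  if (!is.null(template) && inherits(template, "case_record")) {
    template <- template$ed
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  n <- nrow(X)
  s <- svd(Xc, nu = 0)
  tol <- max(s$d) * 1e-10
  rank <- sum(s$d > tol)
  if (rank == 0) {
    warn_cs("zero-variance cohort: atlas has no modes", "degenerate")
    return(structure(list(mu = mu, modes = matrix(0, ncol(X), 0),
                          lambda = numeric(0), frac = numeric(0),
                          cumfrac = numeric(0), K = 0L, n_cases = n,
                          var_threshold = var_threshold,
                          template = template),
                     class = "biv_atlas"))
  }
  V <- s$v[, seq_len(rank), drop = FALSE]
  lambda <- s$d[seq_len(rank)]^2 / (n - 1)
  # deterministic sign: largest-|loading| entry of each mode positive
  for (k in seq_len(rank)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  frac <- lambda / sum(lambda)
  cumfrac <- cumsum(frac)
  K <- if (!is.null(n_modes)) min(as.integer(n_modes), rank) else
    n_modes_for_fraction(lambda, var_threshold)
  structure(list(mu = mu, modes = V, lambda = lambda, frac = frac,
                 cumfrac = cumfrac, K = K, n_cases = n,
                 var_threshold = var_threshold, template = template),
            class = "biv_atlas")
}

#' Smallest mode count reaching a cumulative variance fraction
#'
#' @param lambda Non-increasing per-mode variances.
#' @param threshold Target cumulative fraction in (0, 1].
#' @return Integer mode count.
#' @export
n_modes_for_fraction <- function(lambda, threshold = 0.90) {
  if (length(lambda) == 0) return(0L)
  if (threshold <= 0 || threshold > 1) {
    stop_cs("variance threshold must be in (0, 1]", "domain")
  }
  cf <- cumsum(lambda) / sum(lambda)
  as.integer(which(cf >= threshold - 1e-12)[1])
}

#' @export
print.biv_atlas <- function(x, ...) {
  cat(sprintf("<biv_atlas> %d cases, %d modes (rank), K = %d retained (%.1f%% of variance)\n",
              x$n_cases, length(x$lambda), x$K,
              if (x$K > 0) 100 * x$cumfrac[x$K] else 0))
  invisible(x)
}

#' Morphometric scores
#'
#' Projects shape vectors onto the atlas modes. Standardized scores
#' (`z_k = (x - mu) . phi_k / sqrt(lambda_k)`) have unit sample variance
#' over the training cohort and are the "amount of each mode present";
#' raw projections (mm) are returned when `standardize = FALSE`.
#'
#' @param atlas A [fit_shape_atlas()] result.
#' @param X Shape-vector matrix (or single vector).
#' @param modes Mode indices (default `1:K`).
#' @param standardize Divide by `sqrt(lambda_k)` (default `TRUE`).
#' @return Tibble with `case_id` and one `z<k>` (or `raw<k>`) column per
#'   mode.
#' @export
score_shapes <- function(atlas, X, modes = seq_len(atlas$K),
                         standardize = TRUE) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list("case"))
  if (ncol(X) != length(atlas$mu)) {
    stop_cs(sprintf("shape vectors have %d entries; atlas expects %d",
                    ncol(X), length(atlas$mu)), "correspondence")
  }
  if (length(modes) == 0 || max(modes) > length(atlas$lambda)) {
    stop_cs("requested mode beyond the atlas rank", "key")
  }
  if (standardize && any(atlas$lambda[modes] <= 0)) {
    stop_cs("undefined score: zero-variance mode requested", "degenerate")
  }
  Z <- sweep(X, 2, atlas$mu) %*% atlas$modes[, modes, drop = FALSE]
  if (standardize) Z <- sweep(Z, 2, sqrt(atlas$lambda[modes]), `/`)
  colnames(Z) <- paste0(if (standardize) "z" else "raw", modes)
  dplyr::bind_cols(tibble::tibble(case_id = rownames(X) %||%
                                    paste0("case", seq_len(nrow(X)))),
                   tibble::as_tibble(Z))
}

#' Reconstruct a shape from morphometric scores
#'
#' `x = mu + sum_k z_k sqrt(lambda_k) phi_k`. With a template attached to
#' the atlas the vector is split back into ED and ES meshes on the
#' template connectivity.
#'
#' @param atlas A [fit_shape_atlas()] result.
#' @param scores Numeric vector of standardized scores for modes `1..m`
#'   (`m <= K_max`), or a one-row tibble from [score_shapes()].
#' @param as_mesh Return ED/ES meshes (requires a template; default when a
#'   template is available).
#' @return Shape vector, or list with `vector`, `ed`, `es`.
#' @export
reconstruct_shape <- function(atlas, scores, as_mesh = !is.null(atlas$template)) {
  if (is.data.frame(scores)) {
    scores <- as.numeric(scores[1, grep("^z", names(scores))])
  }
  m <- length(scores)
  if (m > length(atlas$lambda)) {
    stop_cs("more scores than atlas modes", "key")
  }
  x <- atlas$mu
  if (m > 0) {
    x <- x + as.numeric(atlas$modes[, seq_len(m), drop = FALSE] %*%
                          (scores * sqrt(atlas$lambda[seq_len(m)])))
  }
  if (!as_mesh) return(x)
  split_shape_vector(atlas, x)
}

#' @rdname reconstruct_shape
#' @param x Shape vector of length 6N.
#' @export
split_shape_vector <- function(atlas, x) {
  tpl <- atlas$template
  if (is.null(tpl)) stop_cs("atlas has no template to split meshes on", "domain")
  npts <- nrow(tpl$points)
  stopifnot(length(x) == 6 * npts)
  ped <- matrix(x[seq_len(3 * npts)], ncol = 3, byrow = TRUE)
  pes <- matrix(x[3 * npts + seq_len(3 * npts)], ncol = 3, byrow = TRUE)
  list(vector = x,
       ed = biv_mesh(ped, tpl$faces, tpl$labels, tpl$landmarks,
                     case_id = "reconstruction", phase = "ED", validate = FALSE),
       es = biv_mesh(pes, tpl$faces, tpl$labels, tpl$landmarks,
                     case_id = "reconstruction", phase = "ES", validate = FALSE))
}

#' Align, vectorize and fit an atlas in one call
#'
#' @inheritParams procrustes_align
#' @inheritParams fit_shape_atlas
#' @return List with `alignment`, `X`, `atlas`, `scores` (training-cohort
#'   standardized scores).
#' @export
build_atlas <- function(cases, var_threshold = 0.90, n_modes = NULL,
                        tol = 1e-6, max_iter = 100) {
  alignment <- procrustes_align(cases, tol = tol, max_iter = max_iter)
  X <- build_shape_vectors(alignment)
  template <- alignment$cases[[1]]$ed
  atlas <- fit_shape_atlas(X, var_threshold = var_threshold,
                           n_modes = n_modes, template = template)
  scores <- score_shapes(atlas, X)
  list(alignment = alignment, X = X, atlas = atlas, scores = scores)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-mode variance table of an atlas
#'
#' @param x A `biv_atlas`.
#' @param ... Unused.
#' @return Tibble with `mode`, `variance` (mm^2), `frac`, `cumfrac`,
#'   `retained`.
#' @export
tidy.biv_atlas <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$lambda), variance = x$lambda,
                 frac = x$frac, cumfrac = x$cumfrac,
                 retained = seq_along(x$lambda) <= x$K)
}

#' @rdname tidy.biv_atlas
#' @export
glance.biv_atlas <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, rank = length(x$lambda), K = x$K,
                 var_threshold = x$var_threshold,
                 var_captured = if (x$K > 0) x$cumfrac[x$K] else 0)
}

#' Scree plot of an atlas
#'
#' @param object A `biv_atlas`.
#' @param ... Unused.
#' @return A ggplot: per-mode variance fraction with the cumulative curve
#'   and retained-mode cutoff.
#' @export
autoplot.biv_atlas <- function(object, ...) {
  df <- tidy.biv_atlas(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$frac, fill = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumfrac)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumfrac)) +
    ggplot2::geom_hline(yintercept = object$var_threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "mode", y = "variance fraction",
                  title = "Shape-mode variance spectrum") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
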
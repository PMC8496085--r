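#' Standardized design matrix for shape regression
#'
#' Continuous predictors (PRVI, height, weight, age — or BSA in place of
#' height and weight with `use_bsa = TRUE`) are standardized to mean 0 and
#' SD 1; sex and tricuspid-regurgitation grade enter as treatment
#' contrasts with the largest groups (female, none-trace) as reference.
#'
#' @param covariates Tibble with `age`, `sex`, `height`, `weight`, `prvi`,
#'   `tr_grade` (and optionally `case_id`).
#' @param use_bsa Replace height and weight by Mosteller BSA.
#' @return List of class `biv_design`: `frame` (model frame), `formula`,
#'   `scaling` (per-continuous mean/sd), `continuous`, `categorical`.
#' @export
shape_design <- function(covariates, use_bsa = FALSE) {
  cov <- tibble::as_tibble(covariates)
  req <- c("age", "sex", "height", "weight", "prvi", "tr_grade")
  missing_cols <- setdiff(req, names(cov))
  if (length(missing_cols) > 0) {
    stop_cs(paste("covariates missing:", paste(missing_cols, collapse = ", ")),
            "domain")
  }
  if (anyNA(cov[req])) {
    stop_cs("missing covariate entries; regression cases must be complete",
            "domain")
  }
  if (use_bsa) {
    cov$bsa <- bsa(cov$height, cov$weight)
    continuous <- c("prvi", "bsa", "age")
  } else {
    continuous <- c("prvi", "height", "weight", "age")
  }
  scaling <- list()
  frame <- tibble::tibble(.rows = nrow(cov))
  for (v in continuous) {
    s <- sd(cov[[v]])
    if (!is.finite(s) || s == 0) {
      stop_cs(sprintf("degenerate predictor: '%s' is constant", v),
              "degenerate")
    }
    scaling[[v]] <- list(mean = mean(cov[[v]]), sd = s)
    frame[[v]] <- (cov[[v]] - scaling[[v]]$mean) / s
  }
  frame$sex <- factor(as.character(cov$sex), c("F", "M"))
  frame$tr_grade <- factor(as.character(cov$tr_grade), tr_grade_levels())
  categorical <- c("sex", "tr_grade")
  categorical <- categorical[vapply(categorical, function(v) {
    nlevels(droplevels(frame[[v]])) > 1
  }, logical(1))]
  frame[c("sex", "tr_grade")] <- lapply(frame[c("sex", "tr_grade")], droplevels)
  terms_ <- c(continuous, categorical)
  formula <- stats::as.formula(paste("~", paste(terms_, collapse = " + ")))
  structure(list(frame = frame, formula = formula, scaling = scaling,
                 continuous = continuous, categorical = categorical,
                 case_id = cov$case_id %||% NULL),
            class = "biv_design")
}

#' Per-mode regression of morphometric scores on clinical covariates
#'
#' Fits one ordinary-least-squares model per retained mode with the
#' standardized score as response and the standardized design as
#' predictors. Coefficients of continuous predictors are standardized
#' parameter estimates (score SDs per predictor SD); the overall effect of
#' every predictor is tested by a partial F-test of its column block
#' (equivalent to the two-sided t-test for single-column terms). The
#' semi-partial R^2 (drop-one R^2 difference) of each predictor is kept
#' for variance attribution.
#'
#' @param scores Tibble from [score_shapes()] (`case_id` + `z*` columns).
#' @param covariates Covariate tibble (matched to scores by `case_id` when
#'   both carry it, otherwise by row order).
#' @param design Optional prebuilt [shape_design()] (overrides
#'   `covariates`).
#' @param use_bsa Passed to [shape_design()].
#' @param p_adjust Optional p-value adjustment across modes per predictor
#'   (`"none"`, default, or any [stats::p.adjust()] method such as `"BH"`).
#' @return Object of class `biv_modereg`.
#' @export
fit_mode_regressions <- function(scores, covariates = NULL, design = NULL,
                                 use_bsa = FALSE, p_adjust = "none") {
  if (is.null(design)) {
    if (is.null(covariates)) stop_cs("covariates or design required", "domain")
    design <- shape_design(covariates, use_bsa = use_bsa)
  }
  zcols <- grep("^z[0-9]+$", names(scores), value = TRUE)
  if (length(zcols) == 0) stop_cs("no score columns (z1, z2, ...)", "domain")
  zcols <- zcols[order(as.integer(sub("^z", "", zcols)))]
  if (!is.null(design$case_id) && "case_id" %in% names(scores)) {
    idx <- match(scores$case_id, design$case_id)
    if (anyNA(idx)) stop_cs("scores and covariates have unmatched case ids",
                            "correspondence")
    frame <- design$frame[idx, , drop = FALSE]
  } else {
    if (nrow(scores) != nrow(design$frame)) {
      stop_cs("scores and covariates differ in length", "correspondence")
    }
    frame <- design$frame
  }
  X <- stats::model.matrix(design$formula, data = frame)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    stop_cs(sprintf("cohort error: %d cases cannot identify %d coefficients",
                    n, p), "cohort")
  }
  qr_full <- qr(X)
  if (qr_full$rank < p) {
    bad <- colnames(X)[qr_full$pivot[(qr_full$rank + 1):p]]
    stop_cs(paste("collinearity error: aliased column(s):",
                  paste(bad, collapse = ", ")), "collinearity")
  }
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(design$formula), "term.labels")
  Y <- as.matrix(scores[zcols])
  K <- ncol(Y)
  beta <- qr.coef(qr_full, Y)
  resid_full <- qr.resid(qr_full, Y)
  rss_full <- colSums(resid_full^2)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- 1 - rss_full / tss
  df_res <- n - p
  sigma2 <- rss_full / df_res
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  pvals <- matrix(NA_real_, length(term_labels), K,
                  dimnames = list(term_labels, zcols))
  sr2 <- matrix(NA_real_, length(term_labels), K,
                dimnames = list(term_labels, zcols))
  fstat <- pvals
  for (ti in seq_along(term_labels)) {
    cols <- which(assign == ti)
    qr_red <- qr(X[, -cols, drop = FALSE])
    rss_red <- colSums(qr.resid(qr_red, Y)^2)
    df_t <- length(cols)
    f <- ((rss_red - rss_full) / df_t) / (rss_full / df_res)
    pvals[ti, ] <- pf(f, df_t, df_res, lower.tail = FALSE)
    fstat[ti, ] <- f
    sr2[ti, ] <- (rss_red - rss_full) / tss
  }
  if (p_adjust != "none") {
    for (ti in seq_along(term_labels)) {
      pvals[ti, ] <- stats::p.adjust(pvals[ti, ], method = p_adjust)
    }
  }
  dimnames(beta) <- list(colnames(X), zcols)
  dimnames(se) <- dimnames(beta)
  structure(list(beta = beta, se = se, pvals = pvals, fstat = fstat,
                 sr2 = sr2, r2 = r2, n = n, df_res = df_res,
                 modes = seq_len(K), term_labels = term_labels,
                 assign = assign, col_names = colnames(X),
                 col_means = colMeans(X), design = design,
                 p_adjust = p_adjust),
            class = "biv_modereg")
}

#' @export
print.biv_modereg <- function(x, ...) {
  cat(sprintf("<biv_modereg> %d modes ~ %s (n = %d)\n", length(x$modes),
              paste(x$term_labels, collapse = " + "), x$n))
  invisible(x)
}

#' Tidy coefficient table of per-mode regressions
#'
#' @param x A `biv_modereg`.
#' @param ... Unused.
#' @return Tibble with `mode`, `term` (model-matrix column), `predictor`
#'   (design term), `estimate` (standardized PE), `std_error`,
#'   `p_overall` (partial-F p of the predictor block).
#' @export
tidy.biv_modereg <- function(x, ...) {
  K <- length(x$modes)
  cols <- seq_along(x$col_names)
  purrr::map_dfr(seq_len(K), function(k) {
    tibble::tibble(
      mode = k,
      term = x$col_names,
      predictor = c("(Intercept)", x$term_labels)[x$assign + 1L],
      estimate = x$beta[, k],
      std_error = x$se[, k],
      p_overall = c(NA_real_, x$pvals[, k])[x$assign + 1L])
  })
}

#' @rdname tidy.biv_modereg
#' @export
glance.biv_modereg <- function(x, ...) {
  tibble::tibble(n = x$n, n_modes = length(x$modes),
                 df_res = x$df_res, mean_r2 = mean(x$r2))
}

#' Modes significantly associated with a predictor
#'
#' @param mr A [fit_mode_regressions()] result.
#' @param predictor Design term name (e.g. `"prvi"`, `"sex"`,
#'   `"tr_grade"`).
#' @param alpha Overall-effect significance level (default 0.05).
#' @return Tibble with `mode`, `pe` (standardized coefficient; `NA` for
#'   multi-column categorical terms — see [tidy.biv_modereg()] for the
#'   per-contrast estimates) and `p`, sorted by mode.
#' @export
significant_modes <- function(mr, predictor, alpha = 0.05) {
  if (!predictor %in% mr$term_labels) {
    stop_cs(sprintf("unknown predictor '%s' (have: %s)", predictor,
                    paste(mr$term_labels, collapse = ", ")), "key")
  }
  if (alpha < 0 || alpha > 1) stop_cs("alpha must be in [0, 1]", "domain")
  p <- unname(mr$pvals[predictor, ])
  sel <- which(p < alpha)
  ti <- match(predictor, mr$term_labels)
  cols <- which(mr$assign == ti)
  pe <- if (length(cols) == 1) mr$beta[cols, sel] else rep(NA_real_, length(sel))
  tibble::tibble(mode = sel, pe = as.numeric(pe), p = as.numeric(p[sel]))
}

#' Shape variance attributable to a predictor
#'
#' Combines a predictor's significant modes into a single fraction of the
#' total shape variance. The default rule weighs each significant mode's
#' variance fraction by the predictor's semi-partial R^2 in that mode
#' (`sum f_k * sr2_k`); alternatives weigh by the squared standardized
#' coefficient (`"pe2"`) or count the full mode fractions (`"fsum"`).
#'
#' @param mr A [fit_mode_regressions()] result.
#' @param atlas The fitted [fit_shape_atlas()] (for variance fractions).
#' @param predictor Design term name.
#' @param rule `"sr2"` (default), `"pe2"` or `"fsum"`.
#' @param alpha Significance level for mode selection.
#' @return Fraction of total shape variance in `[0, 1]`.
#' @export
variance_attributable <- function(mr, atlas, predictor,
                                  rule = c("sr2", "pe2", "fsum"),
                                  alpha = 0.05) {
  rule <- match.arg(rule)
  sig <- significant_modes(mr, predictor, alpha)
  if (nrow(sig) == 0) {
    warn_cs(sprintf("no modes significant for '%s'; attribution is 0", predictor),
            "no_signal")
    return(0)
  }
  f <- atlas$frac[sig$mode]
  w <- switch(rule,
    sr2 = mr$sr2[predictor, sig$mode],
    pe2 = {
      if (anyNA(sig$pe)) {
        stop_cs("rule 'pe2' needs a single-column predictor", "domain")
      }
      sig$pe^2
    },
    fsum = rep(1, nrow(sig)))
  sum(f * w)
}

#' Reconstruct the regression-predicted shape at covariate values
#'
#' Evaluates every mode's fitted regression at the given covariate values
#' (unspecified covariates stay at their training means, categorical
#' covariates at their training frequencies) and reconstructs the
#' corresponding ED/ES shape. At the training mean of all covariates this
#' returns the atlas mean shape. Predicted scores use all modes' fitted
#' coefficients by default; `modes = "significant"` keeps only the modes
#' significant for `predictor`.
#'
#' @param mr A [fit_mode_regressions()] result.
#' @param atlas The fitted atlas (with template for mesh output).
#' @param values Named list of covariate values in raw units, e.g.
#'   `list(prvi = 40)`, `list(sex = "M", prvi = 5)`.
#' @param modes `"all"` (default) or `"significant"`.
#' @param predictor Predictor for `modes = "significant"`.
#' @param alpha Significance level for mode selection.
#' @return List with `scores` (predicted standardized scores), `vector`,
#'   `ed`, `es` (when the atlas has a template).
#' @export
shape_at_covariates <- function(mr, atlas, values = list(), modes = "all",
                                predictor = "prvi", alpha = 0.05) {
  x_row <- mr$col_means
  design <- mr$design
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm %in% design$continuous) {
      sc <- design$scaling[[nm]]
      std <- (v - sc$mean) / sc$sd
      if (abs(std) > 4) {
        warn_cs(sprintf("'%s' = %g is %.1f SD from the training mean",
                        nm, v, std), "extrapolation")
      }
      x_row[nm] <- std
    } else if (nm %in% design$categorical) {
      lv <- levels(design$frame[[nm]])
      if (!v %in% lv) {
        stop_cs(sprintf("unknown level '%s' for '%s'", v, nm), "key")
      }
      cols <- grep(paste0("^", nm), mr$col_names, value = TRUE)
      x_row[cols] <- 0
      hit <- paste0(nm, v)
      if (hit %in% cols) x_row[hit] <- 1
    } else {
      stop_cs(sprintf("unknown covariate '%s'", nm), "key")
    }
  }
  z <- as.numeric(crossprod(mr$beta, x_row))
  if (identical(modes, "significant")) {
    keep <- significant_modes(mr, predictor, alpha)$mode
    z[setdiff(seq_along(z), keep)] <- 0
  }
  out <- list(scores = z)
  if (!is.null(atlas$template)) {
    out <- c(out, reconstruct_shape(atlas, z, as_mesh = TRUE))
  } else {
    out$vector <- reconstruct_shape(atlas, z, as_mesh = FALSE)
  }
  out
}

#' Signed per-vertex displacement between corresponded meshes
#'
#' Displacement magnitude is the per-vertex Euclidean distance from
#' `mesh_a` to `mesh_b`; the sign is the sign of the displacement's dot
#' product with the outward surface normal of the reference mesh, where
#' outward points away from the LV cavity (positive = outward from the
#' LV, negative = inward). Also serves ED-to-ES motion maps.
#'
#' @param mesh_a,mesh_b Corresponded [biv_mesh()]es.
#' @param sign_reference Mesh whose outward normals define the sign
#'   (default `mesh_a`).
#' @return Tibble with `vertex`, `label`, `dx`, `dy`, `dz`, `magnitude`,
#'   `signed` (mm).
#' @export
displacement_map <- function(mesh_a, mesh_b, sign_reference = mesh_a) {
  check_correspondence(mesh_a, mesh_b, "displacement meshes")
  disp <- unname(mesh_b$points - mesh_a$points)
  mag <- as.numeric(sqrt(rowSums(disp^2)))
  ref <- sign_reference
  faces <- orient_faces(ref$faces)
  nrm <- vertex_normals(ref$points, faces)
  lv_idx <- label_vertices(ref, "LV_ENDO")
  centre <- if (length(lv_idx) > 0) {
    colMeans(ref$points[lv_idx, , drop = FALSE])
  } else {
    colMeans(ref$points)
  }
  outward <- sweep(ref$points, 2, centre)
  # orientation is resolved per anatomical surface (each is a separate
  # connected component with its own arbitrary winding)
  groups <- list(c("LV_ENDO", "MITRAL_RING", "AORTIC_RING"),
                 c("RV_SEPTAL_ENDO", "RV_FREEWALL_ENDO", "TRICUSPID_RING",
                   "PULMONARY_RING"),
                 "EPI")
  any_grouped <- FALSE
  for (g in groups) {
    idx <- which(ref$labels %in% g)
    if (length(idx) == 0) next
    any_grouped <- TRUE
    if (sum(rowSums(outward[idx, , drop = FALSE] * nrm[idx, , drop = FALSE])) < 0) {
      nrm[idx, ] <- -nrm[idx, ]
    }
  }
  if (!any_grouped && sum(rowSums(outward * nrm)) < 0) nrm <- -nrm
  signed <- sign(rowSums(disp * nrm)) * mag
  signed[mag == 0] <- 0
  tibble::tibble(vertex = seq_len(nrow(disp)), label = mesh_a$labels,
                 dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
                 magnitude = mag, signed = signed)
}
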
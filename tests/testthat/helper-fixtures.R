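# Shared lazily-built fixtures. Coarse resolutions keep the suite fast;
# geometry oracles that need finer meshes build their own.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

coarse_params <- function(...) {
  template_params(resolution = c(n_theta = 12, n_phi = 24), ...)
}

get_template <- function() memo("template", make_template())

get_coarse_template <- function() memo("coarse", make_template(coarse_params()))

# 30-case default-condition cohort at coarse resolution
get_cohort <- function() {
  memo("cohort", suppressWarnings(generate_cohort(
    synthetic_cohort_spec(n_cases = 30, params = coarse_params(), seed = 101))))
}

get_atlas_fit <- function() {
  memo("atlas_fit", build_atlas(get_cohort()$cases))
}

rigid_pair <- function(seed = 1) {
  set.seed(seed)
  list(R = random_rotation(), t = runif(3, -20, 20))
}

transform_mesh <- function(mesh, R, t) {
  mesh$points <- apply_rigid(mesh$points, R, t)
  mesh
}

transform_case <- function(case, R, t) {
  case_record(case$case_id, transform_mesh(case$ed, R, t),
              transform_mesh(case$es, R, t), case$covariates)
}

scale_mesh <- function(mesh, s, about = colMeans(mesh$points)) {
  mesh$points <- sweep(s * sweep(mesh$points, 2, about), 2, about, `+`)
  mesh
}

# truncated-ellipsoid volume (flat cap at z0, apex at -c), mm^3
trunc_ellipsoid_volume <- function(a, b, c, z0) {
  pi * a * b * ((z0 - z0^3 / (3 * c^2)) - (-c + c / 3))
}
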
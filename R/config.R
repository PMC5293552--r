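#' Default run configuration
#'
#' The flat key-value configuration governing inference runs. Keys:
#'
#' * `spline.variant` (`"none"`, `"interpolating"`, `"smoothing"`),
#'   `spline.n_points`, `spline.log_scale`, `center` -- preprocessing.
#' * `response` (`"linear"` or `"clipped"`) -- regression response mode.
#' * `noise.mode` (`"gaussian"`: per-node noise variance by method of
#'   moments, exact Gaussian likelihood; `"student_t"`: full marginal
#'   likelihood with quadrature site updates), `noise.a`, `noise.b`,
#'   `noise.var` (fixed variance override, `NA` = estimate).
#' * `prior.slab_var`, `prior.spike_var`, `prior.rho_mol`, `prior.rho_pert`,
#'   `prior.rho_known` -- spike-and-slab prior.
#' * `ep.max_iters`, `ep.tol`, `ep.damping`, `ep.order` -- EP schedule.
#' * `include_intercept`, `jobs`, `seed`.
#'
#' @export
default_config <- function() {
  list(
    spline.variant = "none", spline.n_points = 0, spline.log_scale = FALSE,
    center = FALSE, response = "linear",
    noise.mode = "gaussian", noise.a = 1, noise.b = 0.1, noise.var = NA_real_,
    prior.slab_var = 10, prior.spike_var = 1e-4,
    prior.rho_mol = 0.1, prior.rho_pert = 0.5, prior.rho_known = 0.99,
    ep.max_iters = 20, ep.tol = 1e-4, ep.damping = 0.8, ep.order = "fixed",
    include_intercept = TRUE, jobs = 1, seed = 1)
}

resolve_config <- function(overrides = list()) {
  cfg <- default_config()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read / write a flat key-value configuration file
#'
#' YAML with flat keys; unknown keys are rejected.
#'
#' @param path File path.
#' @export
read_config <- function(path) {
  resolve_config(yaml::read_yaml(path) %||% list())
}

#' @rdname read_config
#' @param config Named list (validated against [default_config()]).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(resolve_config(config), path)
  invisible(path)
}

log_config <- function(cfg, seed_note = NULL) {
  msg <- paste0("resolved config: ",
                paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                         character(1)),
                      sep = "=", collapse = " "))
  message(msg)
}
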
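# Interpolation schedules f(t) and the parameter-space paths between the
# prior and the data Diracs. The path is linear in the parameter tuple:
#   theta_t = f(t) * theta_data + (1 - f(t)) * theta_prior.
# For 1D location-scale families this is the Wasserstein-2 geodesic; for
# Dirichlet concentrations it is the exponential (e-)geodesic of the
# Fisher-Rao geometry. Both claims are exercised by the property suite in
# the evaluation module.

#' Interpolation schedule
#'
#' @param kind one of `"exponential"` (`f(t) = 1 - gamma^t`), `"linear"`
#'   (`f(t) = t`) or `"quadratic"` (`f(t) = t^2`).
#' @param gamma decay rate in (0, 1) for the exponential schedule;
#'   default 0.009. Ignored by the other kinds.
#' @return an object of class `"pif_schedule"`.
#' @details The exponential schedule reaches `f(1) = 1 - gamma`, not 1; the
#'   gap is intentional and closed at sampling time by the final Dirac
#'   prediction (see [sample_denovo()]). No renormalization is applied.
#' @export
pif_schedule <- function(kind = c("exponential", "linear", "quadratic"),
                         gamma = 0.009) {
  kind <- match.arg(kind)
  gamma <- as.numeric(gamma)
  if (kind == "exponential" && (!is.finite(gamma) || gamma <= 0 || gamma >= 1))
    stop_pif("exponential schedule requires gamma in (0, 1)")
  structure(list(kind = kind, gamma = gamma), class = "pif_schedule")
}

#' Prior configuration for the flow
#'
#' @param family continuous coordinate family, `"gaussian"` or `"laplace"`.
#' @param eps0 positive Gaussian prior spread (Angstrom), default 1.
#' @param beta0 positive Laplace prior scale (Angstrom), default 1.
#' @param K number of atom-type classes (>= 2), default 4.
#' @return an object of class `"pif_prior"`. The coordinate prior is
#'   centered at the origin (a pocket/ligand-centered frame is assumed);
#'   the type prior is the uniform concentration `(1/K, ..., 1/K)`.
#' @export
pif_prior <- function(family = c("gaussian", "laplace"),
                      eps0 = 1, beta0 = 1, K = 4) {
  family <- match.arg(family)
  if (eps0 <= 0) stop_pif("eps0 must be positive")
  if (beta0 <= 0) stop_pif("beta0 must be positive")
  K <- as.integer(K)
  if (K < 2L) stop_pif("K must be >= 2")
  structure(list(family = family, eps0 = eps0, beta0 = beta0, K = K),
            class = "pif_prior")
}

#' Evaluate the interpolation schedule
#'
#' @param t time(s) in `[0, 1]`.
#' @param schedule a [pif_schedule()].
#' @return `f(t)` in `[0, 1]`, monotone nondecreasing in `t`.
#' @export
schedule_value <- function(t, schedule) {
  stopifnot(inherits(schedule, "pif_schedule"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop_pif("t must lie in [0, 1]")
  switch(schedule$kind,
         exponential = 1 - schedule$gamma^t,
         linear      = t,
         quadratic   = t^2)
}

#' Interpolate coordinate parameters between prior and data Dirac
#'
#' Componentwise-linear path in the parameter tuple:
#' location `f(t) * x_data`, spread `(1 - f(t)) * eps0` (or `beta0` for the
#' Laplace family). At `f = 0` this is the prior exactly; at `f = 1` the
#' data Dirac exactly.
#'
#' @param x_data data coordinates (n x d matrix or d-vector), taken as the
#'   location of a zero-spread Dirac in a centered frame.
#' @param prior a [pif_prior()].
#' @param t time in `[0, 1]`.
#' @param schedule a [pif_schedule()].
#' @return [gaussian_params()] or [laplace_params()] at time `t`.
#' @export
interpolate_continuous <- function(x_data, prior, t, schedule) {
  stopifnot(inherits(prior, "pif_prior"))
  x_data <- as_coord_matrix(x_data, what = "x_data")
  f <- schedule_value(t, schedule)
  mu_t <- f * x_data
  if (prior$family == "gaussian")
    gaussian_params(mu_t, (1 - f) * prior$eps0)
  else
    laplace_params(mu_t, (1 - f) * prior$beta0)
}

#' Interpolate type parameters between uniform prior and one-hot Dirac
#'
#' `alpha_t = f(t) * onehot(v_data) + (1 - f(t)) * (1/K, ..., 1/K)`;
#' strictly positive for `f(t) < 1`, and the concentration sum is 1 at
#' every `t` (both endpoints sum to 1).
#'
#' @param type_index integer vector of 1-based data types.
#' @param K number of type classes.
#' @param t time in `[0, 1]`.
#' @param schedule a [pif_schedule()].
#' @return [dirichlet_params()] at time `t`.
#' @export
interpolate_discrete <- function(type_index, K, t, schedule) {
  onehot <- make_dirac_discrete(type_index, K)$alpha
  f <- schedule_value(t, schedule)
  dirichlet_params(f * onehot + (1 - f) / K)
}

#' Joint per-atom parameter state of a ligand at time t
#'
#' Bundles coordinate parameters, type parameters and per-atom role flags.
#' Atoms flagged `fixed` hold Dirac parameters at every time (conditioning
#' atoms: pocket context or an inpainting substructure); `generated` atoms
#' follow the interpolation path.
#'
#' @param coord_params [gaussian_params()] or [laplace_params()], one row
#'   per atom.
#' @param type_params [dirichlet_params()], one row per atom.
#' @param fixed logical vector, `TRUE` for conditioning atoms.
#' @param t time in `[0, 1]`.
#' @return an object of class `"ligand_state"`.
#' @export
ligand_state <- function(coord_params, type_params, fixed = NULL, t = 0) {
  stopifnot(inherits(coord_params, c("gaussian_params", "laplace_params")),
            inherits(type_params, "dirichlet_params"))
  n <- nrow(coord_params$mu)
  if (nrow(type_params$alpha) != n) stop_pif("coordinate/type atom counts differ")
  fixed <- fixed %||% rep(FALSE, n)
  if (length(fixed) != n) stop_pif("fixed flag length mismatch")
  structure(list(coord = coord_params, type = type_params,
                 fixed = as.logical(fixed), t = as.numeric(t)),
            class = "ligand_state")
}

#' Append fixed conditioning atoms to a ligand state
#'
#' Conditioning atoms enter the state as Diracs — coordinates with zero
#' spread and one-hot type concentrations — flagged `fixed`, so they hold
#' their values at every time. Generated atoms are untouched. An empty
#' condition returns the state unchanged.
#'
#' @param state a [ligand_state()].
#' @param x_cond conditioning coordinates (m x d matrix), or `NULL`.
#' @param v_cond conditioning type indices (length m), or `NULL`.
#' @return the extended [ligand_state()].
#' @export
concat_condition <- function(state, x_cond = NULL, v_cond = NULL) {
  stopifnot(inherits(state, "ligand_state"))
  if (is.null(x_cond) || NROW(x_cond) == 0L) return(state)
  x_cond <- as_coord_matrix(x_cond, d = ncol(state$coord$mu), what = "x_cond")
  m <- nrow(x_cond)
  if (length(v_cond) != m) stop_pif("x_cond and v_cond atom counts differ")
  K <- state$type$K
  mu <- rbind(state$coord$mu, x_cond)
  if (inherits(state$coord, "gaussian_params"))
    coord <- gaussian_params(mu, c(state$coord$epsilon, rep(0, m)))
  else
    coord <- laplace_params(mu, c(state$coord$b, rep(0, m)))
  alpha <- rbind(state$type$alpha, make_dirac_discrete(v_cond, K)$alpha)
  ligand_state(coord, dirichlet_params(alpha),
               fixed = c(state$fixed, rep(TRUE, m)), t = state$t)
}
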
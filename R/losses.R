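# Training objectives. The continuous loss is a time-weighted squared
# error on the predicted data-endpoint location; the discrete loss is a
# log-gamma/digamma form that, on the concentration-sum-1 manifold the
# interpolation path lives on, equals the exact Dirichlet KL divergence.

#' Loss weights
#'
#' @param lambda_x,lambda_v positive weights for the continuous and
#'   discrete terms; both default to 1.
#' @return an object of class `"pif_loss_weights"`.
#' @export
pif_loss_weights <- function(lambda_x = 1, lambda_v = 1) {
  if (lambda_x < 0 || lambda_v < 0) stop_pif("loss weights must be nonnegative")
  structure(list(lambda_x = lambda_x, lambda_v = lambda_v),
            class = "pif_loss_weights")
}

# the Eq-style time weight (1 - gamma^t)^2 / (2 gamma^t eps0^2):
# zero at t = 0, strictly increasing in t for gamma in (0,1), so training
# capacity concentrates on the low-noise (fine-structure) end of the path.
continuous_time_weight <- function(t, gamma, eps0) {
  g <- gamma^t
  (1 - g)^2 / (2 * g * eps0^2)
}

#' Time-weighted continuous coordinate loss
#'
#' `w(t) * mean_i || mu_hat_i - mu_true_i ||^2` with
#' `w(t) = (1 - gamma^t)^2 / (2 gamma^t eps0^2)`. The weight vanishes at
#' `t = 0` (pure prior; the prediction is unidentifiable there) and grows
#' monotonically toward the data end.
#'
#' @param mu_hat predicted data-endpoint locations (n x d).
#' @param mu_true true data locations (n x d).
#' @param t time in `[0, 1]`.
#' @param gamma exponential schedule decay rate.
#' @param eps0 prior spread.
#' @return nonnegative scalar.
#' @export
loss_continuous <- function(mu_hat, mu_true, t, gamma = 0.009, eps0 = 1) {
  mu_hat <- as_coord_matrix(mu_hat); mu_true <- as_coord_matrix(mu_true)
  if (!all(dim(mu_hat) == dim(mu_true))) stop_pif("shape mismatch")
  if (t < 0 || t > 1) stop_pif("t must lie in [0, 1]")
  continuous_time_weight(t, gamma, eps0) * mean(rowSums((mu_hat - mu_true)^2))
}

#' Discrete (Dirichlet) type loss
#'
#' The `"printed"` form is, per atom,
#' `sum_i [ lgamma(a_i) - lgamma(ahat_i) + (ahat_i - a_i)(psi(ahat_i) - psi(1)) ]`
#' over the K components of the time-t concentration vectors. When both
#' vectors sum to 1 — which holds identically along the interpolation path,
#' since the one-hot data endpoint and the uniform prior both sum to 1 —
#' this equals the exact Dirichlet KL `KL(Dir(ahat) || Dir(a))`: the
#' `lgamma` terms of the concentration sums vanish and `psi(sum) = psi(1)`.
#' The `"exact_kl"` form computes the full closed-form KL and agrees with
#' `"printed"` on sum-1 inputs; off that manifold they differ.
#'
#' @param alpha_hat predicted concentrations at time t ([dirichlet_params()]
#'   or matrix), strictly positive.
#' @param alpha_true true concentrations at time t, strictly positive.
#' @param form `"printed"` (default) or `"exact_kl"`.
#' @return mean per-atom loss (scalar, nats).
#' @export
loss_discrete <- function(alpha_hat, alpha_true, form = c("printed", "exact_kl")) {
  form <- match.arg(form)
  if (inherits(alpha_hat, "dirichlet_params")) alpha_hat <- alpha_hat$alpha
  if (inherits(alpha_true, "dirichlet_params")) alpha_true <- alpha_true$alpha
  if (is.null(dim(alpha_hat))) alpha_hat <- matrix(alpha_hat, nrow = 1L)
  if (is.null(dim(alpha_true))) alpha_true <- matrix(alpha_true, nrow = 1L)
  if (!all(dim(alpha_hat) == dim(alpha_true))) stop_pif("shape mismatch")
  if (any(alpha_hat <= 0) || any(alpha_true <= 0))
    stop_pif("concentrations must be strictly positive (t < 1)")
  if (form == "printed") {
    per_atom <- rowSums(lgamma(alpha_true) - lgamma(alpha_hat) +
                          (alpha_hat - alpha_true) *
                          (digamma(alpha_hat) - digamma(1)))
    mean(per_atom)
  } else {
    mean(kl_dirichlet_exact(dirichlet_params(alpha_hat),
                            dirichlet_params(alpha_true)))
  }
}

#' Time-weighted Laplace coordinate loss
#'
#' Per coordinate, the KL divergence of two Laplace distributions sharing
#' the time-t scale `b_t = (1 - f(t)) * beta0`:
#' `|dmu|/b_t + exp(-|dmu|/b_t) - 1`, summed over coordinates and averaged
#' over atoms. For small errors this behaves as `dmu^2 / (2 b_t^2)`,
#' mirroring the Gaussian loss; the heavy-tailed linear regime kicks in for
#' errors beyond `b_t`.
#'
#' @param mu_hat,mu_true locations (n x d).
#' @param t time in `[0, 1)` (at `t` with `b_t = 0` the loss is 0 on exact
#'   match and infinite otherwise).
#' @param gamma exponential schedule decay rate (sets `f(t) = 1 - gamma^t`).
#' @param beta0 prior Laplace scale.
#' @return nonnegative scalar.
#' @export
loss_laplace <- function(mu_hat, mu_true, t, gamma = 0.009, beta0 = 1) {
  mu_hat <- as_coord_matrix(mu_hat); mu_true <- as_coord_matrix(mu_true)
  if (!all(dim(mu_hat) == dim(mu_true))) stop_pif("shape mismatch")
  f <- 1 - gamma^t
  b_t <- (1 - f) * beta0
  if (b_t == 0) {
    return(if (all(mu_hat == mu_true)) 0 else Inf)
  }
  mean(kl_laplace_equal_scale(mu_hat, mu_true, b_t))
}

#' Combined training loss over the generated atoms of a state
#'
#' `lambda_x * continuous + lambda_v * discrete`, computed over non-fixed
#' atoms only; conditioning atoms never contribute.
#'
#' @param state a [ligand_state()] holding the true data Diracs (coordinate
#'   locations and one-hot types) and fixed flags.
#' @param prediction list with `mu_hat` (n x d) and `alpha_hat` (n x K
#'   simplex rows) covering all atoms of `state`.
#' @param t training time in `[0, 1)`.
#' @param weights a [pif_loss_weights()].
#' @param schedule a [pif_schedule()].
#' @param prior a [pif_prior()].
#' @param dirichlet_form passed to [loss_discrete()].
#' @return list with `total`, `continuous`, `discrete` scalars.
#' @export
total_loss <- function(state, prediction, t,
                       weights = pif_loss_weights(),
                       schedule = pif_schedule(),
                       prior = pif_prior(),
                       dirichlet_form = "printed") {
  stopifnot(inherits(state, "ligand_state"))
  gen <- !state$fixed
  if (!any(gen)) return(list(total = 0, continuous = 0, discrete = 0))
  mu_true <- state$coord$mu[gen, , drop = FALSE]
  mu_hat <- as_coord_matrix(prediction$mu_hat)[gen, , drop = FALSE]
  f <- schedule_value(t, schedule)
  lx <- if (prior$family == "gaussian") {
    if (schedule$kind == "exponential")
      loss_continuous(mu_hat, mu_true, t, schedule$gamma, prior$eps0)
    else
      # non-exponential schedules: the KL-consistent weight f^2/(2(1-f)^2 eps0^2)
      mean(rowSums((mu_hat - mu_true)^2)) *
        f^2 / (2 * max((1 - f)^2, 1e-12) * prior$eps0^2)
  } else {
    b_t <- (1 - f) * prior$beta0
    if (b_t == 0) {
      if (all(mu_hat == mu_true)) 0 else Inf
    } else mean(kl_laplace_equal_scale(mu_hat, mu_true, b_t))
  }
  # types: interpolate prediction and truth to time t, compare there
  K <- state$type$K
  a_true <- f * state$type$alpha[gen, , drop = FALSE] + (1 - f) / K
  a_hat <- f * as.matrix(prediction$alpha_hat)[gen, , drop = FALSE] + (1 - f) / K
  lv <- if (f < 1) loss_discrete(a_hat, a_true, dirichlet_form) else 0
  list(total = weights$lambda_x * lx + weights$lambda_v * lv,
       continuous = lx, discrete = lv)
}
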
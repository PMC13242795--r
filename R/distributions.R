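# Parametric families used by the parameter-interpolation flow:
# isotropic Gaussian and Laplace for coordinates, Dirichlet for atom types.
# A data point enters the flow as the zero-spread (Dirac) member of the
# family: epsilon = 0 / b = 0 for coordinates, a one-hot concentration
# vector (simplex vertex) for types.

#' Isotropic Gaussian parameters for atomic coordinates
#'
#' One row per atom: a location `mu` (Angstrom) and a single nonnegative
#' isotropic spread `epsilon` shared across that atom's coordinates.
#' `epsilon = 0` denotes a Dirac: sampling returns `mu` exactly, and
#' densities/KL are only defined for `epsilon > 0`.
#'
#' @param mu numeric matrix (n atoms x d coordinates) or a single d-vector.
#' @param epsilon nonnegative spread, length 1 (recycled) or n.
#' @return an object of class `"gaussian_params"` with elements `mu`
#'   (n x d matrix) and `epsilon` (length-n vector).
#' @export
gaussian_params <- function(mu, epsilon) {
  mu <- as_coord_matrix(mu, what = "mu")
  epsilon <- as.numeric(epsilon)
  check_finite(epsilon, "epsilon")
  if (any(epsilon < 0)) stop_pif("epsilon must be nonnegative")
  epsilon <- rep_len(epsilon, nrow(mu))
  structure(list(mu = mu, epsilon = epsilon), class = "gaussian_params")
}

#' Isotropic Laplace parameters for atomic coordinates
#'
#' Mirrors [gaussian_params()] with the Laplace scale `b` in the role of the
#' Gaussian spread; `b = 0` denotes a Dirac.
#'
#' @param mu numeric matrix (n x d) or a single d-vector.
#' @param b nonnegative scale, length 1 (recycled) or n.
#' @return an object of class `"laplace_params"`.
#' @export
laplace_params <- function(mu, b) {
  mu <- as_coord_matrix(mu, what = "mu")
  b <- as.numeric(b)
  check_finite(b, "b")
  if (any(b < 0)) stop_pif("b must be nonnegative")
  b <- rep_len(b, nrow(mu))
  structure(list(mu = mu, b = b), class = "laplace_params")
}

#' Dirichlet concentration parameters for atom types
#'
#' One row per atom over `K` type classes. Interior points (all components
#' strictly positive) admit a density and KL divergence; a one-hot row is
#' the boundary Dirac at a simplex vertex and is sampled as that vertex
#' exactly.
#'
#' @param alpha numeric matrix (n x K) of nonnegative concentrations, or a
#'   single K-vector.
#' @return an object of class `"dirichlet_params"`.
#' @export
dirichlet_params <- function(alpha) {
  if (is.null(dim(alpha))) alpha <- matrix(as.numeric(alpha), nrow = 1L)
  alpha <- as.matrix(alpha)
  storage.mode(alpha) <- "double"
  check_finite(alpha, "alpha")
  if (any(alpha < 0)) stop_pif("alpha components must be nonnegative")
  if (any(rowSums(alpha) <= 0)) stop_pif("each alpha row must have positive sum")
  structure(list(alpha = alpha, K = ncol(alpha)), class = "dirichlet_params")
}

#' Point on the probability simplex
#'
#' @param p numeric matrix (n x K) or K-vector of probabilities; rows must
#'   be nonnegative and sum to 1 within 1e-9.
#' @return an object of class `"simplex_point"`.
#' @export
simplex_point <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1L)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  check_finite(p, "p")
  if (any(p < 0)) stop_pif("simplex components must be nonnegative")
  if (any(abs(rowSums(p) - 1) > 1e-9)) stop_pif("simplex rows must sum to 1")
  structure(list(p = p, K = ncol(p)), class = "simplex_point")
}

#' Dirac embedding of observed coordinates
#'
#' Represents a data point as the zero-spread limit of the Gaussian family:
#' location at the data coordinates, standard deviation zero.
#'
#' @param x_data numeric matrix (n x d) or d-vector of observed coordinates.
#' @return [gaussian_params()] with `epsilon = 0`.
#' @export
make_dirac_continuous <- function(x_data) {
  x_data <- as_coord_matrix(x_data, what = "x_data")
  gaussian_params(x_data, 0)
}

#' Dirac embedding of observed atom types
#'
#' Represents observed types as one-hot Dirichlet concentration vectors
#' (boundary Diracs at simplex vertices).
#'
#' @param type_index integer vector of 1-based type indices in `[1, K]`.
#' @param K number of type classes (>= 2).
#' @return [dirichlet_params()] with one-hot rows.
#' @export
make_dirac_discrete <- function(type_index, K) {
  K <- as.integer(K)
  if (K < 2L) stop_pif("K must be >= 2")
  type_index <- as.integer(type_index)
  if (any(is.na(type_index)) || any(type_index < 1L) || any(type_index > K))
    stop_pif("type_index out of range [1, K]")
  alpha <- matrix(0, nrow = length(type_index), ncol = K)
  alpha[cbind(seq_along(type_index), type_index)] <- 1
  dirichlet_params(alpha)
}

#' Draw one sample per atom from Gaussian coordinate parameters
#'
#' Rows with `epsilon = 0` return `mu` exactly (Dirac convention).
#'
#' @param params a [gaussian_params()] object.
#' @return numeric matrix, same shape as `params$mu`.
#' @export
sample_gaussian <- function(params) {
  stopifnot(inherits(params, "gaussian_params"))
  n <- nrow(params$mu); d <- ncol(params$mu)
  noise <- matrix(stats::rnorm(n * d), n, d) * params$epsilon
  params$mu + noise
}

#' Draw one sample per atom from Laplace coordinate parameters
#'
#' Each coordinate is drawn independently from Laplace(mu, b); rows with
#' `b = 0` return `mu` exactly.
#'
#' @param params a [laplace_params()] object.
#' @return numeric matrix, same shape as `params$mu`.
#' @export
sample_laplace <- function(params) {
  stopifnot(inherits(params, "laplace_params"))
  n <- nrow(params$mu); d <- ncol(params$mu)
  # inverse-CDF draw: sign(u) * log(1 - 2|u|) with u ~ U(-1/2, 1/2)
  u <- matrix(stats::runif(n * d) - 0.5, n, d)
  params$mu - params$b * sign(u) * log1p(-2 * abs(u))
}

#' Draw one sample per atom from Dirichlet type parameters
#'
#' Uses the normalized-gamma construction. Components with zero
#' concentration receive probability exactly 0; one-hot rows return the
#' simplex vertex exactly, bypassing the gamma machinery (0/0 avoidance).
#'
#' @param params a [dirichlet_params()] object.
#' @return a [simplex_point()] with one row per atom.
#' @export
sample_dirichlet <- function(params) {
  stopifnot(inherits(params, "dirichlet_params"))
  a <- params$alpha
  p <- matrix(0, nrow(a), ncol(a))
  onehot <- rowSums(a > 0) == 1L
  if (any(onehot)) {
    idx <- max.col(a[onehot, , drop = FALSE], ties.method = "first")
    p[cbind(which(onehot), idx)] <- 1
  }
  rest <- which(!onehot)
  if (length(rest)) {
    ar <- a[rest, , drop = FALSE]
    g <- matrix(0, nrow(ar), ncol(ar))
    pos <- ar > 0
    g[pos] <- stats::rgamma(sum(pos), shape = ar[pos], rate = 1)
    # guard against all-zero gamma draws at tiny concentrations
    zero <- rowSums(g) == 0
    if (any(zero)) {
      idx <- max.col(ar[zero, , drop = FALSE], ties.method = "first")
      g[cbind(which(zero), idx)] <- 1
    }
    p[rest, ] <- g / rowSums(g)
  }
  simplex_point(p)
}

#' KL divergence between isotropic Gaussians
#'
#' Closed form for `KL(p || q)` with `p = N(mu_p, eps_p^2 I)`,
#' `q = N(mu_q, eps_q^2 I)` in d dimensions:
#' `d log(eps_q/eps_p) + (d eps_p^2 + ||mu_p - mu_q||^2) / (2 eps_q^2) - d/2`.
#' Defined for `eps_q > 0`; a Dirac `p` (eps_p = 0) gives the finite limit.
#'
#' @param p,q [gaussian_params()] objects with matching shapes.
#' @return numeric vector of per-atom divergences (nats).
#' @export
kl_gaussian <- function(p, q) {
  stopifnot(inherits(p, "gaussian_params"), inherits(q, "gaussian_params"))
  if (!all(dim(p$mu) == dim(q$mu))) stop_pif("shape mismatch between p and q")
  if (any(q$epsilon == 0)) stop_pif("KL undefined: q has zero spread (Dirac)")
  d <- ncol(p$mu)
  dmu2 <- rowSums((p$mu - q$mu)^2)
  ratio <- ifelse(p$epsilon == 0, -Inf, log(p$epsilon / q$epsilon))
  kl <- d * (-ratio) + (d * p$epsilon^2 + dmu2) / (2 * q$epsilon^2) - d / 2
  # Dirac p: -d*log(0/eps_q) is +Inf in the entropy term but the correct
  # limit of the KL of N(mu_p, s) as s -> 0 is infinite; we follow the
  # convention of returning Inf there only when requested explicitly.
  if (any(p$epsilon == 0)) kl[p$epsilon == 0] <- Inf
  pmax(kl, 0)   # clamp round-off negatives; KL is nonnegative
}

#' KL divergence between equal-dimension Dirichlet distributions
#'
#' Standard closed form using log-gamma and digamma:
#' `log B(alpha_q) - log B(alpha_p) + sum_i (alpha_p,i - alpha_q,i)
#' (psi(alpha_p,i) - psi(alpha_p,0))` where `alpha_0` is the concentration
#' sum. Requires strictly positive components on both sides (interior of
#' the simplex); boundary (one-hot) parameters are rejected.
#'
#' @param p,q [dirichlet_params()] objects with matching shapes.
#' @return numeric vector of per-atom divergences (nats).
#' @export
kl_dirichlet_exact <- function(p, q) {
  stopifnot(inherits(p, "dirichlet_params"), inherits(q, "dirichlet_params"))
  if (!all(dim(p$alpha) == dim(q$alpha))) stop_pif("shape mismatch")
  a <- p$alpha; b <- q$alpha
  if (any(a <= 0) || any(b <= 0))
    stop_pif("KL defined only for strictly positive concentrations")
  a0 <- rowSums(a); b0 <- rowSums(b)
  pmax(lgamma(a0) - rowSums(lgamma(a)) - lgamma(b0) + rowSums(lgamma(b)) +
         rowSums((a - b) * (digamma(a) - digamma(a0))), 0)
}

#' KL divergence between equal-scale Laplace distributions (per coordinate)
#'
#' For `La(mu1, b)` vs `La(mu2, b)` the divergence is
#' `|dmu|/b + exp(-|dmu|/b) - 1`, summed over coordinates.
#'
#' @param mu1,mu2 numeric matrices (n x d) of locations.
#' @param b positive common scale (scalar or length n).
#' @return numeric vector of per-atom divergences (nats).
#' @export
kl_laplace_equal_scale <- function(mu1, mu2, b) {
  mu1 <- as_coord_matrix(mu1); mu2 <- as_coord_matrix(mu2)
  if (!all(dim(mu1) == dim(mu2))) stop_pif("shape mismatch")
  if (any(b <= 0)) stop_pif("b must be positive")
  z <- abs(mu1 - mu2) / b
  rowSums(z + exp(-z) - 1)
}
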
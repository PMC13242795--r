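# Metrics and analytic verifiers: Jensen-Shannon divergence of geometric
# distributions, closed-form and empirical 1D Wasserstein-2 distances,
# and the residual of the Fisher-Rao exponential-geodesic identity that
# the discrete interpolation path must satisfy.

#' Histogram specification for divergence comparisons
#'
#' A frozen binning shared by both sides of a comparison, so reported
#' divergences are reproducible.
#'
#' @param min,max range; must satisfy `max > min`.
#' @param bins bin count (default 64, >= 2).
#' @return an object of class `"histogram_spec"`.
#' @export
histogram_spec <- function(min, max, bins = 64) {
  if (!(max > min)) stop_pif("max must exceed min")
  if (bins < 2) stop_pif("bins must be >= 2")
  structure(list(min = min, max = max, bins = as.integer(bins)),
            class = "histogram_spec")
}

bin_counts <- function(x, spec) {
  br <- seq(spec$min, spec$max, length.out = spec$bins + 1L)
  x <- pmin(pmax(x, spec$min), spec$max)   # clamp tails into edge bins
  counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = spec$bins)
  counts
}

#' Jensen-Shannon divergence between two empirical samples
#'
#' Both samples are binned on the frozen [histogram_spec()] (defaulting to
#' the pooled data range), with an add-half pseudocount per bin, and the
#' JSD is computed in bits: symmetric, bounded by 1, zero for identical
#' samples.
#'
#' @param samples_a,samples_b nonempty numeric vectors.
#' @param spec a [histogram_spec()], or `NULL` to freeze one from the
#'   pooled range of the two samples.
#' @return JSD in bits, in `[0, 1]`.
#' @export
jsd <- function(samples_a, samples_b, spec = NULL) {
  if (!length(samples_a) || !length(samples_b)) stop_pif("empty sample input")
  if (is.null(spec)) {
    r <- range(c(samples_a, samples_b))
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    spec <- histogram_spec(r[1], r[2])
  }
  pa <- bin_counts(samples_a, spec) + 0.5
  pb <- bin_counts(samples_b, spec) + 0.5
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  m <- (pa + pb) / 2
  kl2 <- function(p, q) sum(p * (log2(p) - log2(q)))
  0.5 * kl2(pa, m) + 0.5 * kl2(pb, m)
}

#' Distance-rule adjacency of a molecule
#'
#' Two atoms are bonded when their distance is below the sum of covalent
#' radii times `factor` (default 1.3).
#'
#' @param molecule a [pif_molecule()].
#' @param factor cutoff multiplier.
#' @return integer matrix of bonded pairs (columns `i`, `j`, `i < j`).
#' @export
perceive_bonds <- function(molecule, factor = 1.3) {
  stopifnot(inherits(molecule, "pif_molecule"))
  n <- nrow(molecule$coords)
  if (n < 2L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  radii <- PIF_COVALENT_RADII[pif_elements(molecule$K)][molecule$types]
  dm <- as.matrix(stats::dist(molecule$coords))
  cutoff <- outer(radii, radii, "+") * factor
  hit <- which(dm < cutoff & upper.tri(dm), arr.ind = TRUE)
  colnames(hit) <- c("i", "j")
  hit
}

#' Bond lengths of a molecule under the distance rule
#'
#' @param molecule a [pif_molecule()].
#' @param factor covalent-radius-sum multiplier (default 1.3).
#' @return numeric vector of bond lengths (Angstrom); empty for < 2 atoms.
#' @export
extract_bond_lengths <- function(molecule, factor = 1.3) {
  bonds <- perceive_bonds(molecule, factor)
  if (!nrow(bonds)) return(numeric(0))
  sqrt(rowSums((molecule$coords[bonds[, 1L], , drop = FALSE] -
                  molecule$coords[bonds[, 2L], , drop = FALSE])^2))
}

#' Bond angles of a molecule under the distance rule
#'
#' Angles over all connected triples j-i-k (i the apex).
#'
#' @param molecule a [pif_molecule()].
#' @param factor covalent-radius-sum multiplier (default 1.3).
#' @return numeric vector of angles in degrees; empty for < 3 atoms.
#' @export
extract_bond_angles <- function(molecule, factor = 1.3) {
  bonds <- perceive_bonds(molecule, factor)
  if (nrow(bonds) < 2L) return(numeric(0))
  nb <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
  out <- numeric(0)
  for (i in names(nb)) {
    ns <- sort(unique(nb[[i]]))
    if (length(ns) < 2L) next
    ic <- molecule$coords[as.integer(i), ]
    for (ab in utils::combn(ns, 2L, simplify = FALSE)) {
      v1 <- molecule$coords[ab[1L], ] - ic
      v2 <- molecule$coords[ab[2L], ] - ic
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      out <- c(out, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
    }
  }
  out
}

#' Closed-form Wasserstein-2 distance between 1D Gaussians
#'
#' `W2(N(mu_p, eps_p^2), N(mu_q, eps_q^2)) = sqrt((mu_p - mu_q)^2 +
#' (eps_p - eps_q)^2)`. Linear interpolation of the parameter pair
#' `(mu, eps)` is therefore the W2 geodesic: `W2(p0, pt) = t W2(p0, p1)`.
#'
#' @param p,q 1D [gaussian_params()] (single row, one column).
#' @return nonnegative scalar.
#' @export
w2_gaussian_closed_form <- function(p, q) {
  stopifnot(inherits(p, "gaussian_params"), inherits(q, "gaussian_params"))
  if (ncol(p$mu) != 1L || ncol(q$mu) != 1L) stop_pif("1D parameters required")
  sqrt((p$mu[1] - q$mu[1])^2 + (p$epsilon[1] - q$epsilon[1])^2)
}

#' Empirical 1D Wasserstein-2 distance
#'
#' Quantile coupling of two equal-length sorted samples.
#'
#' @param a,b numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
w2_empirical_1d <- function(a, b) {
  if (length(a) != length(b)) stop_pif("equal sample sizes required")
  sqrt(mean((sort(a) - sort(b))^2))
}

#' Residual of the Fisher-Rao e-geodesic identity for Dirichlet paths
#'
#' Along `alpha_lambda = (1 - lambda) alpha0 + lambda alpha1` the Dirichlet
#' log density satisfies `log p_lambda(v) = (1 - lambda) log p_0(v) +
#' lambda log p_1(v) + const` pointwise — the path is an exponential
#' geodesic of the Fisher-Rao geometry, i.e. a normalized geometric
#' mixture. Returns the variance over probe points of the left-over term;
#' exact geodesics give machine-epsilon residuals.
#'
#' @param alpha0,alpha1 strictly positive K-vectors.
#' @param lambda interpolation weight in `[0, 1]`.
#' @param probes matrix of probe points (rows in the open simplex).
#' @return variance of the log-density mismatch over probes.
#' @export
e_geodesic_residual <- function(alpha0, alpha1, lambda, probes) {
  alpha0 <- as.numeric(alpha0); alpha1 <- as.numeric(alpha1)
  if (any(alpha0 <= 0) || any(alpha1 <= 0))
    stop_pif("interior concentrations required")
  if (is.null(dim(probes))) probes <- matrix(probes, nrow = 1L)
  if (any(probes <= 0) || any(abs(rowSums(probes) - 1) > 1e-9))
    stop_pif("probes must lie in the open simplex")
  ldir <- function(v, a)
    sum((a - 1) * log(v)) - (sum(lgamma(a)) - lgamma(sum(a)))
  al <- (1 - lambda) * alpha0 + lambda * alpha1
  resid <- apply(probes, 1L, function(v)
    ldir(v, al) - (1 - lambda) * ldir(v, alpha0) - lambda * ldir(v, alpha1))
  if (length(resid) < 2L) 0 else stats::var(resid)
}
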
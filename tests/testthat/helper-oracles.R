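# Independent numerical oracles used to freeze expected values. These
# deliberately avoid the package's own closed forms: quadrature and
# Monte-Carlo only.

# KL(N(m1, s1^2) || N(m2, s2^2)) by adaptive quadrature
kl_gaussian_quad <- function(m1, s1, m2, s2) {
  f <- function(x) {
    lp <- dnorm(x, m1, s1, log = TRUE)
    lq <- dnorm(x, m2, s2, log = TRUE)
    exp(lp) * (lp - lq)
  }
  integrate(f, m1 - 12 * s1, m1 + 12 * s1, rel.tol = 1e-10)$value
}

# KL(Beta(a1, b1) || Beta(a2, b2)) by quadrature (the K = 2 Dirichlet)
kl_beta_quad <- function(a1, b1, a2, b2) {
  f <- function(x) {
    lp <- dbeta(x, a1, b1, log = TRUE)
    lq <- dbeta(x, a2, b2, log = TRUE)
    exp(lp) * (lp - lq)
  }
  integrate(f, 0, 1, rel.tol = 1e-9, subdivisions = 2000L,
            stop.on.error = FALSE)$value
}

# KL between two Laplace(mu, b) of equal scale, by quadrature
kl_laplace_quad <- function(m1, m2, b) {
  dlap <- function(x, m) -abs(x - m) / b - log(2 * b)
  f <- function(x) exp(dlap(x, m1)) * (dlap(x, m1) - dlap(x, m2))
  integrate(f, m1 - 40 * b, m1 + 40 * b, rel.tol = 1e-10,
            subdivisions = 400L)$value
}

# Monte-Carlo KL(Dir(a) || Dir(b)) with a standard-error estimate
kl_dirichlet_mc <- function(a, b, n = 1e6, seed = 42) {
  set.seed(seed)
  K <- length(a)
  g <- matrix(rgamma(n * K, shape = rep(a, each = n)), n, K)
  v <- g / rowSums(g)
  ldir <- function(v, al)
    colSums((al - 1) * t(log(v))) - (sum(lgamma(al)) - lgamma(sum(al)))
  w <- ldir(v, a) - ldir(v, b)
  list(est = mean(w), se = sd(w) / sqrt(n))
}

rand_simplex <- function(K) { g <- rgamma(K, 1); g / sum(g) }

# a strictly positive concentration vector summing to 1 (the manifold the
# interpolation path lives on)
rand_sum1_alpha <- function(K) rand_simplex(K)

small_net <- function(K = 4, seed = 1)
  pif_network(K, hidden = 8, layers = 2, n_rbf = 8, t_dim = 4, knn_k = 4,
              seed = seed)

chain_template <- function(n = 6L, sd0 = FALSE)
  molecule_template("chain", n_atoms = n,
                    bond_length_sd = if (sd0) 0 else 0.03,
                    angle_sd = if (sd0) 0 else 3)
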
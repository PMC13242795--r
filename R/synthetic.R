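# Seedable generators of ligand-like point clouds with known geometric
# ground truth: templated chains, rings and branched trees with tight
# bond-length/angle distributions, paired pocket stubs for conditioning,
# and 2D/categorical toy distributions for schedule comparisons.

PIF_ELEMENTS <- c("C", "N", "O", "F", "P", "S", "Cl")
PIF_COVALENT_RADII <- c(C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                        P = 1.07, S = 1.05, Cl = 1.02, H = 0.31)

#' Element alphabet for a K-class type space
#'
#' @param K number of classes (2-7).
#' @return character vector of element symbols.
#' @export
pif_elements <- function(K) {
  if (K < 2 || K > length(PIF_ELEMENTS)) stop_pif("K must be in [2, 7]")
  PIF_ELEMENTS[seq_len(K)]
}

#' Molecular point cloud
#'
#' The package's working molecule representation: per-atom coordinates
#' (Angstrom) and 1-based categorical types over `K` classes mapped to an
#' element alphabet.
#'
#' @param coords n x 3 coordinate matrix.
#' @param types integer vector of types in `[1, K]`.
#' @param K number of type classes.
#' @return an object of class `"pif_molecule"`.
#' @export
pif_molecule <- function(coords, types, K = max(types)) {
  coords <- as_coord_matrix(coords, d = 3, what = "coords")
  types <- as.integer(types)
  if (length(types) != nrow(coords)) stop_pif("coords/types length mismatch")
  if (any(types < 1L) || any(types > K)) stop_pif("types out of range")
  structure(list(coords = coords, types = types, K = as.integer(K)),
            class = "pif_molecule")
}

#' @export
print.pif_molecule <- function(x, ...) {
  cat("<pif_molecule> ", nrow(x$coords), " atoms, K = ", x$K, " (",
      paste(pif_elements(x$K)[x$types], collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Generative recipe for synthetic ligands
#'
#' @param topology `"chain"`, `"ring"` or `"branched"`.
#' @param n_atoms atom count, or a length-2 range sampled uniformly.
#' @param bond_length_mean,bond_length_sd bond length distribution
#'   (Angstrom); defaults 1.5 and 0.03.
#' @param angle_mean bond angle mean (degrees); defaults to 109.5 for
#'   chains/branched and the interior polygon angle for rings.
#' @param angle_sd bond angle standard deviation (degrees); default 3.
#' @param type_distribution K-vector of type probabilities; default a
#'   carbon-rich mix over K = 4 classes.
#' @param K number of type classes.
#' @return an object of class `"molecule_template"`.
#' @export
molecule_template <- function(topology = c("chain", "ring", "branched"),
                              n_atoms = c(6L, 12L),
                              bond_length_mean = 1.5, bond_length_sd = 0.03,
                              angle_mean = NULL, angle_sd = 3,
                              type_distribution = NULL, K = 4) {
  topology <- match.arg(topology)
  if (bond_length_mean <= 0 || bond_length_sd < 0 || angle_sd < 0)
    stop_pif("lengths must be positive and sds nonnegative")
  K <- as.integer(K)
  type_distribution <- type_distribution %||%
    c(0.6, 0.2, 0.15, 0.05, rep(0, max(0, K - 4)))[seq_len(K)]
  type_distribution <- type_distribution / sum(type_distribution)
  n_atoms <- as.integer(n_atoms)
  if (any(n_atoms < ifelse(topology == "ring", 3L, 2L)))
    stop_pif("infeasible template: too few atoms for topology ", topology)
  structure(list(topology = topology, n_atoms = n_atoms,
                 bond_length_mean = bond_length_mean,
                 bond_length_sd = bond_length_sd,
                 angle_mean = angle_mean, angle_sd = angle_sd,
                 type_distribution = type_distribution, K = K),
            class = "molecule_template")
}

deg2rad <- function(x) x * pi / 180

min_nonbonded_distance <- function(coords, bonds) {
  n <- nrow(coords)
  if (n < 3L) return(Inf)
  dm <- as.matrix(stats::dist(coords))
  bonded <- matrix(FALSE, n, n)
  bonded[bonds] <- TRUE
  bonded[bonds[, c(2L, 1L), drop = FALSE]] <- TRUE
  diag(dm) <- Inf
  dm[bonded] <- Inf
  min(dm)
}

# place atom D given A-B-C using bond length, angle at C and torsion about
# B-C (standard internal-coordinate construction)
place_internal <- function(a, b, c, length, angle, torsion) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) { # collinear fallback: any perpendicular
    n <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- n - sum(n * bc) * bc
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(bc[2] * n[3] - bc[3] * n[2],
         bc[3] * n[1] - bc[1] * n[3],
         bc[1] * n[2] - bc[2] * n[1])
  d2 <- -cos(angle) * bc + sin(angle) * (cos(torsion) * n + sin(torsion) * m)
  c + length * d2
}

#' Generate one synthetic ligand from a template
#'
#' Chains and branched trees are embedded atom-by-atom in internal
#' coordinates with bond lengths and angles drawn from the template
#' Normals (torsions mix staggered rotamers at 180/+60/-60 degrees with
#' 10-degree wobble). Rings are built in-plane from drawn edge lengths and
#' interior angles, then the closure error is spread evenly over the
#' vertices (residual below 0.1 Angstrom enforced). Types are i.i.d. from
#' the template type distribution. Coordinates are centered on the
#' molecule centroid.
#'
#' @param template a [molecule_template()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a [pif_molecule()].
#' @export
make_ligand <- function(template, seed = NULL) {
  stopifnot(inherits(template, "molecule_template"))
  with_seed(seed, {
    tpl <- template
    n <- if (length(tpl$n_atoms) > 1L)
      sample(seq(tpl$n_atoms[1], tpl$n_atoms[2]), 1L) else tpl$n_atoms
    # rejection loop: real ligands have no sub-van-der-Waals contacts, so
    # conformers whose nonbonded atoms come closer than 2.2 A are redrawn
    for (attempt in 1:100) {
      built <- switch(tpl$topology,
                      chain = ligand_chain(n, tpl, branched = FALSE),
                      branched = ligand_chain(n, tpl, branched = TRUE),
                      ring = ligand_ring(n, tpl))
      if (min_nonbonded_distance(built$coords, built$bonds) >= 2.2) break
    }
    coords <- built$coords
    types <- sample.int(tpl$K, n, replace = TRUE, prob = tpl$type_distribution)
    coords <- sweep(coords, 2L, colMeans(coords))
    pif_molecule(coords, types, tpl$K)
  })
}

ligand_chain <- function(n, tpl, branched = FALSE) {
  angle_mean <- deg2rad(tpl$angle_mean %||% 109.5)
  angle_sd <- deg2rad(tpl$angle_sd)
  len <- function() stats::rnorm(1, tpl$bond_length_mean, tpl$bond_length_sd)
  ang <- function() stats::rnorm(1, angle_mean, angle_sd)
  tor <- function() deg2rad(sample(c(180, 60, -60), 1L,
                                   prob = c(0.6, 0.2, 0.2)) +
                              stats::rnorm(1, 0, 10) * (tpl$angle_sd > 0))
  coords <- matrix(0, n, 3)
  parent <- integer(n)
  coords[1, ] <- 0
  if (n >= 2) { coords[2, ] <- c(len(), 0, 0); parent[2] <- 1L }
  if (n >= 3) {
    a <- ang()
    coords[3, ] <- coords[2, ] + len() * c(-cos(a), sin(a), 0)
    parent[3] <- 2L
  }
  if (n >= 4) for (i in 4:n) {
    p <- i - 1L
    if (branched && stats::runif(1) < 0.25) {
      kids <- tabulate(parent, nbins = n)
      cand <- which(seq_len(n) >= 2L & seq_len(n) < i & kids < 3L)
      if (length(cand)) p <- cand[sample.int(length(cand), 1L)]
    }
    gp <- parent[p]
    ggp <- if (parent[gp] > 0L) parent[gp] else setdiff(seq_len(i - 1L), c(p, gp))[1]
    coords[i, ] <- place_internal(coords[ggp, ], coords[gp, ], coords[p, ],
                                  len(), ang(), tor())
    parent[i] <- p
  }
  list(coords = coords,
       bonds = if (n >= 2) cbind(2:n, parent[2:n]) else matrix(integer(0), ncol = 2L))
}

ligand_ring <- function(n, tpl) {
  if (n < 3L) stop_pif("infeasible template: ring needs >= 3 atoms")
  interior <- deg2rad(tpl$angle_mean %||% (180 - 360 / n))
  angle_sd <- deg2rad(tpl$angle_sd)
  lens <- stats::rnorm(n, tpl$bond_length_mean, tpl$bond_length_sd)
  angs <- stats::rnorm(n, interior, angle_sd)
  # planar ring: bond headings from drawn interior angles, then the drawn
  # lengths are kept exact and closure (sum l_i u(theta_i) = 0) is enforced
  # by least-norm Newton corrections to the headings only — noise is
  # absorbed in the angles, whose tolerance is far looser than the bonds'
  theta <- cumsum(c(0, pi - angs[2:n]))
  for (it in 1:50) {
    u <- cbind(cos(theta), sin(theta))
    e <- colSums(lens * u)
    if (sqrt(sum(e^2)) < 1e-12) break
    J <- t(lens * cbind(-sin(theta), cos(theta)))   # 2 x n
    theta <- theta - drop(t(J) %*% solve(J %*% t(J), e))
  }
  u <- cbind(cos(theta), sin(theta))
  steps <- lens * u
  coords <- cbind(apply(steps, 2L, cumsum), 0)
  coords <- rbind(c(0, 0, 0), coords[seq_len(n - 1L), , drop = FALSE])
  closure <- abs(sqrt(sum((coords[1, ] - (coords[n, ] + lens[n] * c(u[n, ], 0)))^2)))
  if (closure > 0.1) stop_pif("ring closure residual exceeds 0.1 Angstrom")
  list(coords = coords, bonds = cbind(seq_len(n), c(2:n, 1L)))
}

#' Pocket stub paired with a ligand
#'
#' Anchor atoms on a fixed scaffold (a ring of radius 4 Angstrom with
#' seeded jitter) stand in for a protein binding site. The ligand centroid
#' is placed at the anchor centroid plus `offset` — an exactly invertible
#' rule, so conditional generation has a checkable ground truth.
#'
#' @param template a [molecule_template()] for the ligand.
#' @param pocket_size number of anchor atoms (default 8).
#' @param offset 3-vector from anchor centroid to ligand centroid.
#' @param seed integer seed.
#' @return list with `pocket` (a [pif_molecule()]) and `ligand`
#'   (a [pif_molecule()]); pocket types are drawn from the same alphabet.
#' @export
make_pocket_ligand_pair <- function(template, pocket_size = 8, offset = c(0, 0, 0),
                                    seed = NULL) {
  with_seed(seed, {
    m <- as.integer(pocket_size)
    ang <- 2 * pi * (seq_len(m) - 1) / m
    anchors <- cbind(4 * cos(ang), 4 * sin(ang), 0) +
      matrix(stats::rnorm(3 * m, sd = 0.2), m, 3)
    pocket <- pif_molecule(anchors, sample.int(template$K, m, replace = TRUE),
                           template$K)
    lig <- make_ligand(template)
    shift <- colMeans(pocket$coords) + as.numeric(offset) - colMeans(lig$coords)
    lig$coords <- sweep(lig$coords, 2L, -shift)
    list(pocket = pocket, ligand = lig)
  })
}

#' Generate a dataset of synthetic ligands
#'
#' @param templates a [molecule_template()] or list of templates cycled
#'   over instances.
#' @param n number of molecules.
#' @param seed master seed; instance i uses a derived child seed.
#' @return named list of [pif_molecule()] (`"mol_1"`, ...).
#' @export
make_ligand_dataset <- function(templates, n, seed = 1) {
  if (inherits(templates, "molecule_template")) templates <- list(templates)
  mols <- lapply(seq_len(n), function(i)
    make_ligand(templates[[(i - 1L) %% length(templates) + 1L]],
                seed = derive_seed(seed, i)))
  names(mols) <- paste0("mol_", seq_len(n))
  mols
}

#' Toy 2D mixture distributions
#'
#' Named fixed mixtures used for schedule comparisons: `two_gaussians`
#' (means (-2, 0) and (2, 0), sd 0.5, equal weights), `ring_mixture`
#' (8 components on a radius-2 circle, sd 0.1), `grid_mixture` (3 x 3 grid
#' with spacing 2, sd 0.1).
#'
#' @param name mixture name.
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @return n x 2 matrix of draws.
#' @export
make_toy_continuous <- function(name = c("two_gaussians", "ring_mixture",
                                         "grid_mixture"), n, seed = NULL) {
  name <- match.arg(name)
  if (n < 1) stop_pif("n must be >= 1")
  centers <- switch(name,
    two_gaussians = matrix(c(-2, 0, 2, 0), 2, 2, byrow = TRUE),
    ring_mixture = {
      a <- 2 * pi * (0:7) / 8
      cbind(2 * cos(a), 2 * sin(a))
    },
    grid_mixture = as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2))))
  sd <- if (name == "two_gaussians") 0.5 else 0.1
  with_seed(seed, {
    comp <- sample.int(nrow(centers), n, replace = TRUE)
    centers[comp, , drop = FALSE] + matrix(stats::rnorm(2 * n, sd = sd), n, 2)
  })
}

#' Toy categorical draws
#'
#' @param K number of categories.
#' @param probs K-vector on the simplex.
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer vector of 1-based categories.
#' @export
make_toy_discrete <- function(K, probs, n, seed = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) != K || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop_pif("probs must be a K-vector on the simplex")
  with_seed(seed, sample.int(K, n, replace = TRUE, prob = probs))
}
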
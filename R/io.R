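# Readers and writers: XYZ is the primary interchange (element symbol +
# coordinates is all the model consumes), SDF V2000 optional with
# distance-rule bond perception, plus the structured-config reader.

#' Write a molecule as XYZ
#'
#' Standard XYZ: atom-count line, comment line, then one
#' `element x y z` row per atom at 6 decimals.
#'
#' @param path output file path.
#' @param molecule a [pif_molecule()].
#' @param comment comment-line text.
#' @return the path, invisibly.
#' @export
write_xyz <- function(path, molecule, comment = "generated by pifgen") {
  stopifnot(inherits(molecule, "pif_molecule"))
  n <- nrow(molecule$coords)
  el <- pif_elements(molecule$K)[molecule$types]
  lines <- c(as.character(n), comment,
             if (n > 0) sprintf("%s %.6f %.6f %.6f", el,
                                molecule$coords[, 1], molecule$coords[, 2],
                                molecule$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule from XYZ
#'
#' @param path input file path.
#' @param K number of type classes used to map element symbols (default 4).
#' @return a [pif_molecule()].
#' @export
read_xyz <- function(path, K = 4) {
  lines <- readLines(path)
  if (!length(lines)) stop_pif("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop_pif("malformed XYZ atom-count line 1 in ", path)
  if (length(lines) < n + 2L) stop_pif("XYZ file truncated: ", path)
  if (n == 0L)
    return(pif_molecule(matrix(numeric(0), 0, 3), integer(0), K))
  el <- pif_elements(K)
  coords <- matrix(0, n, 3)
  types <- integer(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 2L]), "\\s+")[[1]]
    if (length(parts) < 4L)
      stop_pif("malformed XYZ atom line ", i + 2L, " in ", path)
    ty <- match(parts[1], el)
    if (is.na(ty))
      stop_pif("unknown element symbol '", parts[1], "' on line ", i + 2L,
               " of ", path)
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz)))
      stop_pif("malformed coordinates on line ", i + 2L, " of ", path)
    coords[i, ] <- xyz
    types[i] <- ty
  }
  pif_molecule(coords, types, K)
}

#' Write a molecule as SDF (V2000)
#'
#' Without bond perception the bond block is empty; with it, atoms within
#' covalent-radius-sum x 1.3 receive single bonds. Distance-rule
#' perception is a convenience for downstream toolkits, not a chemical
#' bond assignment.
#'
#' @param path output file path.
#' @param molecule a [pif_molecule()].
#' @param perceive_bonds add distance-rule single bonds (default TRUE).
#' @param title molecule title line.
#' @return the path, invisibly.
#' @export
write_sdf <- function(path, molecule, perceive_bonds = TRUE,
                      title = "pifgen molecule") {
  stopifnot(inherits(molecule, "pif_molecule"))
  n <- nrow(molecule$coords)
  if (n > 999L) stop_pif("V2000 SDF is limited to 999 atoms")
  bonds <- if (perceive_bonds) perceive_bonds(molecule)
           else matrix(integer(0), ncol = 2L)
  el <- pif_elements(molecule$K)[molecule$types]
  lines <- c(title, "  pifgen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n, nrow(bonds)),
             if (n > 0) sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                molecule$coords[, 1], molecule$coords[, 2],
                                molecule$coords[, 3], el),
             if (nrow(bonds) > 0) sprintf("%3d%3d  1  0  0  0  0",
                                          bonds[, 1], bonds[, 2]),
             "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

# ---- structured configuration ----------------------------------------------

pif_config_schema <- function() {
  list(
    schedule = list(kind = "exponential", gamma = 0.009),
    prior = list(family = "gaussian", eps0 = 1, beta0 = 1, K = 4),
    loss = list(lambda_x = 1, lambda_v = 1, dirichlet_form = "printed"),
    mask = list(p_activate = 0.3, p_atom = 0.3),
    model = list(hidden_dim = 32, layers = 2, knn_k = 16),
    train = list(steps = 2000, batch_size = 8, learning_rate = 1e-3,
                 seed = 1, log_every = 50, t_max = 0.99),
    sample = list(n_steps = 100, seed = 1, n_atoms = NA),
    data = list(template = "chain", n_molecules = 500, seed = 1,
                n_atoms_min = 6, n_atoms_max = 12),
    eval = list(bins = 64))
}

#' Validate and complete a run configuration
#'
#' Nested sections mirror the module parameters; every omitted field
#' receives its documented default, and unknown sections or keys are
#' rejected. The resolved config carries a content hash so artifacts can
#' be traced to the exact settings that produced them.
#'
#' @param cfg nested list (e.g. from [pif_read_config()]); `NULL` or empty
#'   yields all defaults.
#' @return the resolved config with attribute-free `$hash`.
#' @export
pif_config <- function(cfg = list()) {
  schema <- pif_config_schema()
  cfg <- cfg %||% list()
  bad_sections <- setdiff(names(cfg), names(schema))
  if (length(bad_sections))
    stop_pif("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  out <- schema
  for (sec in names(cfg)) {
    bad_keys <- setdiff(names(cfg[[sec]]), names(schema[[sec]]))
    if (length(bad_keys))
      stop_pif("unknown key(s) in [", sec, "]: ",
               paste(bad_keys, collapse = ", "))
    out[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  out$hash <- config_hash(out)
  out
}

#' Read a YAML run configuration
#'
#' @param path YAML file with the sections of [pif_config()].
#' @return resolved, validated config.
#' @export
pif_read_config <- function(path) {
  pif_config(yaml::read_yaml(path))
}
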
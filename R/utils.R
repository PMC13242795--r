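#' @keywords internal
#' @importFrom stats rnorm runif rgamma dist integrate var dnorm dbeta
#' @importFrom utils tail combn write.csv
#' @importFrom graphics plot
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pif <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_pif(what, " must be finite numeric")
  invisible(x)
}

# coerce a coordinate input to an n x d numeric matrix
as_coord_matrix <- function(x, d = NULL, what = "coordinates") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(d) && ncol(x) != d)
    stop_pif(what, " must have ", d, " columns, got ", ncol(x))
  check_finite(x, what)
  x
}

# FNV-1a over the serialized representation; used to stamp artifact configs
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seed <- function(seed, i) {
  (as.integer(seed) + 1000003L * as.integer(i)) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
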
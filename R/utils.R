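#' @useDynLib phytosynth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile var
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom grDevices rgb2hsv
"_PACKAGE"

# ---- condition helpers -------------------------------------------------

phyto_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "phytosynth_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(msg, ...) phyto_stop("phytosynth_validation_error", msg, ...)
stop_config     <- function(msg, ...) phyto_stop("phytosynth_config_error", msg, ...)
stop_render     <- function(msg, ...) phyto_stop("phytosynth_render_error", msg, ...)
stop_io         <- function(msg, ...) phyto_stop("phytosynth_io_error", msg, ...)

check_range <- function(x, field, lo = -Inf, hi = Inf,
                        lo_open = FALSE, hi_open = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("field '%s' must be a finite numeric scalar", field))
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop_validation(sprintf(
      "field '%s' = %g outside %s%g, %g%s", field, x,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"))
  if (integer && x != round(x))
    stop_validation(sprintf("field '%s' = %g must be an integer", field, x))
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# ---- deterministic seed derivation ------------------------------------

# 32-bit mixing done in doubles via 16-bit limbs (exact: all intermediates
# stay below 2^53). Child seeds are a pure function of (seed, stream ids),
# so image k of a dataset is identical regardless of the total count n.
.mul32 <- function(a, b) {
  a0 <- a %% 65536
  a1 <- (a - a0) / 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

.xor32 <- function(a, b) {
  a0 <- a %% 65536; a1 <- (a - a0) / 65536
  b0 <- b %% 65536; b1 <- (b - b0) / 65536
  bitwXor(as.integer(a1), as.integer(b1)) * 65536 +
    bitwXor(as.integer(a0), as.integer(b0))
}

.mix32 <- function(x) {
  x <- x %% 4294967296
  x <- .xor32(x, floor(x / 65536))
  x <- .mul32(x, 2246822519)
  x <- .xor32(x, floor(x / 8192))
  x <- .mul32(x, 3266489917)
  x <- .xor32(x, floor(x / 65536))
  x
}

#' Derive a child seed from a master seed and stream identifiers
#'
#' Counter-based derivation: the child is a pure function of the master seed
#' and the integer stream ids, so derived streams are stable no matter how
#' many sibling streams exist. The result lies in `[1, 2^31 - 2]` and can be
#' passed to [set.seed()].
#'
#' @param seed non-negative integer master seed.
#' @param ... integer stream identifiers (e.g. an image counter).
#' @return an integer scalar seed.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(...)
  h <- .mix32(seed %% 4294967296)
  for (id in ids) h <- .mix32(.xor32(h, (id %% 4294967296)) + 2654435769)
  as.integer(h %% 2147483645) + 1L
}

# evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
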
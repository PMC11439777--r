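# Coherent value noise: smooth-interpolated random lattices summed over
# octaves. This is the only stochastic field primitive used by the texture
# and backdrop generators; everything built on it inherits its determinism.

.smoothstep <- function(t) t * t * (3 - 2 * t)

.noise_octave <- function(h, w, f) {
  f <- max(1L, as.integer(f))
  g <- matrix(runif((f + 1L) * (f + 1L)), f + 1L, f + 1L)
  gy <- (seq_len(h) - 0.5) / h * f
  gx <- (seq_len(w) - 0.5) / w * f
  i0 <- pmin(floor(gy), f - 1L)
  j0 <- pmin(floor(gx), f - 1L)
  fy <- .smoothstep(gy - i0)
  fx <- .smoothstep(gx - j0)
  FY <- matrix(fy, h, w)
  FX <- matrix(fx, h, w, byrow = TRUE)
  g00 <- g[i0 + 1L, j0 + 1L, drop = FALSE]
  g01 <- g[i0 + 1L, j0 + 2L, drop = FALSE]
  g10 <- g[i0 + 2L, j0 + 1L, drop = FALSE]
  g11 <- g[i0 + 2L, j0 + 2L, drop = FALSE]
  (1 - FY) * ((1 - FX) * g00 + FX * g01) + FY * ((1 - FX) * g10 + FX * g11)
}

#' Seeded multi-octave value noise field
#'
#' @param h,w output dimensions in pixels.
#' @param freq base lattice frequency (cells across the field).
#' @param octaves number of octaves; each doubles the frequency and halves
#'   the amplitude.
#' @param seed integer seed; the field is a pure function of
#'   `(h, w, freq, octaves, seed)`.
#' @return an `h x w` matrix rescaled to `[0, 1]`.
#' @export
value_noise <- function(h, w, freq = 4, octaves = 3, seed = 0) {
  with_seed(derive_seed(seed, 101L), {
    out <- matrix(0, h, w)
    amp <- 1
    f <- freq
    for (o in seq_len(octaves)) {
      out <- out + amp * .noise_octave(h, w, f)
      amp <- amp / 2
      f <- f * 2
    }
    rng <- range(out)
    if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out * 0 + 0.5
  })
}
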
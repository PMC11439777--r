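# Leaf material synthesis: layered texture stacks (albedo, tangent-space
# normal, ambient occlusion, height) and parametric disease alterations with
# exact ground-truth lesion masks.

.hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- pmin(floor(h), 5)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  tt <- v * (1 - s * (1 - f))
  r <- v; g <- v; b <- v
  r[i == 1] <- q[i == 1];  r[i == 2] <- p[i == 2];  r[i == 3] <- p[i == 3]
  r[i == 4] <- tt[i == 4]
  g[i == 0] <- tt[i == 0]; g[i == 3] <- q[i == 3];  g[i == 4] <- p[i == 4]
  g[i == 5] <- p[i == 5]
  b[i == 0] <- p[i == 0];  b[i == 1] <- p[i == 1];  b[i == 2] <- tt[i == 2]
  b[i == 5] <- q[i == 5]
  list(r = r, g = g, b = b)
}

.luminance <- function(r, g, b) 0.2126 * r + 0.7152 * g + 0.0722 * b

.normal_from_height <- function(height, relief) {
  H <- nrow(height); W <- ncol(height)
  gy <- (height[c(2:H, H), ] - height[c(1, 1:(H - 1)), ]) * H / 2
  gx <- (height[, c(2:W, W)] - height[, c(1, 1:(W - 1))]) * W / 2
  nx <- -gx * relief
  ny <- -gy * relief
  nz <- matrix(1, H, W)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  out <- array(0, c(H, W, 3))
  out[, , 1] <- nx / nn
  out[, , 2] <- ny / nn
  out[, , 3] <- nz / nn
  out
}

#' Validate a texture stack
#'
#' Checks that the four layers share one size, normals are unit vectors
#' within 1e-3, and ambient occlusion and height lie in `[0, 1]`.
#'
#' @param tex a `phyto_texture`.
#' @return the texture, invisibly.
#' @export
validate_texture_set <- function(tex) {
  if (!inherits(tex, "phyto_texture"))
    stop_validation("not a phyto_texture object")
  H <- tex$size[1]; W <- tex$size[2]
  if (!all(dim(tex$albedo) == c(H, W, 3)) ||
      !all(dim(tex$normal) == c(H, W, 3)) ||
      !all(dim(tex$ambient_occlusion) == c(H, W)) ||
      !all(dim(tex$height) == c(H, W)))
    stop_validation("texture layers do not share a common size")
  nl <- sqrt(tex$normal[, , 1]^2 + tex$normal[, , 2]^2 + tex$normal[, , 3]^2)
  if (max(abs(nl - 1)) > 1e-3)
    stop_validation("normal map is not unit length within 1e-3")
  if (min(tex$ambient_occlusion) < 0 || max(tex$ambient_occlusion) > 1)
    stop_validation("ambient_occlusion outside [0, 1]")
  if (min(tex$height) < 0 || max(tex$height) > 1)
    stop_validation("height outside [0, 1]")
  invisible(tex)
}

#' Default healthy-leaf texture parameters
#'
#' @return a named list: `base_hue` (degrees, default 110, inside the green
#'   band), `hue_var` (degrees), `venation_amplitude` (relief of midrib and
#'   lateral veins; 0 gives a perfectly flat height layer), `vein_freq`
#'   (lateral vein pairs across the blade), `noise_freq` (base frequency of
#'   the color mottle), `relief` (normal-map strength).
#' @export
texture_params <- function() {
  list(base_hue = 110, hue_var = 14, venation_amplitude = 0.3,
       vein_freq = 7, noise_freq = 3, relief = 1.2)
}

#' Synthesize a healthy leaf texture stack
#'
#' Builds the four physically-based layers from coherent noise fields and a
#' procedural venation pattern: mottled green albedo (HSV composition around
#' `base_hue`), height from veins + fine noise scaled by
#' `venation_amplitude`, tangent-space normals (+Z out of the leaf) derived
#' from the height gradient, and ambient occlusion tied to height.
#'
#' @param size integer vector `(H, W)`, both at least 16.
#' @param params parameter list as from [texture_params()]; partial lists
#'   are merged over the defaults.
#' @param seed integer seed; output is a pure function of
#'   `(size, params, seed)`.
#' @return a `phyto_texture` with fields `albedo`, `normal`,
#'   `ambient_occlusion`, `height`, `size`.
#' @export
healthy_texture <- function(size = c(128, 128), params = list(), seed = 0) {
  if (length(size) != 2 || any(size < 16))
    stop_validation("size must be (H, W) with both dimensions >= 16")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  p <- modifyList(texture_params(), params)

  n_coarse <- value_noise(H, W, freq = p$noise_freq, octaves = 3,
                          seed = derive_seed(seed, 1L))
  n_fine <- value_noise(H, W, freq = p$noise_freq * 3, octaves = 2,
                        seed = derive_seed(seed, 2L))

  # venation: midrib along the texture x axis plus curved lateral veins
  yn <- matrix((seq_len(H) - 0.5) / H, H, W)
  xn <- matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE)
  midrib <- exp(-((yn - 0.5) * 14)^2)
  lateral <- abs(cos(pi * p$vein_freq * (xn - 0.35 * abs(yn - 0.5))))^14
  lateral <- lateral * exp(-((yn - 0.5) * 3.2)^2)
  veins <- pmax(midrib, lateral)

  mix <- clamp01(0.6 * (1 - veins) + 0.4 * n_fine)
  height <- clamp01(0.5 + p$venation_amplitude * (mix - 0.5))
  normal <- .normal_from_height(height, p$relief)
  ao <- 0.8 + 0.2 * height

  hue <- (p$base_hue + p$hue_var * (2 * n_coarse - 1)) / 360
  sat <- clamp01(0.55 + 0.25 * (n_fine - 0.5))
  val <- clamp01(0.42 + 0.26 * (n_coarse - 0.5) + 0.10 * veins)
  ch <- .hsv_to_rgb(hue, sat, val)
  albedo <- array(0, c(H, W, 3))
  albedo[, , 1] <- ch$r; albedo[, , 2] <- ch$g; albedo[, , 3] <- ch$b

  structure(list(albedo = albedo, normal = normal,
                 ambient_occlusion = ao, height = height,
                 size = c(H, W)),
            class = "phyto_texture")
}

.disease_families <- c("necrotic_spots", "blight_blotch",
                       "powdery_coating", "chlorosis")

# maximum lesion coverage reached at severity 1, per family
.family_max_coverage <- c(necrotic_spots = 0.25, blight_blotch = 0.5,
                          powdery_coating = 0.7, chlorosis = 0.9)

.family_tint <- list(
  necrotic_spots = c(0.28, 0.16, 0.07),
  blight_blotch = c(0.33, 0.20, 0.08),
  powdery_coating = c(0.93, 0.94, 0.90),
  chlorosis = c(0.78, 0.72, 0.20)
)

#' Disease alteration specification
#'
#' @param family one of `"necrotic_spots"`, `"blight_blotch"`,
#'   `"powdery_coating"`, `"chlorosis"`.
#' @param severity scalar in `[0, 1]`; 0 means healthy (identity). Severity
#'   maps linearly to lesion coverage, see [target_coverage()].
#' @param lesion_density expected lesion count per unit texture area
#'   (spot family only).
#' @param lesion_size_mean,lesion_size_sd lesion radius distribution in
#'   pixels (spot family only); both must be positive.
#' @param color_params optional list; `tint` (RGB in `[0,1]`) overrides the
#'   family's lesion color.
#' @return a `phyto_disease_spec`.
#' @export
disease_spec <- function(family, severity, lesion_density = 30,
                         lesion_size_mean = 6, lesion_size_sd = 2,
                         color_params = NULL) {
  if (!is.character(family) || length(family) != 1L ||
      !(family %in% .disease_families))
    stop_validation(sprintf("unknown disease family '%s' (known: %s)",
                            as.character(family)[1],
                            paste(.disease_families, collapse = ", ")))
  check_range(severity, "severity", 0, 1)
  check_range(lesion_density, "lesion_density", 0, Inf)
  check_range(lesion_size_mean, "lesion_size_mean", 0, Inf, lo_open = TRUE)
  check_range(lesion_size_sd, "lesion_size_sd", 0, Inf, lo_open = TRUE)
  structure(list(family = family, severity = severity,
                 lesion_density = lesion_density,
                 lesion_size_mean = lesion_size_mean,
                 lesion_size_sd = lesion_size_sd,
                 color_params = color_params),
            class = "phyto_disease_spec")
}

#' Target lesion coverage implied by a disease specification
#'
#' The documented severity-to-coverage map: `severity * family_max`, where
#' the per-family maxima are 0.25 / 0.5 / 0.7 / 0.9 for spots / blotch /
#' coating / chlorosis. Monotone non-decreasing in severity and exactly 0 at
#' severity 0.
#'
#' @param spec a [disease_spec()].
#' @return scalar in `[0, 1]`.
#' @export
target_coverage <- function(spec) {
  if (!inherits(spec, "phyto_disease_spec"))
    stop_validation("not a phyto_disease_spec")
  unname(spec$severity * .family_max_coverage[spec$family])
}

.disease_field <- function(spec, H, W, seed) {
  nz <- value_noise(H, W, freq = 5, octaves = 3, seed = derive_seed(seed, 31L))
  switch(spec$family,
    necrotic_spots = {
      with_seed(derive_seed(seed, 32L), {
        n_spots <- max(1L, as.integer(round(spec$lesion_density)))
        cy <- runif(n_spots) * H
        cx <- runif(n_spots) * W
        rr <- pmax(1.5, rnorm(n_spots, spec$lesion_size_mean, spec$lesion_size_sd))
        yn <- matrix(seq_len(H) - 0.5, H, W)
        xn <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
        fld <- matrix(0, H, W)
        for (s in seq_len(n_spots)) {
          d <- sqrt((yn - cy[s])^2 + (xn - cx[s])^2)
          fld <- pmax(fld, 1 - d / rr[s])
        }
        pmax(fld, 0) + 0.25 * nz
      })
    },
    blight_blotch = {
      with_seed(derive_seed(seed, 33L), {
        cy <- runif(1) * H; cx <- runif(1) * W
        yn <- matrix(seq_len(H) - 0.5, H, W)
        xn <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
        d <- sqrt((yn - cy)^2 + (xn - cx)^2) / sqrt(H^2 + W^2)
        0.55 * value_noise(H, W, freq = 3, octaves = 3,
                           seed = derive_seed(seed, 34L)) + 0.45 * (1 - d)
      })
    },
    powdery_coating = value_noise(H, W, freq = 6, octaves = 3,
                                  seed = derive_seed(seed, 35L)),
    chlorosis = value_noise(H, W, freq = 2, octaves = 2,
                            seed = derive_seed(seed, 36L))
  )
}

#' Apply a disease alteration to a healthy texture stack
#'
#' Builds a family-specific continuous intensity field, thresholds it at the
#' field quantile that realizes [target_coverage()] (so realized coverage
#' tracks the target up to pixel rounding), and recolors/perturbs only the
#' masked pixels: necrotic and blotch lesions blend the albedo toward dead
#' brown (the blotch with a chlorotic halo at the lesion rim) and sink the
#' height layer; the powdery coating blends toward white (strictly raising
#' masked-pixel luminance) and raises the height; chlorosis yellows the
#' albedo only. Normals are relaxed toward flat inside lesions. Pixels
#' outside the mask are bit-identical to the input on every layer; severity
#' 0 returns the input unchanged with an empty mask.
#'
#' @param tex a `phyto_texture` from [healthy_texture()].
#' @param spec a [disease_spec()].
#' @param seed integer seed.
#' @return a list with elements `texture` (altered `phyto_texture`) and
#'   `mask` (`phyto_lesion_mask`: logical `mask` plus realized `coverage`).
#' @export
apply_disease <- function(tex, spec, seed = 0) {
  validate_texture_set(tex)
  if (!inherits(spec, "phyto_disease_spec"))
    stop_validation("not a phyto_disease_spec")
  H <- tex$size[1]; W <- tex$size[2]

  if (spec$severity == 0) {
    return(list(texture = tex,
                mask = structure(list(mask = matrix(FALSE, H, W), coverage = 0),
                                 class = "phyto_lesion_mask")))
  }

  target <- target_coverage(spec)
  fld <- .disease_field(spec, H, W, seed)
  tau <- quantile(fld, 1 - target, names = FALSE)
  mask <- fld > tau
  coverage <- mean(mask)
  g <- pmin(pmax((fld - tau) / max(max(fld) - tau, 1e-9), 0), 1)

  tint <- spec$color_params$tint %||% .family_tint[[spec$family]]
  w <- switch(spec$family,
    necrotic_spots = 0.60 + 0.35 * g,
    blight_blotch = 0.55 + 0.40 * g,
    powdery_coating = 0.50 + 0.40 * g,
    chlorosis = 0.45 + 0.45 * g
  )

  out <- tex
  # necrotic spots and blight blotches carry the textbook chlorotic halo:
  # lesion rims (low lesion grade) lean yellow before browning at the core
  halo <- spec$family %in% c("necrotic_spots", "blight_blotch")
  for (k in 1:3) {
    ch <- out$albedo[, , k]
    tk <- tint[k]
    if (halo) {
      rim <- .family_tint$chlorosis[k]
      gg <- pmin(g / 0.35, 1)
      tk <- rim * (1 - gg[mask]) + tint[k] * gg[mask]
    }
    ch[mask] <- (1 - w[mask]) * ch[mask] + w[mask] * tk
    out$albedo[, , k] <- ch
  }

  hgt <- out$height
  dh <- switch(spec$family,
    necrotic_spots = -0.35 * g,
    blight_blotch = -0.30 * g,
    powdery_coating = 0.15 * g,
    chlorosis = 0 * g
  )
  hgt[mask] <- clamp01(hgt[mask] + dh[mask])
  out$height <- hgt

  # relax normals toward flat inside lesions, masked pixels only
  relax <- 0.5 * g[mask]
  nx <- out$normal[, , 1]; ny <- out$normal[, , 2]; nz <- out$normal[, , 3]
  vx <- nx[mask] * (1 - relax)
  vy <- ny[mask] * (1 - relax)
  vz <- nz[mask] * (1 - relax) + relax
  nn <- sqrt(vx^2 + vy^2 + vz^2)
  nx[mask] <- vx / nn; ny[mask] <- vy / nn; nz[mask] <- vz / nn
  out$normal[, , 1] <- nx; out$normal[, , 2] <- ny; out$normal[, , 3] <- nz

  list(texture = out,
       mask = structure(list(mask = mask, coverage = coverage),
                        class = "phyto_lesion_mask"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
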
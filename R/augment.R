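# Staged augmentation regimes. Four registered modes: none (bit-exact
# identity), weak (geometric + brightness), medium (adds Gaussian blur,
# contrast, hue shift, additive Gaussian noise), strong (all ranges doubled).
# Operators apply in a fixed order, geometric before photometric, so blur and
# noise land on the final geometry the way camera artifacts would.

#' Augmentation parameter ranges
#'
#' All parameters are drawn uniformly from their ranges at application time.
#' An operator whose range is exactly 0 is skipped entirely, so the
#' all-zero configuration is a bit-exact identity.
#'
#' @param zoom_range zoom factor half-range (fraction; factor in `1 +/- r`).
#' @param brightness_range multiplicative brightness half-range (fraction).
#' @param flip_h,flip_v horizontal/vertical mirror probabilities in `[0, 1]`.
#' @param rotation_range rotation half-range in degrees.
#' @param blur_sigma_range length-2 range of Gaussian blur sigma in pixels.
#' @param contrast_range contrast factor half-range (fraction).
#' @param hue_shift_range hue shift half-range in degrees.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (fraction of full scale).
#' @return a `phyto_augment_config`.
#' @export
augment_config <- function(zoom_range = 0, brightness_range = 0,
                           flip_h = 0, flip_v = 0, rotation_range = 0,
                           blur_sigma_range = c(0, 0), contrast_range = 0,
                           hue_shift_range = 0, noise_sd = 0) {
  for (f in c("zoom_range", "brightness_range", "rotation_range",
              "contrast_range", "hue_shift_range", "noise_sd"))
    check_range(get(f), f, 0, Inf)
  check_range(flip_h, "flip_h", 0, 1)
  check_range(flip_v, "flip_v", 0, 1)
  if (length(blur_sigma_range) != 2 || any(blur_sigma_range < 0) ||
      blur_sigma_range[2] < blur_sigma_range[1])
    stop_validation("field 'blur_sigma_range' must be a non-negative ascending pair")
  structure(list(zoom_range = zoom_range, brightness_range = brightness_range,
                 flip_h = flip_h, flip_v = flip_v,
                 rotation_range = rotation_range,
                 blur_sigma_range = blur_sigma_range,
                 contrast_range = contrast_range,
                 hue_shift_range = hue_shift_range, noise_sd = noise_sd),
            class = "phyto_augment_config")
}

.augment_modes <- list(
  none = list(),
  weak = list(zoom_range = 0.10, brightness_range = 0.10,
              flip_h = 0.5, flip_v = 0.5, rotation_range = 15),
  medium = list(zoom_range = 0.10, brightness_range = 0.10,
                flip_h = 0.5, flip_v = 0.5, rotation_range = 15,
                blur_sigma_range = c(0, 1.5), contrast_range = 0.20,
                hue_shift_range = 10, noise_sd = 0.02),
  strong = list(zoom_range = 0.20, brightness_range = 0.20,
                flip_h = 0.5, flip_v = 0.5, rotation_range = 45,
                blur_sigma_range = c(0, 3), contrast_range = 0.40,
                hue_shift_range = 20, noise_sd = 0.04)
)

#' Resolve a registered augmentation mode to its configuration
#'
#' @param name one of `"none"`, `"weak"`, `"medium"`, `"strong"`.
#' @return a `phyto_augment_config`.
#' @export
augment_mode <- function(name) {
  if (inherits(name, "phyto_augment_config")) return(name)
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(.augment_modes)))
    stop_config(sprintf("unregistered augmentation mode '%s' (registered: %s)",
                        as.character(name)[1],
                        paste(names(.augment_modes), collapse = ", ")))
  do.call(augment_config, .augment_modes[[name]])
}

#' Fixed operator application order
#'
#' Geometric operators first (flip, rotate, zoom), then photometric
#' (brightness, contrast, hue, blur, noise).
#'
#' @return character vector of the 8 operator names.
#' @export
op_order <- function() {
  c("flip", "rotate", "zoom", "brightness", "contrast", "hue", "blur", "noise")
}

# inverse-mapped bilinear resample (rotation about the image center and/or
# zoom), with edge replication so exposed corners never turn black
.affine_resample <- function(img, angle_deg, zoom) {
  H <- dim(img)[1]; W <- dim(img)[2]
  th <- angle_deg * pi / 180
  jj <- matrix(seq_len(W) - 0.5 - W / 2, H, W, byrow = TRUE)
  ii <- matrix(seq_len(H) - 0.5 - H / 2, H, W)
  xs <- (cos(th) * jj + sin(th) * ii) / zoom + W / 2 - 0.5
  ys <- (-sin(th) * jj + cos(th) * ii) / zoom + H / 2 - 0.5
  xs <- pmin(pmax(xs, 0), W - 1)
  ys <- pmin(pmax(ys, 0), H - 1)
  j0 <- floor(xs); i0 <- floor(ys)
  fx <- xs - j0; fy <- ys - i0
  j1 <- pmin(j0 + 1, W - 1); i1 <- pmin(i0 + 1, H - 1)
  a00 <- (i0 + 1) + H * j0; a01 <- (i0 + 1) + H * j1
  a10 <- (i1 + 1) + H * j0; a11 <- (i1 + 1) + H * j1
  for (k in seq_len(dim(img)[3])) {
    m <- img[, , k]
    img[, , k] <- (1 - fy) * ((1 - fx) * m[a00] + fx * m[a01]) +
      fy * ((1 - fx) * m[a10] + fx * m[a11])
  }
  img
}

.shift_hue <- function(img, degrees) {
  H <- dim(img)[1]; W <- dim(img)[2]
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- rgb2hsv(m, maxColorValue = 1)
  ch <- .hsv_to_rgb(hsv[1, ] + degrees / 360, hsv[2, ], hsv[3, ])
  img[, , 1] <- matrix(ch$r, H, W)
  img[, , 2] <- matrix(ch$g, H, W)
  img[, , 3] <- matrix(ch$b, H, W)
  img
}

#' Apply a random augmentation to an image
#'
#' Operators apply in [op_order()], each drawing its parameter uniformly
#' from the mode's range. Deterministic per `(image, mode, seed)`; mode
#' `"none"` returns the input bit-identically, as does any configuration
#' whose ranges and flip probabilities are all zero.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mode a registered mode name or a [augment_config()].
#' @param seed integer seed.
#' @return an H x W x 3 array of the same dimensions.
#' @export
augment <- function(image, mode = "none", seed = 0) {
  if (!is.array(image) || length(dim(image)) != 3)
    stop_validation("image must be an H x W x 3 array")
  cfg <- augment_mode(mode)
  with_seed(derive_seed(seed, 51L), {
    W <- dim(image)[2]; H <- dim(image)[1]
    if (cfg$flip_h > 0 && runif(1) < cfg$flip_h)
      image <- image[, W:1, , drop = FALSE]
    if (cfg$flip_v > 0 && runif(1) < cfg$flip_v)
      image <- image[H:1, , , drop = FALSE]
    if (cfg$rotation_range > 0)
      image <- .affine_resample(
        image, runif(1, -cfg$rotation_range, cfg$rotation_range), 1)
    if (cfg$zoom_range > 0)
      image <- .affine_resample(
        image, 0, 1 + runif(1, -cfg$zoom_range, cfg$zoom_range))
    if (cfg$brightness_range > 0)
      image <- clamp01(image *
        (1 + runif(1, -cfg$brightness_range, cfg$brightness_range)))
    if (cfg$contrast_range > 0)
      image <- clamp01((image - 0.5) *
        (1 + runif(1, -cfg$contrast_range, cfg$contrast_range)) + 0.5)
    if (cfg$hue_shift_range > 0)
      image <- .shift_hue(
        image, runif(1, -cfg$hue_shift_range, cfg$hue_shift_range))
    if (cfg$blur_sigma_range[2] > 0)
      image <- gaussian_blur(
        image, runif(1, cfg$blur_sigma_range[1], cfg$blur_sigma_range[2]))
    if (cfg$noise_sd > 0)
      image <- clamp01(image + array(rnorm(length(image), 0, cfg$noise_sd),
                                     dim(image)))
    image
  })
}
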
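# Scene composition and rendering: 2.5D textured-polygon rasterization with
# per-pixel Lambert shading, a procedural greenhouse backdrop, an optional
# defocused background branch, and auto-generated ground-truth labels.
# Compositing order is fixed: backdrop -> blurred background branch ->
# foreground branch. The label is a pure function of the generating disease
# specification, never inferred from pixels.

#' Scene specification
#'
#' @param foreground list with `geometry` (a `phyto_branch`), `texture`
#'   (a `phyto_texture`) and optional `disease` (a [disease_spec()]; `NULL`
#'   or severity 0 labels the image healthy).
#' @param background_branch optional list with `geometry`, `texture` and
#'   `defocus_sigma` (Gaussian blur sigma in pixels, >= 0).
#' @param backdrop either a list `list(seed = <int>)` selecting a procedural
#'   greenhouse backdrop, or an H x W x 3 array in `[0, 1]` (e.g. a user
#'   supplied photo read with `png::readPNG`).
#' @param light list with `direction` (3-vector, normalized internally),
#'   `intensity` (>= 0) and `ambient` (in `[0, 1]`).
#' @param view list with `zoom` (> 0) and `offset` (fraction of image size,
#'   length 2).
#' @param resolution integer `(H, W)`, both at least 32.
#' @return a `phyto_scene`.
#' @export
scene_spec <- function(foreground,
                       background_branch = NULL,
                       backdrop = list(seed = 0),
                       light = list(direction = c(-0.3, 0.25, 0.9),
                                    intensity = 1, ambient = 0.35),
                       view = list(zoom = 1, offset = c(0, 0)),
                       resolution = c(256, 256)) {
  if (any(resolution < 32))
    stop_validation("resolution must be at least 32 x 32")
  light$direction <- .normalize3(light$direction)
  check_range(light$intensity, "light.intensity", 0, Inf)
  check_range(light$ambient, "light.ambient", 0, 1)
  check_range(view$zoom, "view.zoom", 0, Inf, lo_open = TRUE)
  if (!is.null(background_branch))
    check_range(background_branch$defocus_sigma, "defocus_sigma", 0, Inf)
  if (!is.null(foreground$disease) &&
      !inherits(foreground$disease, "phyto_disease_spec"))
    stop_validation("foreground$disease must be a phyto_disease_spec or NULL")
  structure(list(foreground = foreground,
                 background_branch = background_branch,
                 backdrop = backdrop, light = light, view = view,
                 resolution = as.integer(resolution)),
            class = "phyto_scene")
}

#' Procedural greenhouse backdrop
#'
#' A stand-in for captured greenhouse panoramas: a soft sky-to-ground
#' gradient, dark vertical row posts with a horizontal rail, low-frequency
#' clutter noise, and a green foliage tint toward the bottom. Deterministic
#' per `(seed, size)`.
#'
#' @param seed integer seed.
#' @param size integer `(H, W)`, both at least 32.
#' @return an H x W x 3 array in `[0, 1]`.
#' @export
procedural_backdrop <- function(seed = 0, size = c(256, 256)) {
  if (any(size < 32)) stop_validation("size must be at least 32 x 32")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  with_seed(derive_seed(seed, 41L), {
    yn <- matrix((seq_len(H) - 0.5) / H, H, W)
    xn <- matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE)
    top <- c(0.78, 0.80, 0.74); bot <- c(0.34, 0.40, 0.31)

    n_posts <- sample(4:8, 1)
    post_x <- runif(n_posts)
    post_w <- runif(n_posts, 0.01, 0.03)
    shade <- matrix(1, H, W)
    for (i in seq_len(n_posts))
      shade <- shade * (1 - 0.55 * exp(-((xn - post_x[i]) / post_w[i])^2))
    rail_y <- runif(1, 0.2, 0.45)
    shade <- shade * (1 - 0.35 * exp(-((yn - rail_y) / 0.012)^2))

    clutter <- value_noise(H, W, freq = 6, octaves = 3,
                           seed = derive_seed(seed, 42L))
    amp <- 0.8 + 0.4 * (clutter - 0.5)
    green_w <- clamp01((yn - 0.35) * 1.4) * clutter
    green <- c(0.30, 0.45, 0.24)

    out <- array(0, c(H, W, 3))
    for (k in 1:3) {
      base <- top[k] + (bot[k] - top[k]) * yn
      ch <- base * shade * amp
      out[, , k] <- clamp01(ch * (1 - green_w) + green[k] * green_w)
    }
    out
  })
}

#' Lambert-shade a texture stack into an RGB layer
#'
#' Per-pixel closed form (clamped to the unit interval):
#' `color = albedo * (ambient + intensity * max(0, n.l)) * ambient_occlusion`
#' with `n` the tangent-space normal and `l` the light direction. This is
#' the same shading the rasterizer applies per covered pixel.
#'
#' @param tex a `phyto_texture`.
#' @param light list with `direction`, `intensity`, `ambient`.
#' @return an H x W x 3 array.
#' @export
shade_leaf <- function(tex, light) {
  validate_texture_set(tex)
  d <- .normalize3(light$direction)
  ndl <- tex$normal[, , 1] * d[1] + tex$normal[, , 2] * d[2] +
    tex$normal[, , 3] * d[3]
  shade <- light$ambient + light$intensity * pmax(0, ndl)
  out <- tex$albedo
  for (k in 1:3)
    out[, , k] <- clamp01(tex$albedo[, , k] * shade * tex$ambient_occlusion)
  out
}

#' Gaussian blur with edge replication
#'
#' Separable convolution; `sigma <= 0` returns the input unchanged
#' (bit-identical), so a defocus of 0 is an exact no-op.
#'
#' @param img matrix or H x W x C array.
#' @param sigma standard deviation in pixels.
#' @return blurred image of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_mat <- function(m) {
    H <- nrow(m); W <- ncol(m)
    tmp <- matrix(0, H, W)
    for (o in -r:r)
      tmp <- tmp + k[o + r + 1] * m[pmin(pmax(seq_len(H) + o, 1), H), , drop = FALSE]
    out <- matrix(0, H, W)
    for (o in -r:r)
      out <- out + k[o + r + 1] * tmp[, pmin(pmax(seq_len(W) + o, 1), W), drop = FALSE]
    out
  }
  if (is.matrix(img)) return(blur_mat(img))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- blur_mat(img[, , ch])
  img
}

# project a branch's leaves to screen space and rasterize them (painter's
# algorithm, far-to-near by leaf centroid depth, ties by leaf index)
.rasterize_branch <- function(branch, tex, mapping, H, W, light,
                              world_offset = c(0, 0, 0)) {
  leaves <- branch$leaves
  entries <- vector("list", length(leaves))
  depth <- numeric(length(leaves))
  for (i in seq_along(leaves)) {
    V <- leaf_world_vertices(leaves[[i]])
    V <- sweep(V, 2, world_offset, "+")
    depth[i] <- mean(V[, 3])
    entries[[i]] <- list(
      px = mapping$sx * (V[, 1] - mapping$cx) + W / 2 + mapping$ox * W,
      py = H / 2 - mapping$sy * (V[, 2] - mapping$cy) + mapping$oy * H,
      tri = leaves[[i]]$triangles,
      u = leaves[[i]]$uv[, 1], v = leaves[[i]]$uv[, 2],
      albedo = tex$albedo, normal = tex$normal, ao = tex$ambient_occlusion,
      rot = leaves[[i]]$frame$rotation,
      th = tex$size[1], tw = tex$size[2]
    )
  }
  ord <- order(depth, seq_along(depth))  # far first; ties by leaf index
  rasterize_leaves_cpp(H, W, entries[ord], light$direction,
                       light$intensity, light$ambient)
}

.composite <- function(base, layer_rgb, layer_alpha) {
  for (k in 1:3)
    base[, , k] <- base[, , k] * (1 - layer_alpha) + layer_rgb[, , k] * layer_alpha
  base
}

#' Render a scene into a labeled image
#'
#' Rasterizes the foreground branch (and, if present, a background branch
#' blurred with the stated Gaussian defocus sigma before compositing) over
#' the backdrop, quantizes to 8 bits, and attaches the generation label:
#' `infected` if and only if the foreground disease specification has
#' severity > 0.
#'
#' @param scene a [scene_spec()].
#' @param seed integer seed (controls backdrop choice fallback and the
#'   background-branch placement).
#' @return a `phyto_labeled_image`: `pixels` (H x W x 3 in `[0, 1]`,
#'   quantized to 8-bit levels), `label`, `provenance`.
#' @export
render_scene <- function(scene, seed = 0) {
  if (!inherits(scene, "phyto_scene")) stop_validation("not a phyto_scene")
  H <- scene$resolution[1]; W <- scene$resolution[2]
  fg <- scene$foreground

  label <- if (!is.null(fg$disease) && fg$disease$severity > 0)
    "infected" else "healthy"
  prov <- list(
    seed = seed,
    label = label,
    disease = fg$disease,
    scene_digest = digest::digest(list(scene$view, scene$light,
                                       scene$resolution,
                                       fg$geometry$spec, fg$geometry$seed))
  )

  if (is.array(scene$backdrop)) {
    bd <- scene$backdrop
    if (!all(dim(bd)[1:2] == c(H, W))) bd <- .resize_nearest(bd, H, W)
    out <- bd
  } else {
    out <- procedural_backdrop(scene$backdrop$seed %||% derive_seed(seed, 43L),
                               c(H, W))
  }

  # screen mapping: a leaf-level close-up crop of the foreground branch,
  # emulating patrol photos taken near the canopy (the branch deliberately
  # overflows the frame)
  allv <- do.call(rbind, lapply(fg$geometry$leaves, leaf_world_vertices))
  if (is.null(allv) || nrow(allv) == 0)
    stop_render("degenerate geometry: no foreground leaves",
                provenance = prov)
  rng_x <- range(allv[, 1]); rng_y <- range(allv[, 2])
  span <- max(diff(rng_x), diff(rng_y), 1e-6)
  sc <- 1.6 * min(H, W) / span * scene$view$zoom
  mapping <- list(sx = sc, sy = sc,
                  cx = mean(rng_x), cy = mean(rng_y),
                  ox = scene$view$offset[1], oy = scene$view$offset[2])

  if (!is.null(scene$background_branch)) {
    bb <- scene$background_branch
    shift <- with_seed(derive_seed(seed, 44L),
                       c(runif(2, -0.2, 0.2), 0) * span)
    lay <- .rasterize_branch(bb$geometry, bb$texture, mapping, H, W,
                             scene$light, world_offset = shift)
    sig <- bb$defocus_sigma
    out <- .composite(out, gaussian_blur(lay$rgb, sig),
                      gaussian_blur(lay$alpha, sig))
  }

  lay <- .rasterize_branch(fg$geometry, fg$texture, mapping, H, W, scene$light)
  if (sum(lay$alpha) == 0)
    stop_render("degenerate geometry: foreground branch rasterized to zero pixels",
                provenance = prov)
  out <- .composite(out, lay$rgb, lay$alpha)

  structure(list(pixels = round(clamp01(out) * 255) / 255,
                 label = label, provenance = prov),
            class = "phyto_labeled_image")
}

.resize_nearest <- function(img, H, W) {
  hi <- dim(img)[1]; wi <- dim(img)[2]
  ri <- pmin(pmax(ceiling((seq_len(H) - 0.5) / H * hi), 1), hi)
  ci <- pmin(pmax(ceiling((seq_len(W) - 0.5) / W * wi), 1), wi)
  img[ri, ci, , drop = FALSE]
}

#' Write a labeled image as PNG plus a JSON provenance sidecar
#'
#' @param img a `phyto_labeled_image`.
#' @param path output PNG path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_labeled_image <- function(img, path) {
  png::writePNG(img$pixels, path)
  side <- sub("\\.png$", ".json", path)
  prov <- img$provenance
  prov$label <- img$label
  prov$severity <- if (is.null(prov$disease)) 0 else prov$disease$severity
  prov$disease <- if (is.null(prov$disease)) NULL else unclass(prov$disease)
  jsonlite::write_json(prov, side, auto_unbox = TRUE, null = "null")
  invisible(path)
}
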
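# Dataset building and manifest persistence. Datasets are exactly
# class-balanced (image k is healthy when k is odd, infected when k is even,
# so image k is identical no matter how many images are built), with a
# stratified validation split of exactly round(0.1 * n) images. All
# randomness is derived per image from the master seed, which makes
# regeneration byte-identical.

.manifest_cols <- c("path", "label", "split", "seed", "preset")

.as_manifest <- function(df, dir = NULL) {
  structure(df, manifest_dir = dir, class = c("phyto_manifest", "data.frame"))
}

# scene assembly for one dataset image; pure function of its arguments
.preset_scene <- function(preset, child_seed, infected, resolution,
                          texture_size) {
  bspec <- sample_branch_spec(preset$name, child_seed)
  geom <- build_branch(bspec, derive_seed(child_seed, 1L))
  tex <- healthy_texture(c(texture_size, texture_size),
                         seed = derive_seed(child_seed, 2L))
  dspec <- NULL
  if (infected) {
    dspec <- with_seed(derive_seed(child_seed, 3L), {
      fam <- if (length(preset$families) == 1) preset$families
             else sample(preset$families, 1)
      sev <- runif(1, max(preset$severity_range[1], 1e-3),
                   preset$severity_range[2])
      disease_spec(fam, sev)
    })
    tex <- apply_disease(tex, dspec, seed = derive_seed(child_seed, 4L))$texture
  }

  bg <- NULL
  if (isTRUE(preset$background_branch)) {
    bg <- list(
      geometry = build_branch(sample_branch_spec(preset$name,
                                                 derive_seed(child_seed, 5L)),
                              derive_seed(child_seed, 6L)),
      texture = healthy_texture(c(texture_size, texture_size),
                                seed = derive_seed(child_seed, 7L)),
      defocus_sigma = preset$defocus_sigma
    )
  }

  with_seed(derive_seed(child_seed, 8L), {
    scene_spec(
      foreground = list(geometry = geom, texture = tex, disease = dspec),
      background_branch = bg,
      backdrop = list(seed = derive_seed(child_seed, 9L)),
      light = list(direction = c(runif(2, -0.45, 0.45), 1),
                   intensity = runif(1, 0.8, 1.2),
                   ambient = runif(1, 0.25, 0.45)),
      view = list(zoom = runif(1, 0.85, 1.15), offset = runif(2, -0.05, 0.05)),
      resolution = c(resolution, resolution)
    )
  })
}

#' Build a labeled synthetic dataset on disk
#'
#' Renders `n` images for an iteration preset (PNG plus a JSON provenance
#' sidecar each), exactly half healthy and half infected, and writes a CSV
#' manifest with a stratified validation split of `round(0.1 * n)` images.
#' Deterministic per `(preset, seed, n, resolution)`: rebuilding into a fresh
#' directory reproduces byte-identical images and manifest.
#'
#' @param preset a preset name (see [preset_names()]) or a [gen_preset()]
#'   value.
#' @param seed master integer seed.
#' @param outdir output directory (created if missing).
#' @param n number of images; defaults to the preset's documented size. Must
#'   be even so classes balance exactly.
#' @param resolution square render resolution in pixels (default 256).
#' @param texture_size leaf texture resolution; defaults to
#'   `clamp(resolution, 32, 128)`.
#' @param severity_range optional length-2 override of the preset's disease
#'   severity sampling range, e.g. `c(0.02, 0.15)` for an early-disease
#'   dataset (presets default to the visible-symptom range 0.15-0.6).
#' @param overwrite set `TRUE` to replace an existing manifest.
#' @return the manifest data frame (`path, label, split, seed, preset`),
#'   with the dataset directory attached as attribute `manifest_dir`.
#' @export
build_dataset <- function(preset, seed = 0, outdir, n = NULL,
                          resolution = 256, texture_size = NULL,
                          severity_range = NULL, overwrite = FALSE) {
  if (is.character(preset)) preset <- gen_preset(preset)
  if (!is.null(severity_range)) {
    if (length(severity_range) != 2 || any(severity_range < 0) ||
        any(severity_range > 1) || severity_range[2] < severity_range[1])
      stop_validation("severity_range must be an ascending pair in [0, 1]")
    preset$severity_range <- severity_range
  }
  n <- as.integer(n %||% preset$n_images)
  if (n < 2 || n %% 2 != 0)
    stop_validation("n must be an even number of images >= 2")
  texture_size <- as.integer(texture_size %||% min(max(resolution, 32), 128))

  manifest_path <- file.path(outdir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop_io(sprintf("manifest already exists at %s (use overwrite = TRUE)",
                    manifest_path))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_io(sprintf("cannot create output directory %s", outdir))

  paths <- character(n); labels <- character(n); seeds <- integer(n)
  for (k in seq_len(n)) {
    child <- derive_seed(seed, k)
    infected <- (k %% 2 == 0)
    scene <- .preset_scene(preset, child, infected, resolution, texture_size)
    img <- render_scene(scene, seed = child)
    fname <- sprintf("img_%05d_%s.png", k, img$label)
    write_labeled_image(img, file.path(outdir, fname))
    paths[k] <- fname; labels[k] <- img$label; seeds[k] <- child
  }

  v <- round(0.1 * n)
  h_idx <- which(labels == "healthy"); i_idx <- which(labels == "infected")
  val <- with_seed(derive_seed(seed, 999L), c(
    sample(h_idx, ceiling(v / 2)),
    sample(i_idx, floor(v / 2))
  ))
  split <- ifelse(seq_len(n) %in% val, "val", "train")

  manifest <- .as_manifest(
    data.frame(path = paths, label = labels, split = split,
               seed = seeds, preset = preset$name,
               stringsAsFactors = FALSE),
    dir = outdir)
  write_manifest(manifest, manifest_path)
  manifest
}

#' Write a manifest to CSV
#'
#' @param manifest a manifest data frame with columns
#'   `path, label, split, seed, preset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(.manifest_cols, names(manifest))
  if (length(missing))
    stop_validation(sprintf("manifest lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  utils::write.csv(as.data.frame(manifest)[, .manifest_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a manifest CSV
#'
#' Checks the header, the label and split tokens of every row, and (by
#' default) that every image path resolves relative to the manifest's
#' directory. An empty manifest (header only) is valid.
#'
#' @param path manifest CSV path.
#' @param check_paths verify image files exist (default `TRUE`).
#' @return a manifest data frame with attribute `manifest_dir`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop_io(sprintf("no manifest at %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.manifest_cols, names(df))
  if (length(missing))
    stop_validation(sprintf("manifest %s lacks column(s): %s", path,
                            paste(missing, collapse = ", ")))
  dir <- dirname(path)
  for (col in c("path", "label", "split", "preset"))
    df[[col]] <- as.character(df[[col]])
  df$seed <- as.integer(df$seed)
  if (nrow(df) > 0) {
    bad <- which(!(df$label %in% c("healthy", "infected")))
    if (length(bad))
      stop_validation(sprintf("row %d: unknown label token '%s'",
                              bad[1], df$label[bad[1]]))
    bad <- which(!(df$split %in% c("train", "val")))
    if (length(bad))
      stop_validation(sprintf("row %d: unknown split token '%s'",
                              bad[1], df$split[bad[1]]))
    if (check_paths) {
      full <- ifelse(file.exists(df$path), df$path, file.path(dir, df$path))
      bad <- which(!file.exists(full))
      if (length(bad))
        stop_validation(sprintf("row %d: image path does not exist: %s",
                                bad[1], df$path[bad[1]]))
    }
  }
  .as_manifest(df, dir = dir)
}

#' Read the JSON provenance sidecar of a dataset image
#'
#' @param png_path path to the PNG as stored in the manifest (resolved
#'   against `dir` when relative).
#' @param dir optional dataset directory.
#' @return provenance list (label, seeds, disease severity, ...).
#' @export
read_provenance <- function(png_path, dir = NULL) {
  p <- if (!is.null(dir) && !file.exists(png_path))
    file.path(dir, png_path) else png_path
  jsonlite::read_json(sub("\\.png$", ".json", p), simplifyVector = TRUE)
}
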
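# Iteration presets.
#
# The six presets mirror the case-study iterations: a plain initial dataset,
# a defocused background branch added from the second iteration on, staged
# augmentation escalation, the full disease-family set from the fourth
# iteration, reduced augmentation in the fifth, and a mixed augmentation
# schedule in the sixth. Geometry parameter ranges and leaflet counts are
# this package's own estimates (the source system never published them) and
# are shared across presets; what changes per iteration is dataset size,
# scene composition, disease variety, and the training augmentation mode.

.preset_registry <- new.env(parent = emptyenv())

.geometry_ranges <- list(
  n_leaves = c(4L, 8L),
  branch_length = c(0.85, 1.15),
  curvature = c(-0.9, 0.9),
  phyllotaxis_angle = c(120, 150),
  internode_jitter = c(0.1, 0.4),
  leaf_scale_jitter = c(0.1, 0.35),
  leaf_length = c(0.28, 0.42),
  width_ratio = c(0.35, 0.6),
  n_leaflets = c(3L, 5L, 7L),
  serration_depth = c(0.2, 0.7),
  lobe_depth = c(0.3, 0.8),
  bend_angle = c(-35, 35),
  twist = c(-20, 20),
  petiole_fraction = c(0.05, 0.2)
)

.register_preset <- function(name, n_images, background_branch, defocus_sigma,
                             families, augment, schedule = NULL, notes = "") {
  assign(name, list(
    name = name, n_images = n_images,
    background_branch = background_branch, defocus_sigma = defocus_sigma,
    families = families, augment = augment, schedule = schedule,
    severity_range = c(0.15, 0.6),
    geometry = .geometry_ranges, notes = notes
  ), envir = .preset_registry)
}

local({
  .register_preset("iter1", 3400L, FALSE, 0, "necrotic_spots", "weak",
                   notes = "initial dataset: single branch, one disease family")
  .register_preset("iter2", 2472L, TRUE, 3, "necrotic_spots", "medium",
                   notes = "defocused background branch; photometric augmentation added")
  .register_preset("iter3", 2472L, TRUE, 3, "necrotic_spots", "strong",
                   notes = "same data as iter2, stronger augmentation")
  .register_preset("iter4", 6400L, TRUE, 3,
                   c("necrotic_spots", "blight_blotch", "powdery_coating", "chlorosis"),
                   "strong", notes = "all disease families, enlarged dataset")
  .register_preset("iter5", 6400L, TRUE, 3,
                   c("necrotic_spots", "blight_blotch", "powdery_coating", "chlorosis"),
                   "medium", notes = "iter4 data, augmentation reduced to medium")
  .register_preset("iter6", 6400L, TRUE, 3,
                   c("necrotic_spots", "blight_blotch", "powdery_coating", "chlorosis"),
                   "medium",
                   schedule = list(type = "mixed", first = "medium",
                                   second = "strong", switch_fraction = 0.5),
                   notes = "mixed schedule: medium then strong halfway")
})

#' Look up a registered iteration preset
#'
#' @param name one of `"iter1"` ... `"iter6"`.
#' @return the preset definition (dataset size, scene options, disease
#'   families, default augmentation, geometry sampling ranges).
#' @export
gen_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !exists(name, envir = .preset_registry, inherits = FALSE))
    stop_config(sprintf("unknown preset '%s' (registered: %s)",
                        as.character(name)[1],
                        paste(sort(ls(.preset_registry)), collapse = ", ")))
  get(name, envir = .preset_registry)
}

#' List registered preset names
#' @return a character vector.
#' @export
preset_names <- function() sort(ls(.preset_registry))

#' Sample a branch specification from a preset
#'
#' Draws every [branch_spec()] field uniformly from the preset's geometry
#' ranges. A pure function of `(preset, seed)`.
#'
#' @param preset a registered preset name (see [preset_names()]).
#' @param seed non-negative integer seed.
#' @return a valid [branch_spec()].
#' @export
sample_branch_spec <- function(preset, seed = 0) {
  g <- gen_preset(preset)$geometry
  with_seed(derive_seed(seed, 23L), {
    ru <- function(r) runif(1, r[1], r[2])
    branch_spec(
      n_leaves = sample(seq(g$n_leaves[1], g$n_leaves[2]), 1),
      branch_length = ru(g$branch_length),
      curvature = ru(g$curvature),
      phyllotaxis_angle = ru(g$phyllotaxis_angle),
      internode_jitter = ru(g$internode_jitter),
      leaf_scale_jitter = ru(g$leaf_scale_jitter),
      leaf_spec_template = leaf_spec(
        length = ru(g$leaf_length),
        width_ratio = ru(g$width_ratio),
        n_leaflets = sample(g$n_leaflets, 1),
        serration_depth = ru(g$serration_depth),
        lobe_depth = ru(g$lobe_depth),
        bend_angle = ru(g$bend_angle),
        twist = ru(g$twist),
        petiole_fraction = ru(g$petiole_fraction)
      )
    )
  })
}
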
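make_scene <- function(seed = 1, infected = FALSE, resolution = 64,
                       background = FALSE, defocus = 2, severity = 0.4) {
  tex <- healthy_texture(c(48, 48), seed = seed)
  dspec <- NULL
  if (infected) {
    dspec <- disease_spec("necrotic_spots", severity)
    tex <- apply_disease(tex, dspec, seed = seed)$texture
  }
  geom <- build_branch(sample_branch_spec("iter1", seed), seed)
  bg <- NULL
  if (background)
    bg <- list(geometry = build_branch(sample_branch_spec("iter1", seed + 50), seed),
               texture = healthy_texture(c(48, 48), seed = seed + 1),
               defocus_sigma = defocus)
  scene_spec(foreground = list(geometry = geom, texture = tex, disease = dspec),
             background_branch = bg, backdrop = list(seed = seed),
             resolution = c(resolution, resolution))
}

test_that("procedural backdrop is deterministic, seed-sensitive and correctly sized", {
  b1 <- procedural_backdrop(5, c(64, 64))
  expect_identical(b1, procedural_backdrop(5, c(64, 64)))
  expect_identical(dim(procedural_backdrop(1, c(256, 256))), c(256L, 256L, 3L))
  expect_true(min(b1) >= 0 && max(b1) <= 1)
  diffs <- vapply(1:20, function(s) {
    mean(abs(procedural_backdrop(s, c(32, 32)) - procedural_backdrop(s + 20, c(32, 32))))
  }, 1.0)
  expect_true(all(diffs > 0))
})

test_that("shade_leaf matches the closed-form Lambert formula (brute-force oracle, 16x16)", {
  tex <- healthy_texture(c(16, 16), seed = 8)
  light <- list(direction = c(0.3, -0.2, 0.93), intensity = 0.9, ambient = 0.2)
  out <- shade_leaf(tex, light)
  d <- light$direction / sqrt(sum(light$direction^2))
  for (i in 1:16) for (j in 1:16) {
    ndl <- max(0, sum(tex$normal[i, j, ] * d))
    for (k in 1:3) {
      expected <- min(1, max(0,
        tex$albedo[i, j, k] * (light$ambient + light$intensity * ndl) *
          tex$ambient_occlusion[i, j]))
      expect_equal(out[i, j, k], expected)
    }
  }
})

test_that("zero light gives black; flat +Z normals return the albedo; AO scales linearly", {
  tex <- flat_texture(16, 16)
  black <- shade_leaf(tex, list(direction = c(0, 0, 1), intensity = 0, ambient = 0))
  expect_true(all(black == 0))
  lamb <- shade_leaf(tex, list(direction = c(0, 0, 1), intensity = 1, ambient = 0))
  expect_equal(lamb, tex$albedo)
  half <- flat_texture(16, 16, ao = 0.5)
  out_half <- shade_leaf(half, list(direction = c(0, 0, 1), intensity = 1, ambient = 0))
  expect_equal(out_half, tex$albedo * 0.5, tolerance = 1 / 255)
})

test_that("render_scene honors resolution, label soundness and determinism", {
  img <- render_scene(make_scene(3, infected = FALSE, resolution = 256), seed = 3)
  expect_identical(dim(img$pixels), c(256L, 256L, 3L))
  expect_identical(img$label, "healthy")

  inf <- render_scene(make_scene(4, infected = TRUE), seed = 4)
  expect_identical(inf$label, "infected")
  # severity 0 disease still labels healthy
  sc <- make_scene(5, infected = FALSE)
  sc$foreground$disease <- disease_spec("chlorosis", 0)
  expect_identical(render_scene(sc, seed = 5)$label, "healthy")

  a <- render_scene(make_scene(6, TRUE, background = TRUE), seed = 6)
  b <- render_scene(make_scene(6, TRUE, background = TRUE), seed = 6)
  expect_identical(a$pixels, b$pixels)
})

test_that("zero defocus equals compositing the background branch unblurred", {
  s0 <- make_scene(7, background = TRUE, defocus = 0)
  img0 <- render_scene(s0, seed = 7)
  # manual composite with no blur anywhere
  expect_identical(gaussian_blur(img0$pixels, 0), img0$pixels)
  s1 <- make_scene(7, background = TRUE, defocus = 3)
  img1 <- render_scene(s1, seed = 7)
  expect_false(identical(img0$pixels, img1$pixels))
})

test_that("pixels are 8-bit quantized and a provenance record is attached", {
  img <- render_scene(make_scene(9), seed = 9)
  expect_true(all(abs(img$pixels * 255 - round(img$pixels * 255)) < 1e-9))
  expect_true(!is.null(img$provenance$scene_digest))
  tmp <- file.path(tempdir(), "render_test.png")
  write_labeled_image(img, tmp)
  expect_true(file.exists(tmp))
  expect_true(file.exists(sub("\\.png$", ".json", tmp)))
  back <- png::readPNG(tmp)
  expect_equal(back, img$pixels, tolerance = 1e-9)
  unlink(c(tmp, sub("\\.png$", ".json", tmp)))
})

test_that("scene validation rejects bad resolutions and degenerate scenes fail loudly", {
  expect_error(make_scene(1, resolution = 16), class = "phytosynth_validation_error")
  sc <- make_scene(2)
  sc$foreground$geometry$leaves <- list()
  expect_error(render_scene(sc, seed = 2), class = "phytosynth_render_error")
})
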
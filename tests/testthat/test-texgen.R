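test_that("healthy textures satisfy the layer invariants and are deterministic", {
  tex <- healthy_texture(c(48, 40), seed = 2)
  expect_silent(validate_texture_set(tex))
  expect_identical(tex$size, c(48L, 40L))
  nl <- sqrt(tex$normal[, , 1]^2 + tex$normal[, , 2]^2 + tex$normal[, , 3]^2)
  expect_lte(max(abs(nl - 1)), 1e-3)
  expect_identical(tex, healthy_texture(c(48, 40), seed = 2))
  expect_false(identical(tex$albedo, healthy_texture(c(48, 40), seed = 3)$albedo))
  expect_error(healthy_texture(c(8, 8)), class = "phytosynth_validation_error")
})

test_that("mean albedo hue stays inside the configured green band", {
  for (s in 1:6) {
    tex <- healthy_texture(c(64, 64), seed = s)
    m <- rbind(as.vector(tex$albedo[, , 1]), as.vector(tex$albedo[, , 2]),
               as.vector(tex$albedo[, , 3]))
    hue <- mean(grDevices::rgb2hsv(m, maxColorValue = 1)[1, ]) * 360
    expect_gte(hue, 70); expect_lte(hue, 150)
  }
})

test_that("zero venation amplitude gives a constant height layer and flat normals", {
  tex <- healthy_texture(c(32, 32), params = list(venation_amplitude = 0), seed = 1)
  expect_lte(diff(range(tex$height)), 1e-9)
  expect_lte(max(abs(tex$normal[, , 3] - 1)), 1e-9)
})

test_that("severity zero is the exact identity with an empty mask", {
  tex <- healthy_texture(c(32, 32), seed = 5)
  out <- apply_disease(tex, disease_spec("chlorosis", 0), seed = 1)
  expect_identical(out$texture, tex)
  expect_equal(out$mask$coverage, 0)
  expect_false(any(out$mask$mask))
})

test_that("target_coverage is the documented monotone severity map", {
  expect_equal(target_coverage(disease_spec("necrotic_spots", 0)), 0)
  expect_equal(target_coverage(disease_spec("necrotic_spots", 1)), 0.25)
  expect_equal(target_coverage(disease_spec("blight_blotch", 1)), 0.5)
  expect_equal(target_coverage(disease_spec("powdery_coating", 1)), 0.7)
  expect_equal(target_coverage(disease_spec("chlorosis", 1)), 0.9)
  grid <- seq(0, 1, by = 0.05)
  for (fam in c("necrotic_spots", "blight_blotch", "powdery_coating", "chlorosis")) {
    tc <- vapply(grid, function(s) target_coverage(disease_spec(fam, s)), 1.0)
    expect_true(all(diff(tc) >= 0))
  }
})

test_that("realized coverage tracks the target within 20% and is monotone in severity (pixel-count oracle)", {
  tex <- healthy_texture(c(96, 96), seed = 7)
  for (fam in c("necrotic_spots", "blight_blotch", "powdery_coating", "chlorosis")) {
    prev <- 0
    for (sev in c(0.1, 0.3, 0.5, 0.8)) {
      spec <- disease_spec(fam, sev)
      out <- apply_disease(tex, spec, seed = 11)
      # independent pixel count of the returned mask
      cov <- sum(out$mask$mask) / length(out$mask$mask)
      expect_equal(cov, out$mask$coverage)
      tgt <- target_coverage(spec)
      expect_gte(cov, 0.8 * tgt)
      expect_lte(cov, 1.2 * tgt)
      expect_gte(cov, prev)   # monotone under a fixed seed
      prev <- cov
    }
  }
})

test_that("disease alterations are local: unmasked pixels are bit-identical on every layer", {
  tex <- healthy_texture(c(64, 64), seed = 3)
  out <- apply_disease(tex, disease_spec("blight_blotch", 0.4), seed = 9)
  keep <- !out$mask$mask
  for (k in 1:3) {
    expect_identical(tex$albedo[, , k][keep], out$texture$albedo[, , k][keep])
    expect_identical(tex$normal[, , k][keep], out$texture$normal[, , k][keep])
  }
  expect_identical(tex$height[keep], out$texture$height[keep])
  expect_identical(tex$ambient_occlusion, out$texture$ambient_occlusion)
  # and something does change inside the mask
  expect_gt(sum(out$mask$mask), 0)
  expect_false(identical(tex$albedo, out$texture$albedo))
  expect_silent(validate_texture_set(out$texture))
})

test_that("powdery coating strictly raises the luminance of masked pixels", {
  tex <- healthy_texture(c(64, 64), seed = 4)
  out <- apply_disease(tex, disease_spec("powdery_coating", 0.5), seed = 2)
  m <- out$mask$mask
  lum <- function(a) 0.2126 * a[, , 1][m] + 0.7152 * a[, , 2][m] + 0.0722 * a[, , 3][m]
  expect_true(all(lum(out$texture$albedo) > lum(tex$albedo)))
})

test_that("disease application is deterministic and rejects unknown families", {
  tex <- healthy_texture(c(32, 32), seed = 1)
  a <- apply_disease(tex, disease_spec("necrotic_spots", 0.3), seed = 5)
  b <- apply_disease(tex, disease_spec("necrotic_spots", 0.3), seed = 5)
  expect_identical(a, b)
  expect_error(disease_spec("rust", 0.3), class = "phytosynth_validation_error")
  expect_error(disease_spec("chlorosis", 1.5), class = "phytosynth_validation_error")
})
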
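test_that("build_dataset produces the requested count, exact balance and split sizes", {
  dir <- file.path(tempdir(), "ds_basic")
  unlink(dir, recursive = TRUE)
  man <- build_tiny_dataset(dir, n = 20)
  expect_equal(nrow(man), 20)
  expect_equal(length(list.files(dir, pattern = "\\.png$")), 20)
  expect_equal(sum(man$label == "healthy"), 10)
  expect_equal(sum(man$label == "infected"), 10)
  expect_equal(sum(man$split == "val"), round(0.1 * 20))
  # class balance within each split never drifts past one image
  for (sp in c("train", "val")) {
    tab <- table(factor(man$label[man$split == sp],
                        levels = c("healthy", "infected")))
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  expect_true(all(file.exists(file.path(dir, man$path))))
})

test_that("n_images = 10 yields exactly one validation image", {
  dir <- file.path(tempdir(), "ds_ten")
  unlink(dir, recursive = TRUE)
  man <- build_tiny_dataset(dir, n = 10)
  expect_equal(sum(man$split == "val"), 1)
})

test_that("odd n and manifest collisions are refused", {
  dir <- file.path(tempdir(), "ds_refuse")
  unlink(dir, recursive = TRUE)
  expect_error(build_tiny_dataset(dir, n = 7), class = "phytosynth_validation_error")
  man <- build_tiny_dataset(dir, n = 4)
  expect_error(build_tiny_dataset(dir, n = 4), class = "phytosynth_io_error")
  expect_silent({man2 <- build_tiny_dataset(dir, n = 4, overwrite = TRUE)})
})

test_that("regeneration with the same (preset, seed) is byte-identical; image k is stable under n", {
  d1 <- file.path(tempdir(), "ds_rep1"); d2 <- file.path(tempdir(), "ds_rep2")
  d3 <- file.path(tempdir(), "ds_rep3")
  unlink(c(d1, d2, d3), recursive = TRUE)
  m1 <- build_tiny_dataset(d1, n = 8, seed = 42)
  m2 <- build_tiny_dataset(d2, n = 8, seed = 42)
  dig <- function(dir, man) vapply(man$path, function(p)
    digest::digest(file = file.path(dir, p)), "")
  expect_identical(unname(dig(d1, m1)), unname(dig(d2, m2)))
  expect_equal(as.data.frame(m1), as.data.frame(m2), ignore_attr = TRUE)
  expect_identical(digest::digest(file = file.path(d1, "manifest.csv")),
                   digest::digest(file = file.path(d2, "manifest.csv")))
  # first 4 images identical even when n doubles (counter-based child seeds)
  m3 <- build_tiny_dataset(d3, n = 16, seed = 42)
  expect_identical(unname(dig(d1, m1)[1:4]), unname(dig(d3, m3)[1:4]))
})

test_that("label soundness: provenance severity is positive iff labeled infected", {
  dir <- file.path(tempdir(), "ds_sound")
  unlink(dir, recursive = TRUE)
  man <- build_tiny_dataset(dir, n = 12, preset = "iter4")
  for (i in seq_len(nrow(man))) {
    prov <- read_provenance(man$path[i], dir)
    if (man$label[i] == "infected") expect_gt(prov$severity, 0)
    else expect_equal(prov$severity, 0)
  }
})

test_that("manifests round-trip through CSV", {
  dir <- file.path(tempdir(), "ds_rt")
  unlink(dir, recursive = TRUE)
  man <- build_tiny_dataset(dir, n = 6)
  p <- file.path(dir, "roundtrip.csv")
  write_manifest(man, p)
  back <- read_manifest(p)
  expect_identical(as.data.frame(back), as.data.frame(man))
})

test_that("manifest validation names offending rows and columns", {
  dir <- file.path(tempdir(), "ds_bad")
  unlink(dir, recursive = TRUE); dir.create(dir)
  # unknown label token
  writeLines(c("path,label,split,seed,preset", "a.png,sick,train,1,iter1"),
             file.path(dir, "bad_label.csv"))
  expect_error(read_manifest(file.path(dir, "bad_label.csv")),
               "row 1.*sick", class = "phytosynth_validation_error")
  # missing column
  writeLines(c("path,label,seed,preset", "a.png,healthy,1,iter1"),
             file.path(dir, "missing.csv"))
  expect_error(read_manifest(file.path(dir, "missing.csv")),
               "split", class = "phytosynth_validation_error")
  # dangling path
  writeLines(c("path,label,split,seed,preset", "gone.png,healthy,train,1,iter1"),
             file.path(dir, "dangling.csv"))
  expect_error(read_manifest(file.path(dir, "dangling.csv")),
               "row 1", class = "phytosynth_validation_error")
  # header-only manifest is fine
  writeLines("path,label,split,seed,preset", file.path(dir, "empty.csv"))
  empty <- read_manifest(file.path(dir, "empty.csv"))
  expect_equal(nrow(empty), 0)
})

test_that("iteration presets carry the documented sizes and options", {
  expect_equal(gen_preset("iter1")$n_images, 3400L)
  expect_equal(gen_preset("iter2")$n_images, 2472L)
  expect_equal(gen_preset("iter4")$n_images, 6400L)
  expect_false(gen_preset("iter1")$background_branch)
  expect_true(all(vapply(paste0("iter", 2:6),
                         function(p) gen_preset(p)$background_branch, TRUE)))
  expect_length(gen_preset("iter1")$families, 1)
  expect_length(gen_preset("iter4")$families, 4)
  expect_length(gen_preset("iter5")$families, 4)
  expect_identical(gen_preset("iter6")$schedule$type, "mixed")
  # every preset size is even so classes can balance exactly
  for (p in preset_names()) expect_equal(gen_preset(p)$n_images %% 2, 0)
})
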
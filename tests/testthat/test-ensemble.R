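make_scores <- function(s, mode = "strong", R = 32) {
  lapply(seq_along(s), function(i)
    structure(list(id = as.character(i), mode = mode, R = as.integer(R),
                   healthy_votes = as.integer(round(s[i] * R)),
                   healthy_score = s[i]),
              class = "phyto_ensemble_score"))
}

test_that("tta_score counts votes, is deterministic, and collapses under mode none", {
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  sc <- tta_score(stub_always_healthy, img, "strong", R = 32, seed = 1)
  expect_equal(sc$healthy_votes, 32L)
  expect_equal(sc$healthy_score, 1)

  # the toy green rule flips under strong hue/brightness augmentation sometimes,
  # but is always deterministic per seed
  green <- array(rep(c(0.30, 0.45, 0.25), each = 48 * 48), c(48, 48, 3))
  a <- tta_score(stub_green_rule, green, "strong", R = 16, seed = 3)
  b <- tta_score(stub_green_rule, green, "strong", R = 16, seed = 3)
  expect_identical(a, b)

  # mode none: network determinism means all or nothing
  n <- tta_score(stub_green_rule, green, "none", R = 32, seed = 5)
  expect_true(n$healthy_score %in% c(0, 1))
  expect_error(tta_score(stub_always_healthy, green, "strong", R = 0),
               class = "phytosynth_validation_error")
})

test_that("vote arithmetic: 24 healthy votes of 32 gives a 0.75 score", {
  cnt <- 0L
  flaky <- function(img) { cnt <<- cnt + 1L; if (cnt %% 4 == 0) "infected" else "healthy" }
  sc <- tta_score(flaky, array(0.5, c(32, 32, 3)), "none", R = 32, seed = 1)
  expect_equal(sc$healthy_votes, 24L)
  expect_equal(sc$healthy_score, 0.75)
})

test_that("decide applies the threshold rule with a healthy boundary", {
  rule <- decision_rule(0.8)
  expect_identical(decide(0.75, rule), "infected")
  expect_identical(decide(0.8, rule), "healthy")
  expect_identical(decide(1.0, rule), "healthy")
  expect_identical(decide(1.0, decision_rule(1)), "healthy")
  expect_error(decision_rule(0), class = "phytosynth_validation_error")
  expect_error(decision_rule(1.2), class = "phytosynth_validation_error")
})

test_that("decide is monotone: raising the threshold never flips infected to healthy", {
  s <- make_scores(seq(0, 1, by = 1 / 32))
  thresholds <- c(0.2, 0.5, 0.8, 1.0)
  prev <- vapply(s, function(x) decide(x, decision_rule(0.01)), "")
  for (t in thresholds) {
    cur <- vapply(s, function(x) decide(x, decision_rule(t)), "")
    expect_true(all(!(prev == "infected" & cur == "healthy")))
    prev <- cur
  }
})

test_that("calibration returns the smallest accuracy-maximizing grid threshold", {
  # separable: healthy at 1.0, infected at 0.5 -> smallest winning t is 17/32
  s <- make_scores(c(rep(1.0, 5), rep(0.5, 5)))
  truth <- c(rep("healthy", 5), rep("infected", 5))
  rule <- calibrate_threshold(s, truth)
  expect_equal(rule$threshold, 17 / 32)

  # matches an exhaustive brute-force grid search
  set.seed(9)
  sv <- sample(0:32, 40, replace = TRUE) / 32
  tv <- sample(c("healthy", "infected"), 40, replace = TRUE)
  tv[1:2] <- c("healthy", "infected")   # ensure both classes
  rule2 <- calibrate_threshold(make_scores(sv), tv)
  grid <- (1:32) / 32
  acc <- vapply(grid, function(t)
    mean(ifelse(sv < t, "infected", "healthy") == tv), 1.0)
  best <- max(acc)
  expect_equal(mean(ifelse(sv < rule2$threshold, "infected", "healthy") == tv), best)
  expect_equal(rule2$threshold, grid[which(acc == best)[1]])

  # identical scores: calibrated rule yields majority-class accuracy
  s3 <- make_scores(rep(0.5, 9))
  t3 <- c(rep("healthy", 6), rep("infected", 3))
  r3 <- calibrate_threshold(s3, t3)
  rep3 <- accuracy_report(s3, t3, r3)
  expect_equal(rep3$overall_accuracy, 6 / 9)

  expect_error(calibrate_threshold(s3, rep("healthy", 9)),
               class = "phytosynth_validation_error")
})

test_that("accuracy_report reproduces the published worked example and recomputes consistently", {
  # 26 of 29 images correct under the 0.8 rule -> 89.6% (to one decimal)
  s <- make_scores(c(rep(0.9, 14), rep(0.85, 1),      # 15 healthy called healthy
                     rep(0.5, 11),                    # 11 infected called infected
                     rep(0.95, 3)))                   # 3 infected missed
  truth <- c(rep("healthy", 15), rep("infected", 14))
  rep <- accuracy_report(s, truth, decision_rule(0.8))
  expect_equal(sum(rep$table$correct), 26)
  expect_equal(rep$overall_accuracy, 26 / 29)
  expect_lt(abs(rep$overall_accuracy_pct - 89.6), 0.1)   # printed to one decimal
  # overall accuracy equals the mean of per-image indicators
  expect_equal(rep$overall_accuracy, mean(rep$table$correct))

  # degenerate: nothing correct
  s0 <- make_scores(rep(1, 4))
  rep0 <- accuracy_report(s0, rep("infected", 4), decision_rule(0.8))
  expect_equal(rep0$overall_accuracy, 0)

  expect_error(accuracy_report(s0, rep("infected", 3)),
               class = "phytosynth_validation_error")
})
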
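test_that("compact network reports its exact trainable weight count", {
  f <- c(16, 32, 64)
  net <- build_network("compact", 96, filters = f, seed = 1)
  fd <- 2 * sum(f)
  manual <- (3 * 3 * 3 * f[1] + f[1]) +
    (3 * 3 * f[1] * f[2] + f[2]) +
    (3 * 3 * f[2] * f[3] + f[3]) +
    2 * fd +          # batch-norm gamma and beta
    (fd * 2 + 2)      # dense head
  expect_equal(net$weight_count, manual)
})

test_that("the full-scale architecture is reported unavailable, not approximated", {
  expect_error(build_network("paper"), "2,960,514",
               class = "phytosynth_config_error")
  expect_error(build_network("resnet"), class = "phytosynth_config_error")
  expect_error(build_network("compact", 96, filters = c(0, 16, 32)),
               class = "phytosynth_config_error")
})

test_that("initialization is deterministic per seed", {
  n1 <- build_network("compact", 96, seed = 5)
  n2 <- build_network("compact", 96, seed = 5)
  expect_identical(n1$weights, n2$weights)
  n3 <- build_network("compact", 96, seed = 6)
  expect_false(identical(n1$weights$W2, n3$weights$W2))
})

test_that("a fresh network outputs uniform probabilities and ln(2) loss on any balanced set", {
  net <- build_network("compact", 48, seed = 3)
  toy <- toy_color_set(n = 32, res = 48)
  p <- predict(net, toy$x)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(abs(p - 0.5) < 1e-12))
  yi <- match(toy$y, net$classes)
  loss <- -mean(log(p[cbind(seq_along(yi), yi)]))
  expect_equal(loss, log(2), tolerance = 1e-3)
})

test_that("the compact net learns a trivially separable color problem in 5 epochs", {
  toy <- toy_color_set(n = 200, res = 48)
  h <- hyperparameters(input_resolution = 48, epochs = 5,
                       augment_mode = "weak", seed = 1)
  res <- train(h, data = toy)
  expect_gte(tail(res$trace$val_acc, 1), 0.95)
  expect_equal(nrow(res$trace), 5)
  p <- predict(res$classifier, toy$x[, , , 1:8])
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("the mixed schedule switches modes at ceiling(switch_fraction * epochs)", {
  toy <- toy_color_set(n = 48, res = 48)
  h <- hyperparameters(input_resolution = 48, epochs = 4,
                       schedule = list(type = "mixed", first = "medium",
                                       second = "strong", switch_fraction = 0.5),
                       seed = 2)
  expect_identical(vapply(1:4, function(e) mode_for_epoch(h, e), ""),
                   c("medium", "medium", "strong", "strong"))
  res <- train(h, data = toy)
  expect_identical(res$trace$mode, c("medium", "medium", "strong", "strong"))
})

test_that("training validates its inputs and the loss stays finite", {
  toy <- toy_color_set(n = 40, res = 48)
  single <- toy
  single$y[] <- "healthy"
  h <- hyperparameters(input_resolution = 48, epochs = 1, seed = 1)
  expect_error(train(h, data = single), class = "phytosynth_validation_error")
  expect_error(hyperparameters(batch_size = 0), class = "phytosynth_validation_error")
  expect_error(hyperparameters(learning_rate = 0), class = "phytosynth_validation_error")
  expect_error(hyperparameters(schedule = list(type = "mixed", first = "weak",
                                               second = "strong",
                                               switch_fraction = 1)),
               class = "phytosynth_validation_error")
})

test_that("error_rate is misclassified/total and accuracy its exact complement", {
  toy <- toy_color_set(n = 60, res = 48)
  # constant predictor: accuracy is exactly the class share
  net <- build_network("compact", 48, seed = 1)
  net$weights$bd <- c(10, 0)   # always healthy
  er <- error_rate(net, list(x = toy$x, y = toy$y))
  expect_equal(er, 0.5)
  expect_identical(accuracy(net, list(x = toy$x, y = toy$y)), 1 - er)
  expect_error(error_rate(net, list(x = NULL, y = character(0))),
               class = "phytosynth_validation_error")
})

test_that("a uniformly random predictor sits at the 50% binary baseline in expectation", {
  set.seed(7)
  truth <- rep(c("healthy", "infected"), 500)
  acc <- vapply(1:50, function(i) {
    mean(sample(c("healthy", "infected"), 1000, replace = TRUE) == truth)
  }, 1.0)
  expect_equal(mean(acc), 0.5, tolerance = 0.02)
})
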
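# Shared fixtures and independent geometric oracles used across the suite.

# shoelace formula: polygon area from the vertex list
shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

# brute-force simplicity check: no two non-adjacent edges intersect
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_intersect(p[i, ], p[i %% n + 1, ],
                             p[j, ], p[j %% n + 1, ])) return(FALSE)
    }
  }
  TRUE
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
    j <- i
  }
  inside
}

# a small flat texture whose shading can be computed in closed form
flat_texture <- function(H = 16, W = 16, albedo_val = c(0.3, 0.6, 0.2),
                         ao = 1) {
  alb <- array(rep(albedo_val, each = H * W), c(H, W, 3))
  nrm <- array(0, c(H, W, 3)); nrm[, , 3] <- 1
  structure(list(albedo = alb, normal = nrm,
                 ambient_occlusion = matrix(ao, H, W),
                 height = matrix(0.5, H, W), size = c(H, W)),
            class = "phyto_texture")
}

# trivially separable toy dataset: uniform green vs uniform brown images
toy_color_set <- function(n = 200, res = 48, noise = 0.03, val_every = 5) {
  x <- array(0, c(res, res, 3, n)); y <- character(n)
  set.seed(1234)
  for (i in seq_len(n)) {
    healthy <- i %% 2 == 1
    col <- if (healthy) c(0.2, 0.6, 0.2) else c(0.45, 0.3, 0.1)
    x[, , , i] <- pmin(pmax(
      array(rep(col, each = res * res), c(res, res, 3)) +
        array(rnorm(res * res * 3, 0, noise), c(res, res, 3)), 0), 1)
    y[i] <- if (healthy) "healthy" else "infected"
  }
  split <- rep("train", n)
  split[seq(1, n, by = val_every)] <- "val"
  list(x = x, y = y, split = split)
}

# stub classifiers for ensemble tests
stub_always_healthy <- function(img) "healthy"

# classifies by mean green-minus-red (matches the toy color set)
stub_green_rule <- function(img) {
  if (mean(img[, , 2]) > mean(img[, , 1])) "healthy" else "infected"
}

build_tiny_dataset <- function(dir, n = 20, preset = "iter1", seed = 1,
                               resolution = 48, ...) {
  build_dataset(preset, seed = seed, outdir = dir, n = n,
                resolution = resolution, ...)
}
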
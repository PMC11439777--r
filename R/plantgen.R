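# Procedural generation of tomato branch and compound-leaf geometry.
#
# The generator is a fixed node pipeline: midrib placement along a circular
# branch arc -> leaf placement by phyllotaxis -> leaf outline as a base
# ellipse deformed by lobe and serration harmonics -> ear-clipping
# triangulation. Every step is a pure function of (spec, seed).

#' Leaf shape specification
#'
#' Parameters of the compound-leaf outline model. The blade is a base
#' ellipse whose radius is modulated by a lobe harmonic (one lobe pair per
#' leaflet) and a higher-frequency serration harmonic. Width is
#' `width_ratio * length`, so scaling `length` scales the whole outline
#' linearly.
#'
#' @param length blade length in scene units (> 0).
#' @param width_ratio blade width as a fraction of length, in (0, 1.5].
#' @param n_leaflets odd number of leaflets (>= 1); sets the lobe harmonic.
#' @param serration_depth serration amplitude in `[0, 1]`.
#' @param lobe_depth lobe amplitude in `[0, 1]`.
#' @param bend_angle out-of-plane curl of the blade, degrees in `[-90, 90]`.
#' @param twist rotation of the blade about its midrib, degrees.
#' @param petiole_fraction fraction of `length` taken by the bare petiole,
#'   in `[0, 0.5]`.
#' @return a `phyto_leaf_spec` object.
#' @export
leaf_spec <- function(length = 0.35, width_ratio = 0.45, n_leaflets = 5,
                      serration_depth = 0.4, lobe_depth = 0.5,
                      bend_angle = 15, twist = 0, petiole_fraction = 0.1) {
  spec <- structure(list(
    length = length, width_ratio = width_ratio, n_leaflets = n_leaflets,
    serration_depth = serration_depth, lobe_depth = lobe_depth,
    bend_angle = bend_angle, twist = twist,
    petiole_fraction = petiole_fraction
  ), class = "phyto_leaf_spec")
  validate_leaf_spec(spec)
  spec
}

validate_leaf_spec <- function(spec) {
  check_range(spec$length, "length", 0, Inf, lo_open = TRUE)
  check_range(spec$width_ratio, "width_ratio", 0, 1.5, lo_open = TRUE)
  check_range(spec$n_leaflets, "n_leaflets", 1, Inf, integer = TRUE)
  if (spec$n_leaflets %% 2 == 0)
    stop_validation(sprintf("field 'n_leaflets' = %d must be odd", spec$n_leaflets))
  check_range(spec$serration_depth, "serration_depth", 0, 1)
  check_range(spec$lobe_depth, "lobe_depth", 0, 1)
  check_range(spec$bend_angle, "bend_angle", -90, 90)
  check_range(spec$twist, "twist", -360, 360)
  check_range(spec$petiole_fraction, "petiole_fraction", 0, 0.5)
  invisible(spec)
}

#' Branch specification
#'
#' @param n_leaves number of leaves on the branch (>= 1).
#' @param branch_length arc length of the branch centerline (> 0, scene units).
#' @param curvature signed curvature of the centerline arc (1/scene-unit);
#'   0 gives a straight branch.
#' @param phyllotaxis_angle angular offset between successive leaves, degrees.
#' @param internode_jitter random spread of leaf positions along the branch,
#'   in `[0, 1]`.
#' @param leaf_scale_jitter random spread of per-leaf scale, in `[0, 1]`.
#' @param leaf_spec_template [leaf_spec()] shared by all leaves on the branch.
#' @return a `phyto_branch_spec` object.
#' @export
branch_spec <- function(n_leaves = 6, branch_length = 1, curvature = 0.6,
                        phyllotaxis_angle = 137.5, internode_jitter = 0.25,
                        leaf_scale_jitter = 0.25,
                        leaf_spec_template = leaf_spec()) {
  spec <- structure(list(
    n_leaves = n_leaves, branch_length = branch_length,
    curvature = curvature, phyllotaxis_angle = phyllotaxis_angle,
    internode_jitter = internode_jitter,
    leaf_scale_jitter = leaf_scale_jitter,
    leaf_spec_template = leaf_spec_template
  ), class = "phyto_branch_spec")
  validate_branch_spec(spec)
  spec
}

validate_branch_spec <- function(spec) {
  check_range(spec$n_leaves, "n_leaves", 1, Inf, integer = TRUE)
  check_range(spec$branch_length, "branch_length", 0, Inf, lo_open = TRUE)
  check_range(spec$curvature, "curvature", -Inf, Inf)
  check_range(spec$phyllotaxis_angle, "phyllotaxis_angle", -Inf, Inf)
  check_range(spec$internode_jitter, "internode_jitter", 0, 1)
  check_range(spec$leaf_scale_jitter, "leaf_scale_jitter", 0, 1)
  validate_leaf_spec(spec$leaf_spec_template)
  invisible(spec)
}

#' Build the geometry of a single compound leaf
#'
#' The outline is sampled in polar form around the blade center, which makes
#' it star-shaped and therefore always a simple closed polygon (deformation
#' amplitudes are bounded so the radius stays positive). With
#' `bend_angle = 0` and `twist = 0` the 3D vertices are exactly coplanar.
#'
#' @param spec a [leaf_spec()].
#' @param seed integer seed (controls the harmonic phases).
#' @param n_vertices outline resolution; default 96.
#' @return a `phyto_leaf` with fields `outline` (n x 2 flat polygon),
#'   `vertices` (n x 3 after bend/twist), `triangles` (1-based index
#'   matrix), `uv` (n x 2 in the unit square) and `frame`.
#' @export
build_leaf <- function(spec, seed = 0, n_vertices = 96) {
  validate_leaf_spec(spec)
  check_range(n_vertices, "n_vertices", 8, Inf, integer = TRUE)
  phases <- with_seed(derive_seed(seed, 7L), runif(2, 0, 2 * pi))

  p <- spec$petiole_fraction * spec$length
  a <- (spec$length - p) / 2                    # semi-major (midrib)
  b <- spec$width_ratio * spec$length / 2       # semi-minor (half width)
  cx <- p + a
  t <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r0 <- a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
  m_lobe <- spec$n_leaflets
  m_serr <- max(8L, 3L * spec$n_leaflets)
  r <- r0 * (1 + 0.30 * spec$lobe_depth * cos(m_lobe * t + phases[1])
               + 0.12 * spec$serration_depth * cos(m_serr * t + phases[2]))
  x <- cx + r * cos(t)
  y <- r * sin(t)
  outline <- cbind(x = x, y = y)

  # progressive curl about the leaf's y axis, then twist about the midrib
  u <- pmax(x, 0) / spec$length
  beta <- spec$bend_angle * pi / 180 * u
  tau <- spec$twist * pi / 180 * u
  x3 <- x * cos(beta)
  z3 <- -x * sin(beta)
  y3 <- y * cos(tau) - z3 * sin(tau)
  z3 <- y * sin(tau) + z3 * cos(tau)
  vertices <- cbind(x3, y3, z3)

  uv <- cbind(
    u = (x - min(x)) / max(diff(range(x)), .Machine$double.eps),
    v = (y - min(y)) / max(diff(range(y)), .Machine$double.eps)
  )

  structure(list(
    outline = outline,
    vertices = vertices,
    triangles = ear_clip_cpp(outline),
    uv = uv,
    frame = list(origin = c(0, 0, 0), rotation = diag(3), scale = 1),
    spec = spec
  ), class = "phyto_leaf")
}

.normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

#' Build a branch: centerline arc plus placed leaves
#'
#' The centerline is a circular arc of the requested length and curvature in
#' the xy-plane (straight when curvature is 0). Leaves are placed at jittered
#' internode positions and oriented by a phyllotactic rotation about the
#' local tangent, with a fixed outward/forward blend so the blade never
#' degenerates to an edge-on sliver.
#'
#' @param spec a [branch_spec()].
#' @param seed integer seed.
#' @param n_vertices outline resolution passed to [build_leaf()].
#' @return a `phyto_branch` with fields `centerline` (polyline, one row per
#'   sample), `leaves` (list of `phyto_leaf` with frames set), `spec`, `seed`.
#' @export
build_branch <- function(spec, seed = 0, n_vertices = 96) {
  validate_branch_spec(spec)
  L <- spec$branch_length
  kap <- spec$curvature
  J <- 32L
  s <- L * (0:J) / J
  if (abs(kap) < 1e-12) {
    centerline <- cbind(s, 0, 0)
    pos_at <- function(ss) c(ss, 0, 0)
    tan_at <- function(ss) c(1, 0, 0)
  } else {
    th <- kap * s
    centerline <- cbind(sin(th) / kap, (1 - cos(th)) / kap, 0)
    pos_at <- function(ss) {
      tt <- kap * ss
      c(sin(tt) / kap, (1 - cos(tt)) / kap, 0)
    }
    tan_at <- function(ss) c(cos(kap * ss), sin(kap * ss), 0)
  }

  n <- spec$n_leaves
  base_u <- if (n == 1) 0.6 else seq(0.15, 0.95, length.out = n)
  du <- if (n == 1) 0.4 else (0.95 - 0.15) / (n - 1)

  leaves <- with_seed(derive_seed(seed, 11L), {
    u <- sort(pmin(pmax(base_u + spec$internode_jitter * (runif(n) - 0.5) * du,
                        0.03), 0.98))
    psi0 <- runif(1, 0, 2 * pi)
    lapply(seq_len(n), function(i) {
      leaf <- build_leaf(spec$leaf_spec_template,
                         seed = derive_seed(seed, 1000L + i),
                         n_vertices = n_vertices)
      tng <- tan_at(u[i] * L)
      n0 <- .normalize3(c(tng[2], -tng[1], 0))   # horizontal normal
      b0 <- .normalize3(c(
        tng[2] * n0[3] - tng[3] * n0[2],
        tng[3] * n0[1] - tng[1] * n0[3],
        tng[1] * n0[2] - tng[2] * n0[1]
      ))
      psi <- psi0 + (i - 1) * spec$phyllotaxis_angle * pi / 180 +
        spec$internode_jitter * (runif(1) - 0.5)
      rad <- cos(psi) * n0 + sin(psi) * b0
      # flatten the radial direction toward the viewing plane so blades face
      # the camera like photographed canopy leaves instead of edge-on slivers
      rad <- .normalize3(c(rad[1], rad[2], 0.35 * rad[3]))
      m_hat <- .normalize3(0.75 * rad + 0.45 * tng)
      up <- .normalize3(c(runif(2, -0.35, 0.35), 1))
      y_hat <- .normalize3(c(
        up[2] * m_hat[3] - up[3] * m_hat[2],
        up[3] * m_hat[1] - up[1] * m_hat[3],
        up[1] * m_hat[2] - up[2] * m_hat[1]
      ))
      z_hat <- .normalize3(c(
        m_hat[2] * y_hat[3] - m_hat[3] * y_hat[2],
        m_hat[3] * y_hat[1] - m_hat[1] * y_hat[3],
        m_hat[1] * y_hat[2] - m_hat[2] * y_hat[1]
      ))
      leaf$frame <- list(
        origin = pos_at(u[i] * L),
        rotation = cbind(m_hat, y_hat, z_hat),
        scale = 1 + spec$leaf_scale_jitter * (runif(1) - 0.5)
      )
      leaf
    })
  })

  structure(list(centerline = centerline, leaves = leaves,
                 spec = spec, seed = seed),
            class = "phyto_branch")
}

#' World-space 3D vertices of a placed leaf
#'
#' @param leaf a `phyto_leaf` whose frame has been set by [build_branch()].
#' @return an n x 3 matrix.
#' @export
leaf_world_vertices <- function(leaf) {
  fr <- leaf$frame
  sweep(leaf$vertices %*% t(fr$rotation) * fr$scale, 2, fr$origin, "+")
}
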
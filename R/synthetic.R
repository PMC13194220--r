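# Synthetic anatomy generator: radius-like bones and T-shaped volar plates
# with analytic ground truth, so every pipeline stage is testable without
# clinical data.
#
# The bone is a loft of elliptical cross-sections along Z with
#  * a distal flare peaking at z_flare,
#  * a volar-rim ledge over |y| <= y_band whose crest is the exact
#    quadratic x = x0 - c2 y^2 at the single ring z = z_ws (the watershed
#    ground truth); the flare peaks 6 mm above the rim so that slice
#    maxima outside the band fall far from the rim in Z and are removed by
#    the watershed Z-band filter,
#  * a styloid apex (the most distal vertex, on +Y),
#  * two planar osteotomy cuts splitting the mesh into a closed proximal
#    and a closed distal fragment, each cut capped by a coarse triangle
#    fan (the "largest mesh triangles" signature the plane detector keys
#    on).

#' Synthetic bone specification
#'
#' @param length bone length in mm.
#' @param shaft_radius volar-dorsal shaft half-width in mm.
#' @param distal_flare scale factor of the distal flare (> 1).
#' @param styloid_height apex height above the last ring (mm).
#' @param ridge_height height of the volar rim above the flare (mm).
#' @param cut_z_levels the two osteotomy cut heights (proximal, distal), mm.
#' @param cut_tilt_deg tilt of the cut planes about the Y axis (degrees).
#' @param seed integer seed driving the vertex jitter.
#' @param noise_sd vertex jitter standard deviation (mm); cut faces are
#'   never jittered so the planes stay exactly planar.
#' @param ring_mm ring spacing along the shaft (mm); controls resolution.
#' @param width_ratio ellipse aspect: Y half-width / X half-width.
#' @return A `bone_spec` list.
#' @export
bone_spec <- function(length = 140, shaft_radius = 10, distal_flare = 1.3,
                      styloid_height = 5, ridge_height = 2.5,
                      cut_z_levels = NULL, cut_tilt_deg = 5, seed = 1,
                      noise_sd = 0.05, ring_mm = 2.5, width_ratio = 1.3) {
  half <- length / 2
  z_ws <- half - 18
  if (is.null(cut_z_levels)) cut_z_levels <- z_ws - c(7, 5)
  spec <- list(length = length, shaft_radius = shaft_radius,
               distal_flare = distal_flare, styloid_height = styloid_height,
               ridge_height = ridge_height, cut_z_levels = sort(cut_z_levels),
               cut_tilt_deg = cut_tilt_deg, seed = as.integer(seed),
               noise_sd = noise_sd, ring_mm = ring_mm,
               width_ratio = width_ratio)
  stopifnot(length > 40, shaft_radius > 3, distal_flare > 1,
            ridge_height > 0, styloid_height > 0)
  if (spec$cut_z_levels[1] >= spec$cut_z_levels[2])
    stop("cut_z_levels must be two distinct heights")
  if (spec$cut_z_levels[2] > z_ws - 4.2 || spec$cut_z_levels[1] < -half + 20)
    stop("generation error: cuts must lie in the shaft below the volar rim")
  class(spec) <- "bone_spec"
  spec
}

#' Synthetic plate specification
#'
#' @param length plate length (mm).
#' @param head_width width of the distal T-head (mm).
#' @param shaft_width width of the shaft (mm).
#' @param thickness plate thickness (mm).
#' @param curvature_radius transverse bending radius (mm); `Inf` for a
#'   flat plate.
#' @param head_length length of the head segment (mm).
#' @param tip_length length of the tapered proximal tip (mm).
#' @param grid_mm surface grid spacing (mm); controls resolution (the
#'   penetration term counts vertices, so density matters).
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(length = 55, head_width = 20, shaft_width = 9,
                       thickness = 2.4, curvature_radius = 17,
                       head_length = 14, tip_length = 6, grid_mm = 1.4) {
  stopifnot(length > 0, head_width > shaft_width, shaft_width > 0,
            thickness > 0, curvature_radius > 0, head_length < length,
            tip_length < length - head_length)
  structure(list(length = length, head_width = head_width,
                 shaft_width = shaft_width, thickness = thickness,
                 curvature_radius = curvature_radius,
                 head_length = head_length, tip_length = tip_length,
                 grid_mm = grid_mm),
            class = "plate_spec")
}

# --- internal building blocks -------------------------------------------

.loft_faces <- function(iA, iB) {
  M <- length(iA)
  j1 <- c(2:M, 1L)
  rbind(cbind(iA, iA[j1], iB[j1]), cbind(iA, iB[j1], iB))
}

.fan_cap <- function(ring, center, up = TRUE) {
  M <- length(ring)
  j1 <- c(2:M, 1L)
  f <- cbind(center, ring, ring[j1])
  if (!up) f <- f[, c(1L, 3L, 2L)]
  f
}

.big_fan_cap <- function(ring, center, up = TRUE, step = 6L) {
  M <- length(ring)
  S <- seq(1L, M, by = step)
  f <- NULL
  for (k in seq_along(S)) {
    s0 <- S[k]
    s1 <- if (k < length(S)) S[k + 1L] else S[1L]
    f <- rbind(f, c(center, ring[s0], ring[s1]))
    jj <- if (s0 == M) 1L else s0 + 1L
    while (jj != s1) {
      jn <- if (jj == M) 1L else jj + 1L
      f <- rbind(f, c(ring[s0], ring[jj], ring[jn]))
      jj <- jn
    }
  }
  if (!up) f <- f[, c(1L, 3L, 2L)]
  f
}

.reduce_cap <- function(big, small, apex, up = TRUE) {
  # big ring (2n) -> small ring (n) -> apex; orientation flipped via `up`
  n <- length(small)
  f <- NULL
  for (m in seq_len(n)) {
    j <- 2L * (m - 1L) + 1L
    j1 <- if (j >= 2L * n) 1L else j + 1L
    j2 <- if (j1 >= 2L * n) 1L else j1 + 1L
    m1 <- if (m == n) 1L else m + 1L
    f <- rbind(f,
               c(big[j], big[j1], small[m]),
               c(big[j1], big[j2], small[m]),
               c(big[j2], small[m1], small[m]))
  }
  f <- rbind(f, .fan_cap(small, apex, up = TRUE))
  if (!up) f <- f[, c(1L, 3L, 2L)]
  f
}

# ring shrink schedule of the dome caps (fractions of the base ring and of
# the base-to-apex height)
.dome_scales <- c(0.93, 0.84, 0.73, 0.6, 0.45)
.dome_ts <- c(0.14, 0.28, 0.43, 0.58, 0.73)

.ensure_outward <- function(mesh, inside_pt) {
  w <- cpp_winding_number(rbind(inside_pt), mesh$vertices, mesh$faces)
  if (w < -0.5) return(tri_mesh(mesh$vertices, mesh$faces[, c(1L, 3L, 2L)]))
  if (w < 0.5) stop("generation error: inconsistent surface orientation")
  mesh
}

#' Generate a synthetic radius-like bone
#'
#' @param spec a [bone_spec()].
#' @return List with `mesh` (a watertight two-fragment [tri_mesh()]) and
#'   `truth`: ground-truth `planes` (distal/proximal [plane3()]), `crest`
#'   (sampled analytic watershed curve), `crest_fun` (its coefficients),
#'   `styloid` apex and the derived geometry parameters.
#' @export
make_bone <- function(spec) {
  stopifnot(inherits(spec, "bone_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  half <- spec$length / 2
  z_ws <- half - 18
  z_flare <- z_ws + 4
  z_top <- half - 4
  cut1 <- spec$cut_z_levels[1]
  cut2 <- spec$cut_z_levels[2]
  tant <- tan(spec$cut_tilt_deg * pi / 180)
  a_max <- spec$shaft_radius * spec$distal_flare
  b_fun <- function(z) spec$width_ratio * a_fun(z)
  a_fun <- function(z) {
    # flare peak just above the rim: wide enough at rim level that every
    # slice maximum outside the rim band comes from the flare (whose Z
    # offset the watershed band filter removes), while the rim ring stays
    # wide enough that the rim is a low ridge rather than a tall fin
    spec$shaft_radius * (1 + (spec$distal_flare - 1) *
                           exp(-((z - z_flare) / 6)^2))
  }
  b_max <- spec$width_ratio * a_max
  yb <- 0.71 * b_max
  x0 <- a_max + spec$ridge_height
  c2 <- (x0 - (a_max * sqrt(1 - (yb / b_max)^2) + 0.5)) / yb^2
  if (c2 <= 0) stop("generation error: rim would not dominate the flare")
  P_fun <- function(y) x0 - c2 * y^2

  # Shared absolute-Y ladder on the volar side, mirrored exactly onto the
  # dorsal side.  Every ring samples the same Y positions (snapped to its
  # own width), so within any watershed Y-slice the widest ring -- the
  # flare -- always owns the most volar vertex outside the rim band, and
  # its Z offset gets it removed by the band filter.  The mirror keeps the
  # rings mass-balanced in X, which keeps the standardized frame's
  # in-plane rotation well under a degree.  Clamped duplicates are welded
  # away after assembly.
  n_in <- 31L
  y_in <- seq(-yb, yb, length.out = n_in)
  y_out <- yb + seq(0.9, 5.9, by = 1)
  y_volar <- c(-rev(y_out), y_in, y_out)
  n_volar <- length(y_volar)
  M <- 2L * n_volar + 10L

  ring_pts <- function(z, feature = FALSE, tilt = FALSE) {
    a <- a_fun(z); b <- b_fun(z)
    ell_x <- function(y) a * sqrt(pmax(0, 1 - (y / b)^2))
    # snap out-of-width ladder points to the widest admissible ladder
    # value: every ladder vertex lies on a shared absolute Y, where the
    # flare ring dominates any narrower ring; two per-ring shoulder points
    # and a side apex close the gap between the ladder's reach and the
    # ring's lateral extreme without large flat side strips
    y_ok <- max(y_volar[y_volar <= 0.98 * b])
    yg <- .clamp(y_volar, -y_ok, y_ok)
    ell_v <- ell_x(yg)
    xv <- ell_v
    if (feature) {
      # the rim is the quadratic ledge wherever it clears the ring's own
      # ellipse; laterally it dies where the quadratic meets the bone
      # surface, so there is no cliff, and slice maxima in the marginal
      # zone are either flare points (removed by the Z filter) or points
      # exactly on the analytic crest
      xv <- pmax(P_fun(yg), xv + 0.05)
    }
    y_ap <- 0.997 * b
    ys <- y_ok + (y_ap - y_ok) * c(1, 2) / 3
    xs <- ell_x(ys)
    pts <- rbind(cbind(xv, yg),                       # volar, y ascending
                 cbind(xs, ys),                       # volar shoulder up
                 c(0, y_ap),                          # +Y side apex
                 cbind(-rev(xs), rev(ys)),            # dorsal shoulder down
                 cbind(-rev(ell_v), rev(yg)),         # dorsal, y descending
                 cbind(-xs, -ys),                     # dorsal shoulder down
                 c(0, -y_ap),                         # -Y side apex
                 cbind(rev(xs), -rev(ys)))            # volar shoulder up
    zc <- if (tilt) z + tant * pts[, 1] else rep(z, M)
    cbind(pts, zc)
  }

  verts <- NULL
  frozen <- logical(0)
  add <- function(p, keep_exact = FALSE) {
    i0 <- nrow(verts %||% matrix(0, 0, 3))
    verts <<- rbind(verts, p)
    frozen <<- c(frozen, rep(keep_exact, nrow(p)))
    i0 + seq_len(nrow(p))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  faces <- NULL

  build_tube <- function(ring_idx_list) {
    for (i in seq_len(length(ring_idx_list) - 1L))
      faces <<- rbind(faces, .loft_faces(ring_idx_list[[i]],
                                         ring_idx_list[[i + 1L]]))
  }

  # ---- proximal fragment ----
  zs_prox <- seq(-half, cut1 - spec$ring_mm, by = spec$ring_mm)
  rings_p <- lapply(zs_prox, function(z) add(ring_pts(z)))
  rings_p <- c(rings_p, list(add(ring_pts(cut1, tilt = TRUE),
                                 keep_exact = TRUE)))
  build_tube(rings_p)
  # dome caps: gradual ring shrink keeps every cap triangle well below the
  # oversized-face threshold used by the plane detector
  dome_cap <- function(i_base, base_pts, apex_xy, apex_z, up) {
    base_z <- mean(base_pts[, 3])
    prev <- i_base
    fc <- NULL
    for (k in seq_along(.dome_scales)) {
      sfac <- .dome_scales[k]
      xy <- sweep(sfac * sweep(base_pts[, 1:2, drop = FALSE], 2, apex_xy),
                  2, apex_xy, "+")
      idx <- add(cbind(xy, base_z + .dome_ts[k] * (apex_z - base_z)))
      fc <- rbind(fc, if (up) .loft_faces(prev, idx) else
        .loft_faces(idx, prev))
      prev <- idx
    }
    hxy <- sweep(0.26 * sweep(base_pts[seq(1L, M, by = 2L), 1:2, drop = FALSE],
                              2, apex_xy),
                 2, apex_xy, "+")
    i_half <- add(cbind(hxy, base_z + 0.88 * (apex_z - base_z)))
    i_apex <- add(rbind(c(apex_xy, apex_z)))
    rbind(fc, .reduce_cap(prev, i_half, i_apex, up = up))
  }
  r1 <- ring_pts(-half)
  faces <- rbind(faces, dome_cap(rings_p[[1L]], r1, c(0, 0), -half - 3.4,
                                 up = FALSE))
  # cut cap (top of proximal fragment, outward +Z)
  i_c1 <- add(rbind(c(0, 0, cut1)), keep_exact = TRUE)
  faces <- rbind(faces, .big_fan_cap(rings_p[[length(rings_p)]], i_c1,
                                     up = TRUE))
  n_prox_faces <- nrow(faces)

  # ---- distal fragment ----
  # regular ring ladder with the single crest ring inserted at z_ws: the
  # only rim-level vertices that can win a watershed slice lie exactly on
  # the analytic crest (plain rings lose to the crest in-band and to the
  # flare, which the Z filter removes, out of band)
  # no ring within 4 mm of the crest: the crest ring is the only source
  # of rim-level vertices inside the watershed Z band
  zs_d <- seq(cut2 + 2.5, z_top, by = 2.5)
  zs_d <- zs_d[abs(zs_d - z_ws) > 4]
  rings_d <- list(add(ring_pts(cut2, tilt = TRUE), keep_exact = TRUE))
  crest_done <- FALSE
  for (z in zs_d) {
    if (!crest_done && z > z_ws) {
      rings_d <- c(rings_d, list(add(ring_pts(z_ws, feature = TRUE))))
      crest_done <- TRUE
    }
    rings_d <- c(rings_d, list(add(ring_pts(z))))
  }
  if (!crest_done)
    rings_d <- c(rings_d, list(add(ring_pts(z_ws, feature = TRUE))))
  build_tube(rings_d)
  # cut cap (bottom of distal fragment, outward -Z)
  i_c2 <- add(rbind(c(0, 0, cut2)), keep_exact = TRUE)
  faces <- rbind(faces, .big_fan_cap(rings_d[[1L]], i_c2, up = FALSE))
  # styloid cap: dome towards an off-axis (+Y) apex, the most distal vertex
  rt <- ring_pts(z_top)
  sty_y <- 1.15 * b_fun(z_top)  # lateral protrusion of the styloid
  faces <- rbind(faces, dome_cap(rings_d[[length(rings_d)]], rt,
                                 c(0, sty_y), z_top + spec$styloid_height,
                                 up = TRUE))

  # ---- weld, jitter, orientation, assembly ----
  # weld first (the clamped Y-ladder piles duplicate points at the ring
  # edges), then jitter, so noise cannot split welded vertices
  tol <- 1e-6
  key <- paste(round(verts[, 1] / tol), round(verts[, 2] / tol),
               round(verts[, 3] / tol))
  firsts <- !duplicated(key)
  map <- match(key, key[firsts])
  verts <- verts[firsts, , drop = FALSE]
  frozen <- as.logical(tapply(frozen, map, any))
  frag <- rep(1:2, c(n_prox_faces, nrow(faces) - n_prox_faces))
  faces <- matrix(map[faces], ncol = 3L)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]
  frag <- frag[!degen]
  if (spec$noise_sd > 0) {
    jit <- matrix(rnorm(3L * nrow(verts), sd = spec$noise_sd), ncol = 3L)
    jit[frozen, ] <- 0
    verts <- verts + jit
  }
  areas_ok <- triangle_areas(tri_mesh(verts, faces)) > 1e-12
  faces <- faces[areas_ok, , drop = FALSE]
  frag <- frag[areas_ok]
  prox <- tri_mesh(verts, faces[frag == 1L, , drop = FALSE])
  dist <- tri_mesh(verts, faces[frag == 2L, , drop = FALSE])
  prox <- .ensure_outward(prox, c(0, 0, (-half + cut1) / 2))
  dist <- .ensure_outward(dist, c(0, 0, (cut2 + z_top) / 2))
  mesh <- tri_mesh(verts, rbind(prox$faces, dist$faces))

  n_cut <- .unit(c(-tant, 0, 1))
  truth <- list(
    planes = list(distal = plane3(c(0, 0, cut2), n_cut),
                  proximal = plane3(c(0, 0, cut1), n_cut)),
    crest = cbind(x = P_fun(y_in), y = y_in, z = z_ws),
    crest_fun = list(x0 = x0, c2 = c2, z_ws = z_ws, y_band = yb),
    styloid = c(0, sty_y, z_top + spec$styloid_height),
    z_flare = z_flare,
    a_max = a_max, b_max = b_max,
    noise_sd = spec$noise_sd,
    spec = spec)
  list(mesh = mesh, truth = truth)
}

#' Generate a synthetic T-shaped volar plate
#'
#' A curved slab: T-head distally, shaft tapering to a single proximal tip
#' edge.  The transverse curvature (radius `curvature_radius`) makes the
#' contact face concave; ground truth records the designed corner points.
#'
#' @param spec a [plate_spec()].
#' @return List with `mesh` (watertight [tri_mesh()], centered on its
#'   vertex centroid) and `truth` (corner coordinates in the same frame).
#' @export
make_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  zt <- spec$length / 2
  zb <- -zt
  z_head <- zt - spec$head_length
  z_taper <- zb + spec$tip_length
  width_at <- function(z) {
    ifelse(z >= z_head - 1e-9, spec$head_width,
           ifelse(z >= z_taper, spec$shaft_width,
                  spec$shaft_width * (z - zb) / spec$tip_length))
  }
  zs <- sort(unique(c(seq(zb, z_head, by = spec$grid_mm), z_head,
                      seq(z_head, zt, by = spec$grid_mm), zt)))
  nc <- max(5L, 2L * floor(spec$head_width / (2 * spec$grid_mm)) + 1L)
  u <- seq(-0.5, 0.5, length.out = nc)
  nr <- length(zs)
  xf <- function(y) -y^2 / (2 * spec$curvature_radius)

  idx <- function(r, c, back) (back * nr + (r - 1L)) * nc + c
  V <- matrix(0, 2L * nr * nc, 3L)
  for (r in seq_len(nr)) {
    y <- u * width_at(zs[r])
    V[idx(r, seq_len(nc), 0L), ] <- cbind(xf(y), y, zs[r])
    V[idx(r, seq_len(nc), 1L), ] <- cbind(xf(y) + spec$thickness, y, zs[r])
  }
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  F <- NULL
  for (r in seq_len(nr - 1L)) for (cc in seq_len(nc - 1L)) {
    F <- rbind(F,
               # front sheet (outward -X)
               quad(idx(r, cc, 0L), idx(r + 1L, cc, 0L),
                    idx(r + 1L, cc + 1L, 0L), idx(r, cc + 1L, 0L)),
               # back sheet (outward +X)
               quad(idx(r, cc, 1L), idx(r, cc + 1L, 1L),
                    idx(r + 1L, cc + 1L, 1L), idx(r + 1L, cc, 1L)))
  }
  for (r in seq_len(nr - 1L)) {
    F <- rbind(F,
               # side walls
               quad(idx(r, 1L, 0L), idx(r, 1L, 1L),
                    idx(r + 1L, 1L, 1L), idx(r + 1L, 1L, 0L)),
               quad(idx(r, nc, 0L), idx(r + 1L, nc, 0L),
                    idx(r + 1L, nc, 1L), idx(r, nc, 1L)))
  }
  for (cc in seq_len(nc - 1L)) {
    F <- rbind(F,
               # top edge wall
               quad(idx(nr, cc, 0L), idx(nr, cc, 1L),
                    idx(nr, cc + 1L, 1L), idx(nr, cc + 1L, 0L)))
  }
  mesh <- weld_vertices(tri_mesh(V, F), tol = 1e-9)
  mesh <- .ensure_outward(mesh, c(spec$thickness / 2, 0, 0))
  ctr <- mesh_centroid(mesh)
  mesh <- tri_mesh(sweep(mesh$vertices, 2, ctr), mesh$faces)

  hw <- spec$head_width / 2
  cand_top <- function(yy) {
    f <- c(xf(yy), yy, zt) - ctr
    b <- c(xf(yy) + spec$thickness, yy, zt) - ctr
    if (sum(f^2) >= sum(b^2)) f else b
  }
  tl <- cand_top(-hw)
  tr <- cand_top(hw)
  tipA <- c(0, 0, zb) - ctr
  tipB <- c(spec$thickness, 0, zb) - ctr
  line_d2 <- function(p, l0, ldir) sum((p - l0)^2) - sum((p - l0) * ldir)^2
  ldir <- .unit(tr - tl)
  bottom <- if (line_d2(tipA, tl, ldir) >= line_d2(tipB, tl, ldir)) tipA else tipB
  truth <- list(top_left = tl, top_right = tr, bottom = bottom,
                plate_length = spec$length, centroid_offset = ctr,
                spec = spec)
  list(mesh = mesh, truth = truth)
}

#' Randomly perturb a pose
#'
#' Adds independent uniform perturbations (at most `max_rot_deg` per
#' rotation axis and `max_trans_mm` per translation axis) to a pose;
#' deterministic per seed.
#'
#' @param pose a [rigid_pose()].
#' @param max_rot_deg,max_trans_mm per-axis perturbation bounds.
#' @param seed integer seed.
#' @return The perturbed [rigid_pose()].
#' @export
perturb_pose <- function(pose, max_rot_deg, max_trans_mm, seed = 1) {
  stopifnot(max_rot_deg >= 0, max_trans_mm >= 0)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  rigid_pose(pose$rotation + runif(3, -max_rot_deg, max_rot_deg),
             pose$translation + runif(3, -max_trans_mm, max_trans_mm),
             pose$center)
}

#' Generate a full randomized synthetic case
#'
#' Draws a bone and a plate specification from realistic parameter ranges
#' (bone length 130-150 mm, shaft half-width 9-11 mm, flare 1.25-1.35,
#' rim height 2-3 mm, cut tilt 2-8 degrees; plate length 52-58 mm), builds
#' both meshes and returns them with their ground truth.  `resolution =
#' "coarse"` uses wider ring/grid spacing for fast optimization
#' experiments.
#'
#' @param seed integer seed.
#' @param resolution `"standard"` or `"coarse"`.
#' @return List with `bone`, `plate` (each `mesh` + `truth`), and the two
#'   specs.
#' @export
synth_case <- function(seed = 1, resolution = c("standard", "coarse")) {
  resolution <- match.arg(resolution)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  len <- runif(1, 130, 150)
  shaft <- runif(1, 9, 11)
  flare <- runif(1, 1.25, 1.35)
  ridge <- runif(1, 2, 3)
  tilt <- runif(1, 2, 8)
  sty <- runif(1, 4, 6)
  plen <- runif(1, 52, 58)
  b_max <- 1.3 * shaft * flare
  yb <- 0.71 * b_max
  head <- min(runif(1, 18, 21), 2 * yb - 1)
  ring_mm <- if (resolution == "coarse") 5 else 2.5
  grid_mm <- if (resolution == "coarse") 2.2 else 1.4
  bs <- bone_spec(length = len, shaft_radius = shaft, distal_flare = flare,
                  styloid_height = sty, ridge_height = ridge,
                  cut_tilt_deg = tilt, seed = seed, ring_mm = ring_mm)
  # contoured plate: transverse curvature sized to the paired bone, as
  # manufacturers contour volar plates to the distal radius
  ps <- plate_spec(length = plen, head_width = head, grid_mm = grid_mm,
                   curvature_radius = b_max)
  list(bone = make_bone(bs), plate = make_plate(ps),
       bone_spec = bs, plate_spec = ps)
}
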
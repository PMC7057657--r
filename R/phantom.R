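#' Specification of a synthetic plant phantom
#'
#' Parameters of the seeded generator of labeled rosebush-like phantoms:
#' branches and petioles are rounded tubes (capsules) around random-walk
#' polylines and leaflets are thin, gently curved elliptical sheets attached
#' through petioles, mirroring the geometric regime of X-ray CT rosebush
#' models (tube stems of sub-mm to few-mm radius, thin leaf sheets, ~0.5 mm
#' voxel sampling, leaf-dominated shoot composition). All lengths are mm.
#'
#' @param n_branches Number of branches (the first starts at the base, the
#'   others attach to earlier branches, so the stem system is connected).
#' @param branch_length Range of branch lengths.
#' @param branch_radius Range of branch radii.
#' @param petiole_radius Range of petiole radii.
#' @param petiole_length Range of petiole lengths.
#' @param leaves_per_branch Compound leaves per branch.
#' @param leaflet_pairs Opposite leaflet pairs per compound leaf (a terminal
#'   leaflet is always added).
#' @param leaflet_semi_major,leaflet_semi_minor Ranges of leaflet ellipse
#'   semi-axes.
#' @param leaf_thickness Leaf sheet thickness.
#' @param upward_bias Strength of the upward drift of the branch random walk.
#' @param step_length Segment length of the branch random walk.
#' @param spacing Voxel spacing, mm (scalar or length 3).
#' @param add_flowers Add a few ellipsoidal flower blobs at branch tips.
#' @param seed Generator seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_branches = 3,
                         branch_length = c(30, 50),
                         branch_radius = c(1.0, 2.5),
                         petiole_radius = c(0.4, 0.9),
                         petiole_length = c(10, 16),
                         leaves_per_branch = 5,
                         leaflet_pairs = 1,
                         leaflet_semi_major = c(5, 15),
                         leaflet_semi_minor = c(3, 10),
                         leaf_thickness = 0.6,
                         upward_bias = 0.65,
                         step_length = 4,
                         spacing = 0.5,
                         add_flowers = FALSE,
                         seed = 1) {
  spec <- list(
    n_branches = as.integer(n_branches),
    branch_length = as.numeric(branch_length),
    branch_radius = as.numeric(branch_radius),
    petiole_radius = as.numeric(petiole_radius),
    petiole_length = as.numeric(petiole_length),
    leaves_per_branch = as.integer(leaves_per_branch),
    leaflet_pairs = as.integer(leaflet_pairs),
    leaflet_semi_major = as.numeric(leaflet_semi_major),
    leaflet_semi_minor = as.numeric(leaflet_semi_minor),
    leaf_thickness = as.numeric(leaf_thickness),
    upward_bias = as.numeric(upward_bias),
    step_length = as.numeric(step_length),
    spacing = if (length(spacing) == 1) rep(as.numeric(spacing), 3) else as.numeric(spacing),
    add_flowers = isTRUE(add_flowers),
    seed = as.integer(seed)
  )
  ranges <- c("branch_length", "branch_radius", "petiole_radius",
              "petiole_length", "leaflet_semi_major", "leaflet_semi_minor")
  for (r in ranges) {
    v <- spec[[r]]
    if (length(v) != 2 || any(v <= 0) || v[1] > v[2]) {
      stop_validation(r, " must be a positive ordered range")
    }
  }
  if (spec$n_branches < 1) stop_validation("n_branches must be >= 1")
  if (any(spec$spacing <= 0)) stop_validation("spacing must be positive")
  if (spec$leaf_thickness <= 0) stop_validation("leaf_thickness must be positive")
  structure(spec, class = "phantom_spec")
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# interpolate a point and tangent at arclength fraction t of a polyline
polyline_point <- function(poly, t) {
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  target <- t * cum[length(cum)]
  k <- max(1, findInterval(target, cum, rightmost.closed = TRUE))
  k <- min(k, nrow(poly) - 1)
  f <- if (seg[k] > 0) (target - cum[k]) / seg[k] else 0
  list(
    point = poly[k, ] + f * (poly[k + 1, ] - poly[k, ]),
    tangent = normalize3(poly[k + 1, ] - poly[k, ])
  )
}

random_walk_branch <- function(start, dir, len, step, upward_bias) {
  n_step <- max(2L, ceiling(len / step))
  poly <- matrix(0, n_step + 1, 3)
  poly[1, ] <- start
  d <- normalize3(dir)
  for (k in seq_len(n_step)) {
    # drift towards a mix of "up" and the branch's own launch direction, so
    # lateral branches keep diverging instead of collapsing onto the vertical
    d <- normalize3(d + upward_bias * normalize3(c(0, 0, 1) + dir) +
                      rnorm(3, 0, 0.25))
    poly[k + 1, ] <- poly[k, ] + d * step
  }
  poly
}

# Build the geometric skeleton: branch/petiole polylines with radii and
# leaflet placement records. Runs inside the generator's seeded RNG scope.
phantom_skeleton <- function(spec) {
  branches <- list()
  branch_azim <- runif(1, 0, 2 * pi)
  for (b in seq_len(spec$n_branches)) {
    if (b == 1) {
      start <- c(0, 0, 0)
      dir <- c(0, 0, 1)
    } else {
      # lateral branches leave low on the primary axis and diverge: spaced
      # azimuths so the crowns do not interleave
      host <- branches[[1]]
      at <- polyline_point(host$poly, runif(1, 0.05, 0.35))
      start <- at$point
      azim <- branch_azim + (b - 1) * 2.39996 + rnorm(1, 0, 0.2)
      elev <- runif(1, 0.35, 0.65) # radians above horizontal: diverge wide
      dir <- c(cos(azim) * cos(elev), sin(azim) * cos(elev), sin(elev))
    }
    branches[[b]] <- list(
      poly = random_walk_branch(start, dir,
                                runif(1, spec$branch_length[1], spec$branch_length[2]),
                                spec$step_length, spec$upward_bias),
      radius = runif(1, spec$branch_radius[1], spec$branch_radius[2])
    )
  }
  petioles <- list()
  leaflets <- list()
  golden <- 2.39996 # spiral phyllotaxis: ~137.5 deg between successive leaves
  for (b in seq_len(spec$n_branches)) {
    azim0 <- runif(1, 0, 2 * pi)
    for (l in seq_len(spec$leaves_per_branch)) {
      frac <- 0.25 + 0.7 * (l - runif(1, 0.2, 0.8)) / spec$leaves_per_branch
      at <- polyline_point(branches[[b]]$poly, frac)
      azim <- azim0 + l * golden + rnorm(1, 0, 0.25)
      elev <- runif(1, -0.15, 0.45)
      pdir <- normalize3(c(cos(azim) * cos(elev), sin(azim) * cos(elev), sin(elev)))
      # keep the petiole pointing away from the branch axis
      pdir <- normalize3(pdir - sum(pdir * at$tangent) * at$tangent * 0.5)
      plen <- runif(1, spec$petiole_length[1], spec$petiole_length[2])
      pp <- matrix(0, 4, 3)
      pp[1, ] <- at$point
      d <- pdir
      for (k in 2:4) {
        d <- normalize3(d + rnorm(3, 0, 0.12) - c(0, 0, 0.06))
        pp[k, ] <- pp[k - 1, ] + d * (plen / 3)
      }
      petioles[[length(petioles) + 1]] <- list(
        poly = pp,
        radius = runif(1, spec$petiole_radius[1], spec$petiole_radius[2]),
        branch = b
      )
      # leaflets: opposite pairs along the petiole plus a terminal one; the
      # leaflets of one compound leaf share a common lamina plane (small
      # per-leaflet deviation), as in real pinnate leaves
      w_leaf <- normalize3(c(0, 0, 1) + rnorm(3, 0, 0.3))
      place <- function(frac, side) {
        pt <- polyline_point(pp, frac)
        w <- normalize3(w_leaf + rnorm(3, 0, 0.07))
        u0 <- if (side == 0) pt$tangent else cross3(pt$tangent, w) * side
        u <- normalize3(u0 - sum(u0 * w) * w)
        v <- cross3(w, u)
        sa <- runif(1, spec$leaflet_semi_major[1], spec$leaflet_semi_major[2])
        sb <- runif(1, spec$leaflet_semi_minor[1], spec$leaflet_semi_minor[2])
        list(
          attach = pt$point, u = u, v = v, w = w, sa = sa, sb = sb,
          bend = runif(1, 0.002, 0.012),
          center = pt$point + u * (0.9 * sa)
        )
      }
      for (p in seq_len(spec$leaflet_pairs)) {
        frac <- 0.35 + 0.5 * (p - 0.5) / spec$leaflet_pairs
        leaflets[[length(leaflets) + 1]] <- place(frac, 1)
        leaflets[[length(leaflets) + 1]] <- place(frac, -1)
      }
      leaflets[[length(leaflets) + 1]] <- place(1, 0)
    }
  }
  flowers <- list()
  if (spec$add_flowers) {
    for (b in seq_len(spec$n_branches)) {
      tip <- branches[[b]]$poly[nrow(branches[[b]]$poly), ]
      flowers[[length(flowers) + 1]] <- list(
        center = tip + c(0, 0, 2), radii = runif(3, 2.5, 5)
      )
    }
  }
  list(branches = branches, petioles = petioles, leaflets = leaflets,
       flowers = flowers)
}

# index range of voxel centres within [lo, hi] (mm, grid frame) along axis a
idx_range <- function(lo, hi, sp, n) {
  i0 <- max(1L, as.integer(ceiling(lo / sp + 0.5)))
  i1 <- min(n, as.integer(floor(hi / sp + 0.5)))
  if (i0 > i1) integer(0) else i0:i1
}

# mark voxels whose centre lies within `radius` of segment p-q
rasterize_capsule <- function(lab, p, q, radius, sp, code) {
  d <- dim(lab)
  rx <- idx_range(min(p[1], q[1]) - radius, max(p[1], q[1]) + radius, sp[1], d[1])
  ry <- idx_range(min(p[2], q[2]) - radius, max(p[2], q[2]) + radius, sp[2], d[2])
  rz <- idx_range(min(p[3], q[3]) - radius, max(p[3], q[3]) + radius, sp[3], d[3])
  if (!length(rx) || !length(ry) || !length(rz)) return(lab)
  cx <- (rx - 0.5) * sp[1]; cy <- (ry - 0.5) * sp[2]; cz <- (rz - 0.5) * sp[3]
  g <- expand.grid(x = cx, y = cy, z = cz)
  seg <- q - p
  L2 <- sum(seg^2)
  t <- if (L2 > 0) {
    pmin(pmax(((g$x - p[1]) * seg[1] + (g$y - p[2]) * seg[2] +
                 (g$z - p[3]) * seg[3]) / L2, 0), 1)
  } else 0
  dx <- g$x - (p[1] + t * seg[1])
  dy <- g$y - (p[2] + t * seg[2])
  dz <- g$z - (p[3] + t * seg[3])
  inside <- dx * dx + dy * dy + dz * dz <= radius^2
  if (any(inside)) {
    ind <- as.matrix(expand.grid(i = rx, j = ry, k = rz))[inside, , drop = FALSE]
    lab[ind] <- code
  }
  lab
}

# mark the nearest voxel of densely sampled points along p-q (keeps thin
# tubes 26-connected regardless of radius)
rasterize_trace <- function(lab, p, q, sp, code) {
  d <- dim(lab)
  len <- sqrt(sum((q - p)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len / (0.4 * min(sp))) + 1L))
  pts <- cbind(p[1] + ts * (q[1] - p[1]), p[2] + ts * (q[2] - p[2]),
               p[3] + ts * (q[3] - p[3]))
  ijk <- sweep(pts, 2, sp, `/`) + 0.5
  ijk <- pmin(pmax(round(ijk), 1), matrix(d, nrow(ijk), 3, byrow = TRUE))
  lab[unique(ijk)] <- code
  lab
}

# radius may be a scalar or per-vertex (linear taper along each segment,
# rasterized with the segment's larger radius and a cone test)
rasterize_polyline <- function(lab, poly, radius, sp, code) {
  n_seg <- nrow(poly) - 1
  radius <- rep_len(radius, nrow(poly))
  for (s in seq_len(n_seg)) {
    lab <- rasterize_cone_capsule(lab, poly[s, ], poly[s + 1, ],
                                  radius[s], radius[s + 1], sp, code)
    lab <- rasterize_trace(lab, poly[s, ], poly[s + 1, ], sp, code)
  }
  lab
}

# capsule with linearly varying radius between the segment end points
rasterize_cone_capsule <- function(lab, p, q, r0, r1, sp, code) {
  rmax <- max(r0, r1)
  d <- dim(lab)
  rx <- idx_range(min(p[1], q[1]) - rmax, max(p[1], q[1]) + rmax, sp[1], d[1])
  ry <- idx_range(min(p[2], q[2]) - rmax, max(p[2], q[2]) + rmax, sp[2], d[2])
  rz <- idx_range(min(p[3], q[3]) - rmax, max(p[3], q[3]) + rmax, sp[3], d[3])
  if (!length(rx) || !length(ry) || !length(rz)) return(lab)
  cx <- (rx - 0.5) * sp[1]; cy <- (ry - 0.5) * sp[2]; cz <- (rz - 0.5) * sp[3]
  g <- expand.grid(x = cx, y = cy, z = cz)
  seg <- q - p
  L2 <- sum(seg^2)
  t <- if (L2 > 0) {
    pmin(pmax(((g$x - p[1]) * seg[1] + (g$y - p[2]) * seg[2] +
                 (g$z - p[3]) * seg[3]) / L2, 0), 1)
  } else 0
  dx <- g$x - (p[1] + t * seg[1])
  dy <- g$y - (p[2] + t * seg[2])
  dz <- g$z - (p[3] + t * seg[3])
  rt <- r0 + (r1 - r0) * t
  inside <- dx * dx + dy * dy + dz * dz <= rt^2
  if (any(inside)) {
    ind <- as.matrix(expand.grid(i = rx, j = ry, k = rz))[inside, , drop = FALSE]
    lab[ind] <- code
  }
  lab
}

rasterize_leaflet <- function(lab, lf, thickness, sp, code) {
  d <- dim(lab)
  # half-thickness floored at half the voxel diagonal so slanted sheets
  # voxelize without holes
  h <- max(thickness / 2, 0.5 * sqrt(sum(sp^2)) / 2 + 0.05)
  reach <- abs(lf$u) * lf$sa + abs(lf$v) * lf$sb +
    abs(lf$w) * (h + lf$bend * (1.9 * lf$sa)^2)
  rx <- idx_range(lf$center[1] - reach[1], lf$center[1] + reach[1], sp[1], d[1])
  ry <- idx_range(lf$center[2] - reach[2], lf$center[2] + reach[2], sp[2], d[2])
  rz <- idx_range(lf$center[3] - reach[3], lf$center[3] + reach[3], sp[3], d[3])
  if (!length(rx) || !length(ry) || !length(rz)) return(lab)
  cx <- (rx - 0.5) * sp[1]; cy <- (ry - 0.5) * sp[2]; cz <- (rz - 0.5) * sp[3]
  g <- expand.grid(x = cx, y = cy, z = cz)
  px <- g$x - lf$center[1]; py <- g$y - lf$center[2]; pz <- g$z - lf$center[3]
  a <- px * lf$u[1] + py * lf$u[2] + pz * lf$u[3]
  b <- px * lf$v[1] + py * lf$v[2] + pz * lf$v[3]
  cc <- px * lf$w[1] + py * lf$w[2] + pz * lf$w[3]
  a_from_attach <- a + 0.9 * lf$sa
  inside <- (a / lf$sa)^2 + (b / lf$sb)^2 <= 1 &
    abs(cc - lf$bend * a_from_attach^2) <= h
  if (any(inside)) {
    ind <- as.matrix(expand.grid(i = rx, j = ry, k = rz))[inside, , drop = FALSE]
    lab[ind] <- code
  }
  lab
}

rasterize_ellipsoid <- function(lab, center, radii, sp, code) {
  d <- dim(lab)
  rx <- idx_range(center[1] - radii[1], center[1] + radii[1], sp[1], d[1])
  ry <- idx_range(center[2] - radii[2], center[2] + radii[2], sp[2], d[2])
  rz <- idx_range(center[3] - radii[3], center[3] + radii[3], sp[3], d[3])
  if (!length(rx) || !length(ry) || !length(rz)) return(lab)
  g <- expand.grid(x = (rx - 0.5) * sp[1], y = (ry - 0.5) * sp[2],
                   z = (rz - 0.5) * sp[3])
  inside <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
    ((g$z - center[3]) / radii[3])^2 <= 1
  if (any(inside)) {
    ind <- as.matrix(expand.grid(i = rx, j = ry, k = rz))[inside, , drop = FALSE]
    lab[ind] <- code
  }
  lab
}

#' Generate a labeled plant phantom
#'
#' Deterministically (given the spec's seed) builds the skeleton, rasterizes
#' leaflets as thin curved sheets (organ code 2) and then stems and petioles
#' as capsules (code 1, overwriting leaves at attachment zones so petiole
#' connectivity is preserved), and derives the surface voxel set and the
#' labeled surface point cloud.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: a list with the solid label grid
#'   (`grid`), the surface label grid (`surface`), the labeled surface point
#'   cloud (`cloud`), the geometric `skeleton`, and the solid-voxel leaf and
#'   stem fractions of the shoot (`fractions`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    skel <- phantom_skeleton(spec)
    sp <- spec$spacing
    # bounding box of all geometry, 2 mm margin
    pts <- do.call(rbind, c(
      lapply(skel$branches, function(b) b$poly),
      lapply(skel$petioles, function(p) p$poly),
      lapply(skel$leaflets, function(l) {
        rbind(l$center - (l$sa + l$sb + 3), l$center + (l$sa + l$sb + 3))
      }),
      lapply(skel$flowers, function(f) {
        rbind(f$center - f$radii, f$center + f$radii)
      })
    ))
    margin <- 2 + max(vapply(skel$branches, `[[`, 0, "radius"))
    origin <- apply(pts, 2, min) - margin
    extent <- apply(pts, 2, max) + margin - origin
    dims <- pmax(as.integer(ceiling(extent / sp)), 4L)

    shift <- function(m) sweep(m, 2, origin)
    skel$branches <- lapply(skel$branches, function(b) {
      b$poly <- shift(b$poly); b
    })
    skel$petioles <- lapply(skel$petioles, function(p) {
      p$poly <- shift(p$poly); p
    })
    skel$leaflets <- lapply(skel$leaflets, function(l) {
      l$attach <- l$attach - origin; l$center <- l$center - origin; l
    })
    skel$flowers <- lapply(skel$flowers, function(f) {
      f$center <- f$center - origin; f
    })

    lab <- array(0L, dims)
    for (lf in skel$leaflets) {
      lab <- rasterize_leaflet(lab, lf, spec$leaf_thickness, sp, organ_code("leaf"))
    }
    for (f in skel$flowers) {
      lab <- rasterize_ellipsoid(lab, f$center, f$radii, sp, organ_code("flower"))
    }
    for (p in skel$petioles) {
      radii <- seq(p$radius, 0.75 * p$radius, length.out = nrow(p$poly))
      lab <- rasterize_polyline(lab, p$poly, radii, sp, organ_code("stem"))
    }
    for (b in skel$branches) {
      # branches taper towards the tip, like real shoots; leaf-bearing tips
      # stay near a millimetre
      radii <- seq(b$radius, max(0.6 * b$radius, 0.8),
                   length.out = nrow(b$poly))
      lab <- rasterize_polyline(lab, b$poly, radii, sp, organ_code("stem"))
    }
    if (!any(lab != 0)) stop_validation("phantom spec produced an empty plant")

    grid <- voxel_grid(lab, spacing = sp, kind = "label")
    shoot <- shoot_mask(grid)
    surf <- extract_surface(shoot)
    surf_lab <- array(0L, dims)
    keep <- surf$values != 0
    surf_lab[keep] <- lab[keep]
    surface <- voxel_grid(surf_lab, spacing = sp, kind = "label")
    cloud <- voxels_to_points(surface)

    n_shoot <- sum(shoot$values)
    fractions <- c(
      leaf = sum(lab == organ_code("leaf")) / n_shoot,
      stem = sum(lab == organ_code("stem")) / n_shoot,
      flower = sum(lab == organ_code("flower")) / n_shoot
    )
    structure(
      list(spec = spec, grid = grid, surface = surface, cloud = cloud,
           skeleton = skel, fractions = fractions),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<phantom seed %d: %d x %d x %d voxels, %d surface points, leaf %.0f%% / stem %.0f%% of shoot>\n",
    x$spec$seed, d[1], d[2], d[3], nrow(x$cloud),
    100 * x$fractions["leaf"], 100 * x$fractions["stem"]
  ))
  invisible(x)
}

#' Write a benchmark suite of phantoms to disk
#'
#' Generates `n_models` phantoms with seeds `base_seed, base_seed + 1, ...`,
#' writes each model's labeled surface cloud (PLY) and solid label volume
#' (multi-page TIFF + sidecar), designates the first model as training data
#' and the rest as test data, and writes a `manifest.csv`.
#'
#' @param dir Output directory (created if needed).
#' @param n_models Number of phantom models (>= 2).
#' @param base_seed Seed of the first model.
#' @param spec A [phantom_spec()] used for every model (its seed is
#'   overridden per model).
#' @return The manifest tibble with columns `model_id`, `cloud`, `volume`,
#'   `role`, `seed`.
#' @export
make_benchmark_suite <- function(dir, n_models = 6, base_seed = 1,
                                 spec = phantom_spec()) {
  stopifnot(n_models >= 2)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n_models), function(i) {
    sp <- spec
    sp$seed <- as.integer(base_seed + i - 1)
    ph <- generate_phantom(sp)
    mdir <- file.path(dir, sprintf("model_%02d", i))
    dir.create(mdir, showWarnings = FALSE)
    cloud_path <- file.path(mdir, "cloud.ply")
    vol_path <- file.path(mdir, "labels.tif")
    write_point_cloud(ph$cloud, cloud_path)
    write_volume(ph$grid, vol_path)
    tibble::tibble(
      model_id = sprintf("model_%02d", i),
      cloud = cloud_path, volume = vol_path,
      role = if (i == 1) "train" else "test",
      seed = sp$seed
    )
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}
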
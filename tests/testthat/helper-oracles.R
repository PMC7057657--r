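# Independent oracles and small fixtures shared across tests. Everything here
# is deliberately brute force / closed form, independent of the package's
# spatial indexes, separable filters and max-flow solver.

# O(N^2) strict-radius neighbour scan
brute_neighbors <- function(coords, i, d) {
  d2 <- colSums((t(coords) - coords[i, ])^2)
  which(d2 < d^2)
}

# O(N^2) edge scan (i < j, strict)
brute_edges <- function(coords, d) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1)) {
    d2 <- colSums((t(coords[(i + 1):n, , drop = FALSE]) - coords[i, ])^2)
    js <- which(d2 < d^2) + i
    if (length(js)) out[[length(out) + 1]] <- cbind(i, js)
  }
  if (length(out)) {
    m <- do.call(rbind, out)
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  } else {
    matrix(0L, 0, 2)
  }
}

# exhaustive 2^n minimization of an mrf_problem energy
brute_min_energy <- function(problem) {
  n <- problem$n_nodes
  best <- Inf
  for (m in 0:(2^n - 1)) {
    lab <- ifelse(bitwAnd(m, bitwShiftL(1, 0:(n - 1))) > 0, "L", "S")
    e <- mrf_energy(problem, lab)
    if (e < best) best <- e
  }
  best
}

random_mrf_problem <- function(max_nodes = 12) {
  n <- sample(1:max_nodes, 1)
  pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(0L, 0, 2)
  ne <- if (nrow(pairs)) sample(0:nrow(pairs), 1) else 0
  edges <- pairs[sample(nrow(pairs), ne), , drop = FALSE]
  mrf_problem(
    unary = matrix(runif(2 * n, 0, 3.2), n, 2),
    edges = edges,
    pairwise = if (ne) runif(ne, 0, 8) else numeric(0),
    w_D = runif(1, 0.2, 1), w_V = runif(1, 0, 0.6)
  )
}

# dense (non-separable) 3D convolution by shift-and-add of the full 3D
# kernel, replicate boundary; kernel = outer product of the 1D kernels
brute_conv3 <- function(vol, kx, ky, kz) {
  d <- dim(vol)
  hx <- (length(kx) - 1) / 2
  hy <- (length(ky) - 1) / 2
  hz <- (length(kz) - 1) / 2
  ix <- pmin(pmax(seq_len(d[1] + 2 * hx) - hx, 1), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * hy) - hy, 1), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2 * hz) - hz, 1), d[3])
  pad <- vol[ix, iy, iz, drop = FALSE]
  out <- array(0, d)
  for (a in seq_along(kx)) {
    for (b in seq_along(ky)) {
      for (cc in seq_along(kz)) {
        w <- kx[a] * ky[b] * kz[cc]
        if (w == 0) next
        # correlation convention, matching the separable filters:
        # out[x] = sum_k w[k] * in[x + k - 1 - h]
        out <- out + w * pad[
          seq_len(d[1]) + (a - 1),
          seq_len(d[2]) + (b - 1),
          seq_len(d[3]) + (cc - 1),
          drop = FALSE
        ]
      }
    }
  }
  out
}

# a random rigid motion (proper rotation + translation)
random_rigid_motion <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 20))
}

apply_rigid <- function(cloud, motion) {
  xyz <- as.matrix(cloud[, c("x", "y", "z")]) %*% t(motion$R)
  out <- cloud
  out$x <- xyz[, 1] + motion$t[1]
  out$y <- xyz[, 2] + motion$t[2]
  out$z <- xyz[, 3] + motion$t[3]
  out
}

# compact phantom spec for unit tests (small grids, fast)
test_phantom_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      n_branches = 2, branch_length = c(12, 18), branch_radius = c(1.0, 1.8),
      petiole_length = c(5, 8), leaves_per_branch = 2, leaflet_pairs = 1,
      leaflet_semi_major = c(4, 7), leaflet_semi_minor = c(2.5, 4.5),
      seed = seed
    ),
    list(...)
  )
  do.call(phantom_spec, args)
}

# surface point cloud of a tube (cylinder) along z, radius r
tube_cloud <- function(r = 1, len = 20, step = 0.4) {
  zs <- seq(0, len, by = step)
  th <- seq(0, 2 * pi, length.out = max(8, ceiling(2 * pi * r / step)) + 1)[-1]
  g <- expand.grid(z = zs, th = th)
  point_cloud(cbind(r * cos(g$th), r * sin(g$th), g$z))
}

# flat sheet patch point cloud in the xy plane
sheet_cloud <- function(side = 20, step = 0.4, thickness = 0) {
  g <- expand.grid(x = seq(0, side, by = step), y = seq(0, side, by = step),
                   z = if (thickness > 0) c(0, thickness) else 0)
  point_cloud(as.matrix(g))
}

# 26-connected components of a logical 3D array, via union over neighbour
# edges of voxel centres (igraph); returns membership per nonzero voxel
voxel_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(integer(0))
  e <- shootseg:::cpp_radius_pairs(idx * 1.0, 1.8) # < sqrt(3)+eps, > diag
  g <- igraph::make_graph(t(e), n = nrow(idx), directed = FALSE)
  igraph::components(g)$membership
}
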
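channel_cols <- function(bank, channel) {
  grep(paste0("^", channel, "_s"), names(bank), value = TRUE)
}

test_that("constant volumes have zero derivative channels, unit smoothing", {
  g <- voxel_grid(array(1L, c(12, 12, 12)), 0.5, "binary_mask")
  bank <- feature_bank(g, scales = c(0.7, 1.6))
  for (ch in c("gradmag", "log", "dog", "hess_xx", "hess_xy", "st_ev1")) {
    expect_true(all(abs(as.matrix(bank[channel_cols(bank, ch)])) < 1e-10),
                info = ch)
  }
  expect_true(all(abs(as.matrix(bank[channel_cols(bank, "gauss")]) - 1) < 1e-10))
})

test_that("impulse response of the smoothing channel is a unit-mass Gaussian", {
  v <- array(0L, c(21, 21, 21)); v[11, 11, 11] <- 1L
  g <- voxel_grid(v, 0.5, "binary_mask")
  sm <- shootseg:::gaussian_derivative(
    {vv <- g$values; storage.mode(vv) <- "double"; vv}, g$spacing, 1.0
  )
  expect_equal(sum(sm), 1, tolerance = 1e-9) # normalized kernels keep mass
  expect_equal(which.max(sm), which(v == 1))
  # response along the x-line through the impulse is kx * ky[0] * kz[0]
  k <- shootseg:::gaussian_kernel(2, 0)      # sigma = 1.0mm / 0.5mm voxels
  h <- (length(k) - 1) / 2
  expect_equal(sm[11 + seq(-4, 4), 11, 11],
               k[h + 1 + seq(-4, 4)] * k[h + 1]^2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("separable filters equal the dense 3D convolution oracle", {
  set.seed(40)
  v <- array(rnorm(20^3), c(20, 20, 20))
  spacing <- c(0.5, 0.5, 0.5)
  for (s in c(0.7, 1.0)) {
    for (orders in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 1, 0))) {
      got <- shootseg:::gaussian_derivative(v, spacing, s, orders)
      sig <- s / spacing
      ks <- lapply(1:3, function(a) {
        shootseg:::gaussian_kernel(sig[a], orders[a], spacing[a])
      })
      want <- brute_conv3(v, ks[[1]], ks[[2]], ks[[3]])
      expect_equal(as.vector(got), as.vector(want), tolerance = 1e-6)
    }
  }
})

test_that("filter responses to a Gaussian blob match analytic closed forms", {
  # a sampled Gaussian blob convolved with Gaussian-derivative kernels equals
  # the analytic derivative of a Gaussian at the combined sigma
  n <- 41; c0 <- 21
  sp <- c(0.5, 0.5, 0.5)
  sb <- 1.5 # blob sigma, mm
  ax <- ((1:n) - c0) * sp[1]
  blob <- exp(-outer(outer(ax^2, ax^2, `+`), ax^2, `+`) / (2 * sb^2))
  s <- 1.0
  sc <- sqrt(sb^2 + s^2)
  gauss3 <- function(x, y, z, sg) exp(-(x^2 + y^2 + z^2) / (2 * sg^2)) *
    (sb / sg)^3 # amplitude of blob * kernel (unit-sum kernel)
  sm <- shootseg:::gaussian_derivative(blob, sp, s, c(0, 0, 0))
  # probe away from the centre so derivatives are non-trivial
  probe <- cbind(c0 + 4, c0 - 3, c0 + 2)
  x <- 4 * sp[1]; y <- -3 * sp[2]; z <- 2 * sp[3]
  expect_equal(sm[probe], gauss3(x, y, z, sc), tolerance = 1e-3)
  gx <- shootseg:::gaussian_derivative(blob, sp, s, c(1, 0, 0))
  expect_equal(gx[probe], -x / sc^2 * gauss3(x, y, z, sc), tolerance = 1e-3)
  hxx <- shootseg:::gaussian_derivative(blob, sp, s, c(2, 0, 0))
  expect_equal(hxx[probe], (x^2 / sc^4 - 1 / sc^2) * gauss3(x, y, z, sc),
               tolerance = 1e-3)
  hxy <- shootseg:::gaussian_derivative(blob, sp, s, c(1, 1, 0))
  expect_equal(hxy[probe], x * y / sc^4 * gauss3(x, y, z, sc), tolerance = 1e-3)
})

test_that("smoothing preserves the mass of interior blobs within 0.5%", {
  n <- 40
  v <- array(0, c(n, n, n))
  ax <- (1:n) - 20.5
  v <- exp(-outer(outer(ax^2, ax^2, `+`), ax^2, `+`) / (2 * 3^2))
  sm <- shootseg:::gaussian_derivative(v, c(0.5, 0.5, 0.5), 1.6)
  expect_lt(abs(sum(sm) - sum(v)) / sum(v), 0.005)
})

test_that("feature bank has 22 channels per scale and sorted eigenvalues", {
  ph <- generate_phantom(test_phantom_spec(seed = 1))
  surf <- extract_surface(shoot_mask(ph$grid))
  at <- sample(which(surf$values != 0), 200)
  bank <- feature_bank(surf, scales = c(1.0, 3.5), at = at)
  expect_equal(ncol(bank) - 1, 2 * 22) # minus the .voxel column
  m <- as.matrix(bank)
  expect_true(all(is.finite(m)))
  for (s in c(1, 3.5)) {
    st <- m[, sprintf("st_ev%d_s%g", 1:3, s)]
    he <- m[, sprintf("hess_ev%d_s%g", 1:3, s)]
    expect_true(all(st[, 1] <= st[, 2] & st[, 2] <= st[, 3]))
    expect_true(all(he[, 1] <= he[, 2] & he[, 2] <= he[, 3]))
  }
})

test_that("axis permutation permutes features consistently", {
  set.seed(41)
  v <- array(as.integer(runif(18^3) < 0.2), c(18, 18, 18))
  g <- voxel_grid(v, 0.5, "binary_mask")
  at <- which(v != 0)
  bank <- feature_bank(g, scales = 1.0, at = at)
  # permute axes (x,y,z) -> (z,x,y) with matching index mapping
  vp <- aperm(v, c(3, 1, 2))
  gp <- voxel_grid(vp, 0.5, "binary_mask")
  ijk <- which(v != 0, arr.ind = TRUE)
  atp <- ijk[, c(3, 1, 2)]
  atp_lin <- atp[, 1] + (atp[, 2] - 1) * 18 + (atp[, 3] - 1) * 18 * 18
  bankp <- feature_bank(gp, scales = 1.0, at = atp_lin)
  # rotation-invariant channels are unchanged
  for (ch in c("gauss", "gradmag", "log", "dog", "st_ev1", "st_ev2", "st_ev3",
               "hess_ev1", "hess_ev2", "hess_ev3")) {
    expect_equal(bankp[[paste0(ch, "_s1")]], bank[[paste0(ch, "_s1")]],
                 tolerance = 1e-9, info = ch)
  }
  # raw tensor entries permute: xx' = zz, yy' = xx, zz' = yy, xy' = xz...
  expect_equal(bankp$hess_xx_s1, bank$hess_zz_s1, tolerance = 1e-9)
  expect_equal(bankp$hess_yy_s1, bank$hess_xx_s1, tolerance = 1e-9)
  expect_equal(bankp$hess_xy_s1, bank$hess_xz_s1, tolerance = 1e-9)
})

test_that("pyramid path approximates direct filtering of smooth fields", {
  # grid large enough that the coarse-level kernel support fits inside it
  n <- 64
  ax <- (1:n) - 32.5
  v <- array(as.integer(exp(-outer(outer(ax^2, ax^2, `+`), ax^2, `+`) / 72) > 0.2),
             c(n, n, n))
  g <- voxel_grid(v, 0.5, "binary_mask")
  at <- which(v != 0)[seq(1, sum(v), by = 13)]
  direct <- feature_bank(g, scales = 3.5, at = at, pyramid_sigma = Inf)
  pyr <- feature_bank(g, scales = 3.5, at = at, pyramid_sigma = 3)
  sm_d <- direct$gauss_s3.5
  sm_p <- pyr$gauss_s3.5
  expect_lt(max(abs(sm_d - sm_p)) / max(abs(sm_d)), 0.02)
})

test_that("random forest separates plate from rod voxels and is deterministic", {
  # plate phantom vs rod phantom: distinguishable by Hessian eigenstructure
  v <- array(0L, c(40, 40, 40))
  v[6:35, 6:35, 20] <- 1L                      # plate (leaf-like), label 2
  v[20, 20, 5:16] <- 1L; v[21, 20, 5:16] <- 1L # rod (stem-like), label 1
  lab <- array(0L, dim(v))
  lab[, , 20] <- 2L * v[, , 20]
  lab[, , 5:16] <- v[, , 5:16]
  g <- voxel_grid(v, 0.5, "binary_mask")
  at <- which(v != 0)
  bank <- feature_bank(g, scales = c(0.7, 1.6), at = at)
  labels <- as.integer(lab[at])
  m <- fit_lfvd(bank, labels, n_trees = 50, seed = 9)
  expect_gt(1 - m$oob_error, 0.95)
  # resubstitution accuracy at least matches out-of-bag accuracy
  pred <- predict(m, bank)
  expect_gte(mean(pred == labels), 1 - m$oob_error)
  # identical seed, identical predictions
  m2 <- fit_lfvd(bank, labels, n_trees = 50, seed = 9)
  expect_identical(predict(m2, bank), pred)
  # model file round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_identical(predict(load_model(f), bank), pred)
})

test_that("volumetric training and prediction validate their inputs", {
  v <- array(1L, c(6, 6, 6))
  g_int <- voxel_grid(array(0.7, c(6, 6, 6)), 0.5, "intensity")
  expect_error(feature_bank(g_int), "binary_mask")
  g <- voxel_grid(v, 0.5, "binary_mask")
  bank <- feature_bank(g, scales = 0.7, at = 1:20)
  expect_error(fit_lfvd(bank, rep(2L, 20)), "both leaf and stem")
  m <- fit_lfvd(bank, rep(c(1L, 2L), 10), n_trees = 10, seed = 1)
  expect_error(predict(m, bank[, 1:10]), "schema")
})

test_that("segmentation writes labels only on the mask", {
  v <- array(0L, c(16, 16, 16))
  v[4:12, 4:12, 8] <- 1L
  v[8, 8, 2:6] <- 1L
  g <- voxel_grid(v, 0.5, "binary_mask")
  lab <- array(0L, dim(v)); lab[, , 8] <- 2L * v[, , 8]; lab[8, 8, 2:6] <- 1L
  bank <- feature_bank(g, scales = c(0.7, 1.6))
  m <- fit_lfvd(bank, as.integer(lab[which(v != 0)]), n_trees = 30, seed = 2)
  seg <- segment_lfvd(m, g)
  expect_true(all(seg$values[v == 0] == 0))
  expect_true(all(seg$values[v == 1] %in% 1:2))
  # empty mask leaves the grid untouched
  seg0 <- segment_lfvd(m, g, mask = integer(0))
  expect_true(all(seg0$values == 0))
})
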
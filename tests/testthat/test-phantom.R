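test_that("noise fields have the requested marginal SD and determinism", {
  expect_equal(noise_field(c(16, 16), sd_hu = 0, seed = 1),
               matrix(0, 16, 16))

  sds <- vapply(1:10, function(s) {
    sd(as.vector(noise_field(c(256, 256), sd_hu = 20, corr_sigma = 0, seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(sds) / 20 - 1), 0.03)

  f1 <- noise_field(c(64, 64), 10, 3, seed = 42)
  f2 <- noise_field(c(64, 64), 10, 3, seed = 42)
  expect_identical(f1, f2)
  expect_false(identical(f1, noise_field(c(64, 64), 10, 3, seed = 43)))
})

test_that("texturing adds neighbor correlation but preserves the SD", {
  stats <- vapply(1:10, function(s) {
    f <- noise_field(c(128, 128), sd_hu = 10, corr_sigma = 3, seed = s)
    lag1 <- cor(as.vector(f[-1, ]), as.vector(f[-nrow(f), ]))
    c(sd(as.vector(f)), lag1)
  }, numeric(2))
  expect_lt(abs(mean(stats[1, ]) / 10 - 1), 0.03)
  expect_gt(min(stats[2, ]), 0.5)
  # Gaussian-kernel autocorrelation oracle: smoothing white noise with a
  # kernel of scale s gives lag-d correlation exp(-d^2 / (4 s^2))
  expect_equal(mean(stats[2, ]), exp(-1 / (4 * 3^2)), tolerance = 0.05)
})

test_that("noise field rejects bad arguments", {
  expect_error(noise_field(c(0, 4), 10), "positive")
  expect_error(noise_field(c(8, 8), -1), ">= 0")
})

test_that("disk phantoms render the insert geometry exactly", {
  spec <- phantom_spec(shape = c(64, 64), background_hu = 0,
                       insert_contrast_hu = 100, insert_radius = 10,
                       edge_blur_sigma = 0, noise_sd_hu = 0)
  img <- disk_phantom(spec)
  px <- as.matrix(img)
  ctr <- spec$insert_center
  expect_equal(px[ctr[1] - 0.5, ctr[2] - 0.5], 100)
  expect_equal(px[round(ctr[1]), round(ctr[2] + 2 * spec$insert_radius)], 0)

  # determinism with noise
  spec_n <- phantom_spec(shape = c(64, 64), noise_sd_hu = 12, seed = 9,
                         insert_radius = 10)
  expect_identical(as.matrix(disk_phantom(spec_n)),
                   as.matrix(disk_phantom(spec_n)))
})

test_that("a blurred edge crosses half-contrast at the nominal radius", {
  spec <- phantom_spec(shape = c(128, 128), background_hu = 0,
                       insert_contrast_hu = 100, insert_radius = 30,
                       edge_blur_sigma = 2, noise_sd_hu = 0,
                       insert_center = c(64, 64))
  px <- as.matrix(disk_phantom(spec))
  # value on the nominal radius, sampled on-axis to avoid interpolation
  expect_equal(px[64, 64 + 30], 50, tolerance = 2)  # erf-ramp midpoint, HU
})

test_that("noiseless disks are radially symmetric about the insert center", {
  spec <- phantom_spec(shape = c(128, 128), insert_radius = 20.5,
                       edge_blur_sigma = 1.5, noise_sd_hu = 0)
  px <- as.matrix(disk_phantom(spec))
  prof <- radial_profile(px, center = spec$insert_center)
  # per-angle spread around the angle-averaged profile is interpolation-level
  ang <- (0:359) * 2 * pi / 360
  d <- 15:25
  vals <- effcnr:::bilinear_sample(px,
    as.vector(spec$insert_center[1] + outer(d, sin(ang))),
    as.vector(spec$insert_center[2] + outer(d, cos(ang))))
  vals <- matrix(vals, length(d), length(ang))
  expect_lt(max(apply(vals, 1, sd)), 1.5)
  expect_equal(prof$mean_hu[15:25], rowMeans(vals), tolerance = 1e-12)
})

test_that("phantom invariants reject impossible inserts", {
  expect_error(phantom_spec(shape = c(64, 64), insert_radius = 40),
               "fit inside")
  expect_error(phantom_spec(shape = c(64, 64), insert_radius = 20,
                            insert_center = c(5, 32)), "outside")
  expect_error(phantom_spec(noise_sd_hu = -1), ">= 0")
})

test_that("model_profile evaluates the closed form exactly", {
  p <- sde_params(c0 = 60, sigma = 1, gamma = 2.5, baseline = 0)
  prof <- model_profile(p, t = 0:49)
  # t = 0: g = (lambda + 3*50)/sqrt(50) = 16.979952, Phi ~ 1
  expect_equal(prof$mean_hu[1], 60, tolerance = 1e-8)
  # symmetry point: where lambda + (gamma + sigma^2/2)(T - t) = 0, value = B + C0/2
  t_mid <- 50 + log(1e-13) / 3
  expect_equal(sde_edge(t_mid, p), 30, tolerance = 1e-12)
  # t -> T: value -> baseline
  expect_lt(sde_edge(49.999, p), 1e-6)
  expect_error(model_profile(p, t = c(1, 50)), "T")
})

test_that("presets produce the documented noise/texture regimes", {
  fbp <- phantom_preset("fbp_like")
  ir <- phantom_preset("ir_like")
  dlr <- phantom_preset("dlr_like")
  expect_equal(fbp$noise_corr_sigma, 0)
  expect_gt(ir$noise_corr_sigma, dlr$noise_corr_sigma)
  expect_gt(fbp$noise_sd_hu, max(ir$noise_sd_hu, dlr$noise_sd_hu))
  expect_lt(dlr$edge_blur_sigma, min(fbp$edge_blur_sigma, ir$edge_blur_sigma))
})
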
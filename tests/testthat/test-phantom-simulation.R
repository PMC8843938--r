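test_that("phantom voxelization encodes the nine-insert layout", {
  g <- small_geometry(n_views = 12)
  ph <- build_insert_phantom(g)
  labs <- sort(unique(as.integer(ph$label)))
  expect_equal(labs, 0:10)           # air, body, center insert, 8 inserts
  expect_equal(length(setdiff(labs, c(0, 1))), 9)
  # zero-concentration insert is water
  ph0 <- build_insert_phantom(g, concentrations = c(0, rep(0.01, 7)))
  idx <- which(ph0$label == 3)       # first peripheral insert
  expect_equal(unique(ph0$rho[idx]), 1)
  expect_equal(ph0$lambda[idx[1], ], c(H = 0.1119, O = 0.8881, I = 0),
               tolerance = 1e-6)
  # 2.5% dilution carries 4.375 mg/ml iodine
  ph25 <- build_insert_phantom(g, concentrations = c(0.025, rep(0.01, 7)))
  expect_equal(max(ph25$iodine_mg_ml), 4.375)  # 0.025 x 175 mgI/ml
  expect_error(build_insert_phantom(g, ring_radius_cm = 1),
               "overlap")
  expect_error(build_insert_phantom(g, concentrations = rep(2, 8)),
               "dilution")
})

test_that("noise-free single-energy-bin scans equal the linear projector", {
  g <- small_geometry(n_views = 30)
  ph <- build_insert_phantom(g)
  sp <- mono_spectrum(60)
  proto <- acquisition_protocol(n_views = 30, kvp_cycle = 60,
                                mas_per_view = 1, noise = FALSE)
  s <- simulate_kvp_switching_scan(ph, proto, g, list(sp))
  # monoenergetic mu image from the element density maps
  mu_img <- matrix(0, g$n_pixels, g$n_pixels)
  for (e in colnames(ph$element_density))
    mu_img <- mu_img + matrix(ph$element_density[, e], g$n_pixels) *
      mass_attenuation(e, 60)
  P <- build_system_matrix(g)
  expect_equal(s$B, forward_project(mu_img, P), tolerance = 1e-10)
})

test_that("kVp cycling partitions views and is seed-reproducible", {
  g <- small_geometry(n_views = 30)
  ph <- build_insert_phantom(g)
  proto <- acquisition_protocol(n_views = 30, rng_seed = 5)
  s1 <- simulate_kvp_switching_scan(ph, proto, g, test_spectra())
  s2 <- simulate_kvp_switching_scan(ph, proto, g, test_spectra())
  expect_identical(s1$B, s2$B)
  expect_equal(as.numeric(table(s1$channel_of_view)), c(10, 10, 10))
  proto3 <- acquisition_protocol(n_views = 30, rng_seed = 6)
  s3 <- simulate_kvp_switching_scan(ph, proto3, g, test_spectra())
  expect_false(identical(s1$B, s3$B))
  expect_true(all(is.finite(s1$B)))
})

test_that("ground-truth channel images reflect spectral physics", {
  g <- small_geometry(n_views = 12)
  ph <- build_insert_phantom(g)
  sp <- test_spectra()
  gt <- make_ground_truth_channel_images(ph, sp)
  # water value in the body
  idx <- which(ph$label == 1)[1]
  for (i in 1:3)
    expect_equal(gt[, , i][idx],
                 effective_channel_attenuation(water_material(), sp[[i]]),
                 tolerance = 1e-12)
  # insert values increase with concentration, per channel
  for (i in 1:3) {
    vals <- vapply(3:10, function(lab) gt[, , i][which(ph$label == lab)[1]],
                   numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  # contrast enhancement larger at lower kVp
  wmu <- vapply(1:3, function(i) gt[, , i][idx], numeric(1))
  ins <- vapply(1:3, function(i) gt[, , i][which(ph$label == 10)[1]],
                numeric(1))
  enh_hu <- 1000 * (ins - wmu) / wmu
  expect_true(all(diff(enh_hu) < 0))
})

test_that("Poisson noise follows counting statistics", {
  g <- small_geometry(n_views = 240)
  ph <- build_insert_phantom(g)
  sd_bg <- numeric(2)
  n <- g$n_pixels
  cen <- as.vector(outer((n / 2 - 4):(n / 2 + 4),
                         ((n / 2 - 4):(n / 2 + 4) - 1) * n, "+"))
  for (k in 1:2) {
    proto <- acquisition_protocol(n_views = 240, kvp_cycle = 80,
                                  mas_per_view = 1.4,
                                  photons_per_ray_at_unit_mas = 4000 * 2^(k - 1),
                                  rng_seed = 21)
    s <- suppressWarnings(simulate_kvp_switching_scan(ph, proto, g,
                                                      test_spectra()[1]))
    rec <- fbp_reconstruct(s$B, g)
    sd_bg[k] <- sd(rec[cen])
  }
  expect_equal(sd_bg[1] / sd_bg[2], sqrt(2), tolerance = 0.2)
})
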
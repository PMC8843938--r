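test_that("enhancement and CNR follow their defining arithmetic", {
  img <- matrix(100, 20, 20)
  roi <- 1:16; bg <- 101:116
  img[roi] <- 270
  expect_equal(contrast_enhancement(img, roi, bg), 170)
  expect_equal(contrast_enhancement(img + 55, roi, bg), 170)  # shift invariant
  expect_error(contrast_enhancement(img, integer(0), bg), "empty")
  set.seed(12)
  img2 <- matrix(rnorm(400, 100, 100), 20)
  img2[roi] <- rnorm(16, 300, 100)
  # analytic example: means 300/100, sds 100/100 -> 2 * 200 / sqrt(2e4)
  img3 <- matrix(0, 20, 20)
  img3[roi] <- c(rep(200, 8), rep(400, 8))      # mean 300, sd ~103
  img3[bg] <- c(rep(0, 8), rep(200, 8))         # mean 100
  s2 <- sd(img3[roi])^2 + sd(img3[bg])^2
  expect_equal(cnr(img3, roi, bg), 2 * 200 / sqrt(s2))
  expect_equal(cnr(5 * img3, roi, bg), cnr(img3, roi, bg), tolerance = 1e-12)
  expect_equal(cnr(img3, roi, roi), 0)
  flat <- matrix(1, 20, 20); flat[roi] <- 2
  expect_equal(cnr(flat, roi, bg), Inf)
  expect_error(cnr(img3, 1:3, bg), "4 pixels")
})

test_that("insert ROIs lie strictly inside their inserts", {
  g <- scan_geometry(n_pixels = 128, pixel_size_cm = 0.2, n_views = 12)
  ph <- build_insert_phantom(g)
  rois <- insert_rois(ph)
  for (m in 1:8) {
    labs <- ph$label[rois$rois[[m]]]
    expect_true(all(labs == m + 2L), label = sprintf("insert %d", m))
  }
  expect_true(all(ph$label[rois$bg] == 2L))
  expect_length(intersect(rois$bg, unlist(rois$rois)), 0)
  expect_error(insert_rois(ph, side = 12), "margin")
  # too-coarse grids are refused
  g2 <- scan_geometry(n_pixels = 32, pixel_size_cm = 0.8, n_views = 12)
  ph2 <- build_insert_phantom(g2)
  expect_error(insert_rois(ph2), "too coarse")
})

test_that("concentration errors are relative to ground truth", {
  g <- scan_geometry(n_pixels = 128, pixel_size_cm = 0.2, n_views = 12)
  ph <- build_insert_phantom(g)
  rois <- insert_rois(ph)
  est <- ph$iodine_mg_ml
  ce <- concentration_error(est, ph, rois)
  expect_equal(ce$rel_error, rep(0, 8))
  expect_equal(attr(ce, "mean_rel_error"), 0)
  ce2 <- concentration_error(1.15 * est, ph, rois)
  expect_equal(attr(ce2, "mean_rel_error"), 0.15, tolerance = 1e-9)
  ph0 <- build_insert_phantom(g, concentrations = c(0, rep(0.01, 7)))
  expect_message(ce3 <- concentration_error(ph0$iodine_mg_ml, ph0,
                                            insert_rois(ph0)),
                 "zero-concentration")
  expect_equal(nrow(ce3), 7)
})

test_that("a length-1 sensitivity sweep equals a direct reconstruction", {
  mi_g <- small_geometry(n_views = 120)
  ph <- build_insert_phantom(mi_g)
  rois <- insert_rois(ph, side = 2)
  sp <- test_spectra()
  calib <- calibrate_scanner(sp, geometry = mi_g)
  dict <- build_dictionary()
  proto <- acquisition_protocol(n_views = 120, rng_seed = 2)
  s <- suppressWarnings(simulate_kvp_switching_scan(ph, proto, mi_g, sp))
  params <- meer_params(k_max = 6, tol = 0)
  views <- lapply(1:3, function(ch) which(s$channel_of_view == ch))
  projs <- lapply(views, build_system_matrix, geometry = mi_g)
  tab <- sensitivity_sweep("beta", 50, s, ph, rois, dict, calib, params,
                           projectors = projs)
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$error))
  rec <- meer_reconstruct(s, dict, calib, params, projectors = projs)
  hu <- mu_to_hu(rec$F[, , 1], calib$mu_water[1])
  expect_equal(tab$cnr_insert3, cnr(hu, rois$rois[[3]], rois$bg),
               tolerance = 1e-10)
  # deterministic given the scan
  tab2 <- sensitivity_sweep("beta", 50, s, ph, rois, dict, calib, params,
                            projectors = projs)
  expect_equal(tab, tab2)
  expect_error(sensitivity_sweep("beta", numeric(0), s, ph, rois, dict,
                                 calib, params), "nonempty")
})

test_that("insert CNR is insensitive to the dictionary sparsity weight", {
  mi_g <- scan_geometry(n_pixels = 80, pixel_size_cm = 0.32, n_views = 150)
  ph <- build_insert_phantom(mi_g)
  rois <- insert_rois(ph)       # 3x3 ROIs at this resolution
  sp <- test_spectra()
  calib <- calibrate_scanner(sp, geometry = mi_g)
  dict <- build_dictionary()
  proto <- acquisition_protocol(n_views = 150, rng_seed = 2)
  s <- suppressWarnings(simulate_kvp_switching_scan(ph, proto, mi_g, sp))
  params <- meer_params(k_max = 25, tol = 1e-4)
  views <- lapply(1:3, function(ch) which(s$channel_of_view == ch))
  projs <- lapply(views, build_system_matrix, geometry = mi_g)
  tab <- sensitivity_sweep("alpha2", c(1e-4, 1e-3, 1e-2), s, ph, rois,
                          dict, calib, params, projectors = projs)
  # spread of the mean insert CNR across two decades around the default
  expect_lt(diff(range(tab$cnr_mean)) / mean(tab$cnr_mean), 0.10)
})
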
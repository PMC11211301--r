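test_that("PSF width grows with distance from its intrinsic floor", {
  psf <- psf_model(intrinsic_fwhm = 4, slope = 0.055)
  expect_equal(psf_fwhm(psf, 0), 4)
  d <- seq(0, 400, by = 25)
  expect_true(all(diff(psf_fwhm(psf, d)) >= 0))
  expect_equal(psf_fwhm(psf, 250), sqrt(16 + (0.055 * 250)^2))
  expect_error(psf_model(-1), ">= 0")
})

test_that("auto-contoured orbit follows the support of the body", {
  ## spherical body: constant radius R + margin at every angle
  g <- voxel_grid(c(41, 41, 21), 5)
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(g$n[a]) - 1) * 5)
  R <- 62
  ball <- array(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2 * 0, `+`)
                <= R^2, g$n)
  views <- view_angles(n_views_per_head = 12, n_heads = 2)
  orb <- auto_contour_orbit(list(mask = ball, grid = g), margin = 30, views)
  expect_lt(max(orb$radius) - min(orb$radius), 5)    # voxel-level constancy
  expect_equal(mean(orb$radius), R + 30, tolerance = 0.05)
  ## doubling the margin adds exactly the increment everywhere
  orb2 <- auto_contour_orbit(list(mask = ball, grid = g), margin = 60, views)
  expect_equal(orb2$radius, orb$radius + 30)
  ## elliptical body: widest stand-off facing the long axis
  ell <- array(outer(outer((ax[[1]] / 90)^2, (ax[[2]] / 50)^2, `+`),
                     ax[[3]] * 0, `+`) <= 1, g$n)
  orb3 <- auto_contour_orbit(list(mask = ell, grid = g), margin = 20,
                             view_angles(6, 2, start_deg = 0))
  r_long <- orb3$radius[orb3$angle_deg %in% c(0, 180)]
  r_short <- orb3$radius[orb3$angle_deg %in% c(90, 270)]
  expect_true(min(r_long) > max(r_short))
  expect_error(auto_contour_orbit(list(mask = ball, grid = g), -1, views),
               "non-negative")
})

test_that("projector conserves counts, applies Beer-Lambert, and blurs at FWHM(D)", {
  g <- centered_grid()
  ic <- (g$n + 1) / 2                        # centre voxel on the axis
  vol <- array(0, g$n); vol[ic[1], ic[2], ic[3]] <- 5
  orb <- fixed_orbit(seq(0, 330, by = 30), 200)
  emission <- 5 * prod(g$voxel_size) / 1000
  ## no attenuation, no PSF: every view total equals the emission
  sys0 <- spect_system(g, orb)
  p0 <- forward_project(sys0, vol)
  expect_equal(apply(p0, 3, sum), rep(emission, 12), tolerance = 1e-12)
  ## an arbitrary interior volume is also conserved view-by-view
  volr <- interior_random_volume(g, seed = 7)
  pr <- forward_project(sys0, volr)
  expect_equal(apply(pr, 3, sum),
               rep(sum(volr) * prod(g$voxel_size) / 1000, 12),
               tolerance = 1e-10)
  ## uniform attenuation: view total scales by the closed-form path factor
  mu0 <- 0.01
  sysa <- spect_system(g, orb, mu_map = array(mu0, g$n))
  pa <- forward_project(sysa, vol)
  path <- g$voxel_size[2] * (0.5 + g$n[2] - ic[2])   # half own plane + rest
  expect_equal(apply(pa, 3, sum), rep(emission * exp(-mu0 * path), 12),
               tolerance = 1e-6)
  ## PSF: the view profile of an axis source is Gaussian with FWHM(D), D = radius
  psf <- psf_model(intrinsic_fwhm = 6, slope = 0.06)
  sysp <- spect_system(g, fixed_orbit(90, 250), psf = psf)
  prof <- rowSums(forward_project(sysp, vol)[, , 1])
  u <- (seq_len(g$n[1]) - ic[1]) * g$voxel_size[1]
  sd_fit <- sqrt(sum(prof * u^2) / sum(prof))
  fwhm_fit <- 2 * sqrt(2 * log(2)) * sd_fit
  expect_equal(fwhm_fit, psf_fwhm(psf, 250), tolerance = 0.05)
})

test_that("forward projector is linear and exactly adjoint to the backprojector", {
  g <- centered_grid(n = 17L, nz = 7L, vox = 12)
  orb <- fixed_orbit(c(25, 130, 255), 180)
  mu <- array(0, g$n); mu[5:13, 5:13, ] <- 0.012
  psf <- psf_model()
  for (p in list(NULL, psf)) {
    sys <- spect_system(g, orb, psf = p, mu_map = mu, cal = 3.7)
    x <- interior_random_volume(g, seed = 11)
    y <- interior_random_volume(g, seed = 12)
    ## linearity
    expect_equal(forward_project(sys, 2 * x + 3 * y),
                 2 * forward_project(sys, x) + 3 * forward_project(sys, y),
                 tolerance = 1e-12)
    ## adjoint identity <Ax, z> = <x, A'z>
    z <- withr::with_seed(13, array(runif(g$n[1] * g$n[3] * 3),
                                    c(g$n[1], g$n[3], 3)))
    lhs <- sum(forward_project(sys, x) * z)
    rhs <- sum(x * back_project(sys, z))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("scatter model fills windows that TEW inverts", {
  g <- centered_grid(n = 33L, nz = 9L, vox = 8)
  ax <- g$origin[1] + (seq_len(g$n[1]) - 1) * g$voxel_size[1]
  disk <- array(0, g$n)
  xy <- outer(ax^2, ax^2, `+`) <= 70^2
  for (k in 4:6) disk[, , k] <- xy
  sys <- spect_system(g, fixed_orbit(c(0, 90, 180, 270), 200))
  prim <- forward_project(sys, disk)
  sm <- scatter_model(k = 0.2, kernel_fwhm = 60)
  win <- add_scatter(prim, sm, g$voxel_size[1])
  ## mass bookkeeping: main = (1 + k) x primary
  expect_equal(sum(win$main), (1 + sm$k) * sum(prim), tolerance = 1e-10)
  ## k = 0: untouched primary, empty side windows
  win0 <- add_scatter(prim, scatter_model(k = 0), g$voxel_size[1])
  expect_equal(win0$main, prim)
  expect_true(all(win0$lower == 0) && all(win0$upper == 0))
  ## TEW on the noise-free windows returns the injected scatter exactly
  s_hat <- tew_estimate(win$lower, win$upper, sm$w_low, sm$w_up, sm$w_main)
  expect_equal(s_hat, win$scatter_true, tolerance = 1e-12)
  ## trapezoid closed forms
  expect_equal(tew_estimate(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))),
               array(0, c(2, 2, 1)))
  s <- 0.37
  expect_equal(tew_estimate(array(s * 20.8, c(2, 2, 1)),
                            array(s * 20.8, c(2, 2, 1)),
                            20.8, 20.8, 41.6)[1, 1, 1], s * 41.6)
  expect_error(tew_estimate(prim, prim, w_low = 0), "positive")
  ## with Poisson counts the TEW estimate tracks the truth per view
  cal <- calibrate_sensitivity(win$main, 25000)
  proj <- scale_and_poisson(win, cal, 1, seed = 5)
  est <- tew_estimate(proj$counts_lower, proj$counts_upper,
                      sm$w_low, sm$w_up, sm$w_main)
  rel <- abs(apply(est, 3, sum) - apply(win$scatter_true * cal, 3, sum)) /
    apply(win$scatter_true * cal, 3, sum)
  expect_lt(mean(rel), 0.05)
})

test_that("count scaling and Poisson draws are calibrated and reproducible", {
  win <- list(main = array(c(0, 2, 4, 10), c(2, 2, 1)),
              lower = array(0.5, c(2, 2, 1)), upper = array(0.5, c(2, 2, 1)))
  ps1 <- scale_and_poisson(win, sensitivity = 10, exposure = 2, seed = 99)
  ps2 <- scale_and_poisson(win, sensitivity = 10, exposure = 2, seed = 99)
  expect_identical(ps1$counts_main, ps2$counts_main)
  expect_identical(ps1$counts_lower, ps2$counts_lower)
  ## a zero-expectation bin never fires
  expect_equal(ps1$counts_main[1, 1, 1], 0)
  expect_true(all(ps1$counts_main == floor(ps1$counts_main)))
  ## sample mean of a lambda = 100 bin over 1e4 draws within 3 sigma
  draws <- vapply(seq_len(1e4), function(s)
    scale_and_poisson(list(main = array(100, c(1, 1, 1)),
                           lower = array(0, c(1, 1, 1)),
                           upper = array(0, c(1, 1, 1))),
                      1, 1, seed = s)$counts_main[1, 1, 1], 0)
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / 1e4))
  expect_error(scale_and_poisson(win, -1, 1, seed = 1), "positive")
  expect_error(scale_and_poisson(list(main = array(-1, c(1, 1, 1)),
                                      lower = array(0, c(1, 1, 1)),
                                      upper = array(0, c(1, 1, 1))),
                                 1, 1, seed = 1), "negative expected")
})
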
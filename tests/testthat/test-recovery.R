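test_that("recovery coefficient definition behaves at its fixed points", {
  g <- voxel_grid(c(40, 40, 40), 1)
  occ <- sphere_occupancy(g, c(0, 0, 0), 28, supersample = 4L)
  vox_ml <- prod(g$voxel_size) / 1000
  nominal <- 2 * occupancy_volume_ml(occ)
  ## a perfectly recovered uniform concentration gives RC = 1 exactly
  uniform <- array(2, dim(occ$frac))
  expect_equal(compute_rc(uniform, occ$frac, nominal, vox_ml), 1)
  ## no signal, no recovery
  expect_equal(compute_rc(array(0, dim(occ$frac)), occ$frac, nominal, vox_ml),
               0)
  expect_error(compute_rc(uniform, occ$frac, 0, vox_ml), "positive")
  expect_error(compute_rc(array(0, c(2, 2, 2)), occ$frac, 1, vox_ml),
               "identical grids")
})

test_that("RC of a Gaussian-blurred sphere matches the analytic spill-out integral", {
  ## implementation path: voxelize at 1 mm, separable Gaussian blur,
  ## occupancy-weighted RC; oracle: erf-based radial integral
  R <- 14; sigma <- 6
  g <- voxel_grid(c(76, 76, 76), 1)
  occ <- sphere_occupancy(g, c(0, 0, 0), 2 * R, supersample = 4L)
  act <- array(0, g$n)
  d <- dim(occ$frac)
  ix <- occ$offset[1] + seq_len(d[1]); iy <- occ$offset[2] + seq_len(d[2])
  iz <- occ$offset[3] + seq_len(d[3])
  act[ix, iy, iz] <- 2 * occ$frac
  B <- spectrc:::blur_matrix(g$n[1], 1, 2 * sqrt(2 * log(2)) * sigma)
  for (k in seq_len(g$n[3])) act[, , k] <- B %*% act[, , k] %*% t(B)
  act <- aperm(apply(act, c(1, 2), function(v) as.numeric(B %*% v)),
               c(2, 3, 1))
  rc <- compute_rc(act[ix, iy, iz], occ$frac,
                   2 * occupancy_volume_ml(occ), prod(g$voxel_size) / 1000)
  expect_equal(rc, blurred_ball_rc_oracle(R, sigma), tolerance = 0.01)
})

test_that("permutation statistics implement the spread definition", {
  rec <- data.frame(phantom_type = "NEMA_SPECT", perm_index = 1:3,
                    arm = "noRR", updates = 50, diameter = 28,
                    position = c(2, 4, 6), rc = c(0.8, 1.0, 1.2))
  st <- permutation_stats(rec)
  expect_equal(st$mean_rc, 1.0)
  expect_equal(st$theta_rc, 0.4)
  expect_equal(st$argmax_position, 6)
  expect_equal(st$argmin_position, 2)
  ## zero spread
  rec$rc <- 0.7
  expect_equal(permutation_stats(rec)$theta_rc, 0)
  ## scale invariance of the spread statistic
  rec$rc <- c(0.8, 1.0, 1.2)
  st_scaled <- permutation_stats(transform(rec, rc = 3.1 * rc))
  expect_equal(st_scaled$theta_rc, 0.4)
  expect_error(permutation_stats(rec[0, ]), "empty")
})

test_that("extreme configurations report the dominant position and its neighbours", {
  ## a subset placing every diameter at every position, so dominance of one
  ## position is observable for each diameter
  perms <- desk_permutations(nema_diameters("NEMA_SPECT"))
  ## construct records where position 4 is uniformly 10% hotter
  rows <- do.call(rbind, lapply(seq_len(nrow(perms)), function(i) {
    d <- as.numeric(perms[i, paste0("pos", 1:6)])
    data.frame(phantom_type = "NEMA_SPECT", perm_index = perms$index[i],
               arm = "noRR", updates = 50, diameter = d, position = 1:6,
               rc = 0.5 * d / 60 * ifelse(1:6 == 4, 1.1, 1.0))
  }))
  st <- permutation_stats(rows)
  expect_true(all(st$argmax_position == 4))
  cfg <- phantom_config("NEMA_SPECT")
  ext <- extreme_configurations(st, perms, cfg)
  expect_equal(nrow(ext), 2 * nrow(st))
  ## neighbour metadata is consistent with the reported permutation
  for (i in seq_len(nrow(ext))) {
    perm <- perms[perms$index == ext$perm_index[i], ]
    d <- as.numeric(perm[paste0("pos", 1:6)])
    pos <- ext$position[i]
    expect_equal(ext$neighbor_next[i], d[(pos %% 6) + 1])
    expect_equal(ext$neighbor_prev[i], d[((pos - 2) %% 6) + 1])
  }
})

test_that("desk sweep reproduces the structure of the permutation study", {
  sw <- desk_sweep_cached()
  an <- analysis_rc(sw)
  st <- permutation_stats(an)
  ds <- sort(unique(st$diameter))
  st_no <- st[st$arm == "noRR", ][order(st$diameter[st$arm == "noRR"]), ]
  st_rr <- st[st$arm == "RR", ][order(st$diameter[st$arm == "RR"]), ]
  ## RC grows with sphere size (recovery-curve shape), both arms
  expect_true(all(diff(st_no$mean_rc) > 0))
  expect_true(all(diff(st_rr$mean_rc) > 0))
  ## the spread shrinks with sphere size
  expect_true(all(diff(st_no$theta_rc) < 0))
  expect_true(all(diff(st_rr$theta_rc) < 0))
  ## resolution modeling recovers more and varies less
  expect_true(all(st_rr$mean_rc >= st_no$mean_rc))
  expect_true(all(st_rr$theta_rc < st_no$theta_rc))
})

test_that("shared diameters recover less in the SPECT phantom than in the PET phantom", {
  ## the 60 mm sphere soaks up counts that the PET phantom's 10 mm does not
  sw_spect <- desk_sweep_cached()
  sw_pet <- pet_rotations_cached()
  rot6 <- sw_spect$permutations$index[1:6]   # standard-ordering rotations
  an_s <- analysis_rc(sw_spect)
  an_s <- an_s[an_s$perm_index %in% rot6, ]
  an_p <- analysis_rc(sw_pet)
  shared <- c(13, 17, 22, 28, 37)
  for (arm in c("noRR", "RR")) {
    m_s <- sapply(shared, function(d)
      mean(an_s$rc[an_s$diameter == d & an_s$arm == arm]))
    m_p <- sapply(shared, function(d)
      mean(an_p$rc[an_p$diameter == d & an_p$arm == arm]))
    ## aggregate contrast is strict; individual cells may tie within the
    ## counting noise of a six-permutation average
    expect_lt(mean(m_s), mean(m_p))
    expect_gte(sum(m_s < m_p), 4)
  }
})
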
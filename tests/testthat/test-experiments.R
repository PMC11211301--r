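test_that("the structured desk subset covers every diameter-position pair", {
  p <- desk_permutations()
  expect_equal(nrow(p), 24)
  keys <- apply(p[paste0("pos", 1:6)], 1, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  ## every diameter visits every position exactly four times
  for (pos in paste0("pos", 1:6))
    expect_true(all(table(p[[pos]]) == 4))
  ## the indices refer back to the full enumeration
  full <- enumerate_permutations()
  expect_true(all(p$index %in% full$index))
})

test_that("sweep bookkeeping: row counts and determinism", {
  perms <- desk_permutations()[c(1, 7), ]
  acq <- desk_acquisition()
  sw1 <- run_sweep("NEMA_SPECT", permutations = perms, arms = "noRR",
                   acquisition = acq, master_seed = 5L, noRR_iterations = 2)
  ## 2 permutations x 2 snapshots x 6 spheres
  expect_equal(nrow(sw1$rc_table), 2 * 2 * 6)
  expect_setequal(unique(sw1$rc_table$updates), c(10, 20))
  sw2 <- run_sweep("NEMA_SPECT", permutations = perms, arms = "noRR",
                   acquisition = acq, master_seed = 5L, noRR_iterations = 2)
  expect_identical(sw1$rc_table, sw2$rc_table)
  ## different master seed, different noise, different RCs
  sw3 <- run_sweep("NEMA_SPECT", permutations = perms, arms = "noRR",
                   acquisition = acq, master_seed = 6L, noRR_iterations = 2)
  expect_false(identical(sw1$rc_table$rc, sw3$rc_table$rc))
})

test_that("sweep resumes from cached per-permutation outputs", {
  perms <- desk_permutations()[1, ]
  acq <- desk_acquisition()
  dir <- withr::local_tempdir()
  sw1 <- run_sweep("NEMA_SPECT", permutations = perms, arms = "noRR",
                   acquisition = acq, master_seed = 5L, noRR_iterations = 1,
                   out_dir = dir)
  f <- list.files(dir, pattern = "^rc_.*csv$", full.names = TRUE)
  expect_length(f, 1)
  ## poison the cache: resume must reuse it, not recompute
  tab <- read.csv(f)
  tab$rc <- -1
  write.csv(tab, f, row.names = FALSE)
  sw2 <- run_sweep("NEMA_SPECT", permutations = perms, arms = "noRR",
                   acquisition = acq, master_seed = 5L, noRR_iterations = 1,
                   out_dir = dir)
  expect_true(all(sw2$rc_table$rc == -1))
})

test_that("convergence study aggregates mean RC per update count", {
  tab <- expand.grid(phantom_type = "NEMA_SPECT", perm_index = 1:3,
                     arm = "noRR", diameter = c(13, 60), updates = c(10, 20),
                     position = 1)
  tab$rc <- with(tab, updates / 100 + diameter / 1000 + perm_index / 100)
  conv <- convergence_study(tab)
  expect_equal(nrow(conv), 4)
  got <- conv$mean_rc[conv$diameter == 13 & conv$updates == 20]
  expect_equal(got, mean(tab$rc[tab$diameter == 13 & tab$updates == 20]))
})

test_that("recovery converges along the two-arm protocol on the desk sweep", {
  sw <- desk_sweep_cached()
  conv <- convergence_study(sw$rc_table)
  ds <- sort(unique(conv$diameter))
  ## noRR is flat after 50 updates: < 0.01 change in RC (one point of
  ## recovery, the scale on which the convergence curves are read) per sphere
  for (d in ds) {
    c50 <- conv$mean_rc[conv$arm == "noRR" & conv$diameter == d &
                          conv$updates == 50]
    c100 <- conv$mean_rc[conv$arm == "noRR" & conv$diameter == d &
                           conv$updates == 100]
    expect_lt(abs(c100 - c50), 0.01)
  }
  ## RR recovery is non-decreasing in updates for every sphere
  for (d in ds) {
    tr <- conv[conv$arm == "RR" & conv$diameter == d, ]
    tr <- tr[order(tr$updates), ]
    expect_true(all(diff(tr$mean_rc) > -2e-3))
  }
  ## the largest sphere is within 0.01 RC of its final value at half the
  ## update budget; the smallest is still climbing
  big <- conv[conv$arm == "RR" & conv$diameter == max(ds), ]
  small <- conv[conv$arm == "RR" & conv$diameter == min(ds), ]
  gap_to_end <- function(tr, u) {
    fin <- tr$mean_rc[which.max(tr$updates)]
    abs(tr$mean_rc[tr$updates == u] - fin)
  }
  expect_lt(gap_to_end(big, 100), 0.01)
  expect_gt(gap_to_end(small, 100), 0.01)
})

test_that("noRR extremes sit where the detector comes closest", {
  sw <- desk_sweep_cached()
  an <- analysis_rc(sw)
  st <- permutation_stats(an[an$arm == "noRR", ])
  ca <- closest_approach(sw$config, sw$orbit)
  best <- ca$position[which.min(ca$min_distance)]
  ## one position dominates for every diameter, and it is the closest one
  expect_equal(length(unique(st$argmax_position)), 1)
  expect_equal(unique(st$argmax_position), best)
})

test_that("the PVC worked example quantifies the arrangement effect", {
  ex <- pvc_worked_example()
  expect_equal(ex$rc_a, 0.84)
  expect_equal(ex$rc_b, 0.92)
  expect_equal(ex$factor_a, 1.19)
  expect_equal(ex$factor_b, 1.09)
  expect_equal(ex$percent_difference, 9.2)
  ## full-precision reciprocals are consistent
  expect_equal(ex$factor_a_full * ex$rc_a_full, 1)
})

test_that("volume and configuration round-trips preserve data", {
  g <- voxel_grid(c(8, 9, 10), c(2, 2, 3))
  vol <- withr::with_seed(4, array(runif(prod(g$n)), g$n))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, g, path)
  rt <- read_volume(path)
  expect_equal(rt$vol, vol, tolerance = 1e-6)
  expect_equal(rt$grid$voxel_size, g$voxel_size)
  expect_equal(rt$grid$origin, g$origin, tolerance = 1e-5)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  cfg <- phantom_config("NEMA_SPECT")
  write_config_yaml(cfg, ypath)
  expect_equal(read_config_yaml(ypath)$ring_radius, cfg$ring_radius)
})
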
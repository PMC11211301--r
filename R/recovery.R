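#' Recovery coefficient of one sphere
#'
#' RC = (image-based total activity in the sphere) / (nominal activity),
#' with the image-based total taken as the occupancy-weighted sum on the
#' high-resolution mask grid: `sum(activity * occupancy) * voxel_volume`.
#'
#' @param activity_on_mask_grid activity values (MBq/mL) on the mask grid,
#'   shaped like `occupancy`.
#' @param occupancy occupancy-fraction array (same grid and shape).
#' @param nominal_mbq nominal activity in the sphere (MBq); must be > 0.
#' @param voxel_volume_ml mask-grid voxel volume (mL).
#' @return dimensionless recovery coefficient (>= 0; may exceed 1).
#' @export
compute_rc <- function(activity_on_mask_grid, occupancy, nominal_mbq,
                       voxel_volume_ml) {
  if (nominal_mbq <= 0) stop("nominal activity must be positive")
  if (!all(dim(activity_on_mask_grid) == dim(occupancy)))
    stop("activity and occupancy must be on identical grids")
  sum(activity_on_mask_grid * occupancy) * voxel_volume_ml / nominal_mbq
}

#' Recovery coefficient of a phantom sphere from a reconstructed volume
#'
#' Interpolates the reconstruction tri-linearly at the mask-grid voxel
#' centres inside the sphere's bounding box and applies [compute_rc()].
#'
#' @param volume reconstructed activity (MBq/mL).
#' @param grid reconstruction [voxel_grid()].
#' @param sphere one element of `phantom$spheres` from [build_phantom()].
#' @return recovery coefficient.
#' @export
rc_for_sphere <- function(volume, grid, sphere) {
  occ <- sphere$mask
  d <- dim(occ$frac)
  ax <- lapply(1:3, function(a)
    grid_axis(occ$grid, a)[occ$offset[a] + seq_len(d[a])])
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- array(interp_trilinear(volume, grid, pts), d)
  compute_rc(vals, occ$frac, sphere$nominal_mbq,
             grid_voxel_volume_ml(occ$grid))
}

#' Permutation statistics of recovery coefficients
#'
#' For every (phantom type, reconstruction arm, sphere diameter) cell:
#' mean, min and max RC over the permutations, the spread statistic
#' `theta_rc = (RC_max - RC_min) / mean(RC)`, and the permutation/position
#' attaining each extreme.
#'
#' @param records data.frame with columns `phantom_type`, `perm_index`,
#'   `arm`, `updates`, `diameter`, `position`, `rc` (an RC table as produced
#'   by [run_sweep()]).
#' @return data.frame of per-cell statistics.
#' @export
permutation_stats <- function(records) {
  need <- c("phantom_type", "perm_index", "arm", "diameter", "position", "rc")
  if (!all(need %in% names(records))) stop("missing RC-table columns")
  if (nrow(records) == 0) stop("empty RC table")
  key <- interaction(records$phantom_type, records$arm, records$diameter,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    i_max <- which.max(g$rc); i_min <- which.min(g$rc)
    data.frame(phantom_type = g$phantom_type[1], arm = g$arm[1],
               diameter = g$diameter[1], n = nrow(g),
               mean_rc = mean(g$rc), min_rc = min(g$rc), max_rc = max(g$rc),
               theta_rc = (max(g$rc) - min(g$rc)) / mean(g$rc),
               argmax_perm = g$perm_index[i_max],
               argmax_position = g$position[i_max],
               argmin_perm = g$perm_index[i_min],
               argmin_position = g$position[i_min])
  }))
  rownames(out) <- NULL
  out[order(out$phantom_type, out$arm, out$diameter), ]
}

#' Extreme-configuration report
#'
#' For each (phantom, arm, diameter) cell, reports the permutation and ring
#' position attaining the largest and smallest RC together with the
#' diameters of the two ring neighbours and their surface gaps -- the
#' geometric context in which the extremes occur.
#'
#' @param stats output of [permutation_stats()].
#' @param permutations the permutation table the sweep ran over (from
#'   [enumerate_permutations()], possibly subset).
#' @param config the [phantom_config()] (for the ring geometry). With
#'   multiple phantom types, a named list keyed by phantom type.
#' @return data.frame with one row per (cell, extreme).
#' @export
extreme_configurations <- function(stats, permutations, config) {
  get_cfg <- function(pt) if (inherits(config, "phantom_config")) config
  else config[[pt]]
  rows <- lapply(seq_len(nrow(stats)), function(i) {
    s <- stats[i, ]
    do.call(rbind, lapply(c("max", "min"), function(which_ex) {
      pidx <- s[[paste0("arg", which_ex, "_perm")]]
      pos <- s[[paste0("arg", which_ex, "_position")]]
      perm <- permutations[permutations$index == pidx, ]
      d <- perm_diameters(perm)
      gaps <- neighbor_surface_gaps(get_cfg(as.character(s$phantom_type)),
                                    perm)
      nb_prev <- ((pos - 2) %% 6) + 1; nb_next <- (pos %% 6) + 1
      data.frame(phantom_type = s$phantom_type, arm = s$arm,
                 diameter = s$diameter, extreme = which_ex,
                 rc = if (which_ex == "max") s$max_rc else s$min_rc,
                 perm_index = pidx, position = pos,
                 neighbor_prev = d[nb_prev], neighbor_next = d[nb_next],
                 gap_prev = gaps$gap_mm[gaps$pos_b == pos],
                 gap_next = gaps$gap_mm[gaps$pos_a == pos])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
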
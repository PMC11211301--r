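#' Reconstruction configuration
#'
#' @param n_subsets ordered subsets; must divide the view count. Views are
#'   interleaved by stride `n_subsets` (subset s takes views s, s+n_subsets,
#'   ...), a fixed, seed-independent ordering.
#' @param n_iterations full passes over all subsets.
#' @param rr logical: model the distance-dependent PSF in the system matrix
#'   (resolution recovery)?
#' @param recon_grid reconstruction [voxel_grid()].
#' @param snapshot_updates update counts (iterations x subsets performed so
#'   far) at which to emit a volume; defaults to every full iteration.
#' @param floor small positive value keeping the multiplicative update away
#'   from sticky zeros.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(n_subsets = 10, n_iterations = 10, rr = FALSE,
                         recon_grid, snapshot_updates = NULL,
                         floor = 1e-12) {
  if (is.null(snapshot_updates))
    snapshot_updates <- n_subsets * seq_len(n_iterations)
  n_updates <- n_subsets * n_iterations
  if (any(snapshot_updates < 1 | snapshot_updates > n_updates))
    stop("snapshot_updates must lie in 1..n_subsets*n_iterations")
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations), rr = rr,
                 recon_grid = recon_grid,
                 snapshot_updates = sort(unique(as.integer(snapshot_updates))),
                 floor = floor),
            class = "recon_config")
}

#' Ordered-subset EM iteration on an abstract system
#'
#' The multiplicative update
#' `x <- x / s_k * back_k( y_k / (fwd_k(x) + b_k) )`, with subset
#' sensitivity `s_k = back_k(1)`. Voxels with zero total sensitivity are
#' excluded (held at zero) rather than divided through. Bins whose model
#' denominator is zero contribute a zero ratio (their data are almost surely
#' zero under the model). Scatter enters additively in the denominator,
#' preserving Poisson statistics and non-negativity; no pre-subtraction.
#'
#' With one subset this is plain MLEM.
#'
#' @param y list of per-subset data (any conformable numeric arrays).
#' @param fwd function `(x, k)` -> expected data of subset k.
#' @param back function `(r, k)` -> backprojection of subset-k residual ratio.
#' @param scatter list of per-subset additive contamination terms (or NULL).
#' @param n_subsets number of subsets (cycled in order 1..n_subsets).
#' @param snapshot_updates update counts at which to record the image.
#' @param x0 initial image (positive array), or NULL for a uniform constant
#'   scaled to the total counts.
#' @param floor lower clamp applied inside the support after each update.
#' @return named list of images, one per snapshot (names are update counts).
#' @export
osem_em <- function(y, fwd, back, scatter = NULL, n_subsets = length(y),
                    snapshot_updates, x0 = NULL, floor = 1e-12, sens = NULL) {
  ones_like <- function(v) {
    if (is.null(dim(v))) rep(1, length(v)) else array(1, dim(v))
  }
  if (is.null(sens))
    sens <- lapply(seq_len(n_subsets), function(k) back(ones_like(y[[k]]), k))
  total_sens <- Reduce(`+`, sens)
  support <- total_sens > 0
  if (is.null(x0)) {
    tot <- sum(vapply(y, sum, 0))
    x0 <- array(if (sum(total_sens) > 0) tot / sum(total_sens) else 1,
                dim(total_sens))
  }
  x <- x0
  x[!support] <- 0
  out <- vector("list", length(snapshot_updates))
  names(out) <- as.character(snapshot_updates)
  n_updates <- max(snapshot_updates)
  for (u in seq_len(n_updates)) {
    k <- ((u - 1L) %% n_subsets) + 1L
    den <- fwd(x, k)
    if (!is.null(scatter)) den <- den + scatter[[k]]
    ratio <- ifelse(den > 0, y[[k]] / den, 0)
    upd <- back(ratio, k)
    sk <- sens[[k]]
    x <- ifelse(sk > 0, x * upd / sk, x)
    nz <- support & (x > 0)
    x[nz] <- pmax(x[nz], floor)
    if (u %in% snapshot_updates) out[[as.character(u)]] <- x
  }
  out
}

#' OSEM reconstruction of a SPECT projection set
#'
#' Builds matched forward/backprojectors on the reconstruction grid (with
#' attenuation always, PSF only when `config$rr`), applies the TEW-style
#' scatter estimate additively in the denominator, and runs ordered-subset
#' EM, emitting volumes at the requested update counts. The initial image
#' is a uniform positive constant scaled to the total measured counts.
#'
#' @param proj a `projection_set` from [scale_and_poisson()].
#' @param mu_map attenuation map and its grid: list(values, grid) or an
#'   array already on `config$recon_grid`.
#' @param orbit the acquisition orbit (defaults to `proj$orbit`).
#' @param scatter scatter estimate per main-window bin (e.g. from
#'   [tew_estimate()]), same shape as `proj$counts_main`; NULL for none.
#' @param config a [recon_config()].
#' @param psf [psf_model()] used when `config$rr` (ignored otherwise).
#' @param system optional prebuilt [spect_system()] on the recon grid
#'   matching `config$rr` and `proj$cal` (reused across permutations, whose
#'   attenuation map is shared).
#' @return list with `volumes` (named list of arrays, MBq/mL, one per
#'   snapshot), `grid`, `arm` ("RR"/"noRR"), `config`.
#' @export
osem <- function(proj, mu_map, orbit = proj$orbit, scatter = NULL, config,
                 psf = NULL, system = NULL, sens = NULL) {
  grid <- config$recon_grid
  nv <- nrow(orbit)
  if (nv %% config$n_subsets != 0)
    stop("n_subsets must divide the number of views")
  sys <- if (!is.null(system)) system else {
    mu <- if (is.list(mu_map) && !is.null(mu_map$grid)) {
      resample_to_grid(mu_map$values, mu_map$grid, grid)
    } else mu_map
    spect_system(grid, orbit, psf = if (config$rr) psf else NULL,
                 mu_map = mu, cal = proj$cal)
  }
  subsets <- lapply(seq_len(config$n_subsets),
                    function(s) seq(s, nv, by = config$n_subsets))
  y <- lapply(subsets, function(vs) proj$counts_main[, , vs, drop = FALSE])
  b <- if (is.null(scatter)) NULL else
    lapply(subsets, function(vs) scatter[, , vs, drop = FALSE])
  fwd <- function(x, k) forward_project(sys, x, subsets[[k]])
  back <- function(r, k) back_project(sys, r, subsets[[k]])
  vols <- osem_em(y, fwd, back, scatter = b, n_subsets = config$n_subsets,
                  snapshot_updates = config$snapshot_updates, x0 = NULL,
                  floor = config$floor, sens = sens)
  list(volumes = vols, grid = grid, arm = if (config$rr) "RR" else "noRR",
       config = config)
}

#' Per-subset sensitivity images for a system
#'
#' `s_k = A_k' 1`; reusable across reconstructions that share the system
#' operator (the attenuation map is identical for all permutations of one
#' phantom type).
#'
#' @param sys a [spect_system()].
#' @param n_subsets subset count (interleaved view ordering).
#' @return list of sensitivity volumes, one per subset.
#' @export
osem_sensitivities <- function(sys, n_subsets) {
  nv <- nrow(sys$orbit)
  lapply(seq_len(n_subsets), function(s) {
    vs <- seq(s, nv, by = n_subsets)
    back_project(sys, array(1, c(sys$grid$n[1], sys$grid$n[3], length(vs))),
                 vs)
  })
}

## trilinear interpolation of a gridded volume at arbitrary world points
interp_trilinear <- function(vol, grid, pts) {
  f <- sapply(1:3, function(a)
    (pts[, a] - grid$origin[a]) / grid$voxel_size[a] + 1)
  if (is.null(dim(f))) f <- matrix(f, ncol = 3)
  i0 <- floor(f)
  a <- f - i0
  val <- numeric(nrow(pts))
  n <- grid$n
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- i0[, 1] + cx; iy <- i0[, 2] + cy; iz <- i0[, 3] + cz
    w <- (if (cx) a[, 1] else 1 - a[, 1]) *
         (if (cy) a[, 2] else 1 - a[, 2]) *
         (if (cz) a[, 3] else 1 - a[, 3])
    ok <- ix >= 1 & ix <= n[1] & iy >= 1 & iy <= n[2] & iz >= 1 & iz <= n[3] &
      w > 0
    if (any(ok))
      val[ok] <- val[ok] +
        w[ok] * vol[cbind(ix[ok], iy[ok], iz[ok])]
  }
  val
}

#' Resample a volume onto another grid by tri-linear interpolation
#'
#' Values at target voxel centres outside the source support are zero.
#'
#' @param vol source array.
#' @param from source [voxel_grid()].
#' @param to target [voxel_grid()].
#' @return array on the target grid.
#' @export
resample_to_grid <- function(vol, from, to) {
  lo_s <- from$origin - from$voxel_size / 2
  hi_s <- from$origin + (from$n - 0.5) * from$voxel_size
  lo_t <- to$origin; hi_t <- to$origin + (to$n - 1) * to$voxel_size
  if (any(hi_t < lo_s) || any(lo_t > hi_s))
    stop("disjoint grid domains")
  pts <- as.matrix(expand.grid(x = grid_axis(to, 1), y = grid_axis(to, 2),
                               z = grid_axis(to, 3)))
  array(interp_trilinear(vol, from, pts), to$n)
}

#' Resample a reconstruction onto the high-resolution mask grid
#'
#' Convenience wrapper mirroring the analysis step of interpolating SPECT
#' volumes to the high-resolution (CT-like) mask grid before computing
#' per-sphere activity sums.
#'
#' @param volume array on `from` (e.g. one snapshot from [osem()]).
#' @param from reconstruction [voxel_grid()].
#' @param mask_grid target [voxel_grid()].
#' @return array on `mask_grid`.
#' @export
resample_to_mask_grid <- function(volume, from, mask_grid) {
  resample_to_grid(volume, from, mask_grid)
}
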
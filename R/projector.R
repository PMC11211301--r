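## Rotation-based SPECT projector.
##
## For each view the volume is rotated (mass-preserving bilinear splat) into
## the detector frame, attenuated voxel-by-voxel along the perpendicular ray
## to the detector (own plane counted at half depth), blurred plane-by-plane
## with the distance-dependent Gaussian PSF, and summed along the ray. The
## backprojector is the exact algebraic adjoint: every step is a linear
## operator applied through its transpose, so <Ax, y> == <x, A'y> to
## floating precision. Blur matrices are column-normalized so the projector
## conserves counts when attenuation is off and the support stays inside
## the field of view.

## 1-D Gaussian convolution matrix (n x n), columns normalized to sum 1.
## Returns NULL for a negligible width (identity).
blur_matrix <- function(n, vox, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (!is.finite(sigma) || sigma < 1e-3 * vox) return(NULL)
  m <- min(n - 1L, as.integer(ceiling(4 * sigma / vox)))
  off <- -m:m
  k <- stats::dnorm(off * vox, 0, sigma)
  B <- matrix(0, n, n)
  idx <- outer(seq_len(n), seq_len(n), `-`)   # row - col offset
  sel <- abs(idx) <= m
  B[sel] <- k[idx[sel] + m + 1L]
  sweep(B, 2, colSums(B), "/")
}

## separable 2-D blur; NULL matrix means identity along that axis
apply_sep_blur <- function(img, Bu, Bv) {
  if (!is.null(Bu)) img <- Bu %*% img
  if (!is.null(Bv)) img <- img %*% t(Bv)
  as.matrix(img)
}

## In-plane rotation operators on the (x, y) grid, flattened to nx*ny.
## splat: column-normalized scatter of each source voxel to its rotated
##        position (conserves mass; used for activity).
## gather: row-normalized bilinear sampling at the back-rotated position
##        (reproduces constants; used for the attenuation map).
rotation_matrix <- function(grid, angle_deg, type = c("splat", "gather")) {
  type <- match.arg(type)
  nx <- grid$n[1]; ny <- grid$n[2]
  phi <- angle_deg * pi / 180
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2)
  wx <- rep(xs, times = ny); wy <- rep(ys, each = nx)
  if (type == "splat") {
    ## world -> detector frame: x' = x sin(phi) - y cos(phi), y' = x cos + y sin
    px <- wx * sin(phi) - wy * cos(phi)
    py <- wx * cos(phi) + wy * sin(phi)
  } else {
    ## target voxel in detector frame back-rotated into the world frame
    px <- wx * sin(phi) + wy * cos(phi)
    py <- -wx * cos(phi) + wy * sin(phi)
  }
  fx <- (px - grid$origin[1]) / grid$voxel_size[1] + 1
  fy <- (py - grid$origin[2]) / grid$voxel_size[2] + 1
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  n_cell <- nx * ny
  cell <- seq_len(n_cell)
  ii <- jj <- ww <- vector("list", 4)
  corner <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  wts <- list((1 - ax) * (1 - ay), ax * (1 - ay), (1 - ax) * ay, ax * ay)
  for (c4 in 1:4) {
    ci <- i0 + corner[[c4]][1]; cj <- j0 + corner[[c4]][2]
    ok <- ci >= 1 & ci <= nx & cj >= 1 & cj <= ny & wts[[c4]] > 0
    tgt <- ci[ok] + (cj[ok] - 1) * nx
    if (type == "splat") {
      ii[[c4]] <- tgt; jj[[c4]] <- cell[ok]
    } else {
      ii[[c4]] <- cell[ok]; jj[[c4]] <- tgt
    }
    ww[[c4]] <- wts[[c4]][ok]
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(n_cell, n_cell))
  norm <- if (type == "splat") Matrix::colSums(S) else Matrix::rowSums(S)
  norm[norm == 0] <- 1
  if (type == "splat") S %*% Matrix::Diagonal(x = 1 / norm)
  else Matrix::Diagonal(x = 1 / norm) %*% S
}

#' SPECT system operator
#'
#' Precomputes, for every view of an orbit, the rotation operators, the
#' per-voxel attenuation factors in the detector frame and the per-plane
#' PSF blur matrices, and exposes a matched forward/backprojector pair.
#'
#' @param grid volume [voxel_grid()]; detector bins coincide with the
#'   rotated grid columns (`nx` transaxial bins of width `voxel_size[1]`,
#'   `nz` axial bins).
#' @param orbit an `orbit_spec` from [auto_contour_orbit()].
#' @param psf a [psf_model()], or `NULL` for a purely geometric projector.
#' @param mu_map attenuation map (1/mm) on `grid`, or `NULL` to disable
#'   attenuation.
#' @param cal calibration factor (expected counts per MBq).
#' @return object of class `spect_system`.
#' @export
spect_system <- function(grid, orbit, psf = NULL, mu_map = NULL, cal = 1) {
  nx <- grid$n[1]; ny <- grid$n[2]; nz <- grid$n[3]
  nv <- nrow(orbit)
  voxy <- grid$voxel_size[2]
  ywrld <- grid_axis(grid, 2)
  blur_cache <- new.env(parent = emptyenv())
  get_blur <- function(n, vox, fwhm) {
    fw <- round(fwhm / 0.05) * 0.05          # quantize to share matrices
    key <- sprintf("%d:%.3f:%.2f", n, vox, fw)
    if (is.null(blur_cache[[key]]))
      blur_cache[[key]] <- blur_matrix(n, vox, fw)
    blur_cache[[key]]
  }
  S <- St <- att <- Bx <- Bz <- vector("list", nv)
  for (v in seq_len(nv)) {
    S[[v]] <- rotation_matrix(grid, orbit$angle_deg[v], "splat")
    St[[v]] <- Matrix::t(S[[v]])
    if (!is.null(mu_map)) {
      G <- rotation_matrix(grid, orbit$angle_deg[v], "gather")
      murot <- array(as.matrix(G %*% matrix(mu_map, nx * ny, nz)),
                     c(nx, ny, nz))
      a <- array(0, c(nx, ny, nz))
      running <- matrix(0, nx, nz)
      for (iy in ny:1) {
        a[, iy, ] <- exp(-voxy * (running + 0.5 * murot[, iy, ]))
        running <- running + murot[, iy, ]
      }
      att[[v]] <- a
    }
    if (!is.null(psf)) {
      D <- pmax(orbit$radius[v] - ywrld, 0)
      fw <- psf_fwhm(psf, D)
      Bx[[v]] <- lapply(fw, function(f) get_blur(nx, grid$voxel_size[1], f))
      Bz[[v]] <- lapply(fw, function(f) get_blur(nz, grid$voxel_size[3], f))
    }
  }
  structure(list(grid = grid, orbit = orbit, psf = psf, cal = cal,
                 has_att = !is.null(mu_map), has_psf = !is.null(psf),
                 S = S, St = St, att = att, Bx = Bx, Bz = Bz,
                 vox_ml = grid_voxel_volume_ml(grid)),
            class = "spect_system")
}

## forward projection of one view: activity (MBq/mL) -> expected counts
forward_view <- function(sys, v, vol) {
  g <- sys$grid
  rot <- array(as.matrix(sys$S[[v]] %*% matrix(vol, g$n[1] * g$n[2], g$n[3])),
               g$n)
  if (sys$has_att) rot <- rot * sys$att[[v]]
  proj <- matrix(0, g$n[1], g$n[3])
  if (sys$has_psf) {
    for (iy in seq_len(g$n[2]))
      proj <- proj + apply_sep_blur(rot[, iy, ], sys$Bx[[v]][[iy]],
                                    sys$Bz[[v]][[iy]])
  } else {
    for (iy in seq_len(g$n[2])) proj <- proj + rot[, iy, ]
  }
  proj * (sys$cal * sys$vox_ml)
}

## exact adjoint of forward_view
back_view <- function(sys, v, proj) {
  g <- sys$grid
  proj <- proj * (sys$cal * sys$vox_ml)
  rot <- array(0, g$n)
  if (sys$has_psf) {
    for (iy in seq_len(g$n[2])) {
      Bu <- sys$Bx[[v]][[iy]]; Bv <- sys$Bz[[v]][[iy]]
      p <- proj
      if (!is.null(Bu)) p <- crossprod(Bu, p)
      if (!is.null(Bv)) p <- p %*% Bv
      rot[, iy, ] <- p
    }
  } else {
    for (iy in seq_len(g$n[2])) rot[, iy, ] <- proj
  }
  if (sys$has_att) rot <- rot * sys$att[[v]]
  array(as.matrix(sys$St[[v]] %*% matrix(rot, g$n[1] * g$n[2], g$n[3])), g$n)
}

#' Forward project a volume through all (or selected) views
#'
#' @param sys a [spect_system()].
#' @param vol activity volume (MBq/mL) on the system grid.
#' @param views view indices (default all).
#' @return array `nx x nz x length(views)` of expected counts.
#' @export
forward_project <- function(sys, vol, views = seq_len(nrow(sys$orbit))) {
  if (!all(dim(vol) == sys$grid$n)) stop("volume/grid mismatch")
  out <- array(0, c(sys$grid$n[1], sys$grid$n[3], length(views)))
  for (i in seq_along(views)) out[, , i] <- forward_view(sys, views[i], vol)
  out
}

#' Backproject projections (adjoint of [forward_project()])
#'
#' @param sys a [spect_system()].
#' @param proj array `nx x nz x length(views)`.
#' @param views view indices matching the third dimension of `proj`.
#' @return volume on the system grid.
#' @export
back_project <- function(sys, proj, views = seq_len(nrow(sys$orbit))) {
  vol <- array(0, sys$grid$n)
  for (i in seq_along(views))
    vol <- vol + back_view(sys, views[i], proj[, , i])
  vol
}
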
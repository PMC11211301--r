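#' Distance-dependent collimator response model
#'
#' Gaussian point-spread function whose width grows with the distance D
#' between the source and the collimator face:
#' `FWHM(D) = sqrt(intrinsic_fwhm^2 + (slope * D)^2)`.
#' Defaults emulate a medium-energy low-penetration collimator at the
#' 208 keV photopeak (about 14 mm FWHM at 250 mm).
#'
#' @param intrinsic_fwhm system resolution at the collimator face (mm).
#' @param slope blur growth per mm of source-detector distance.
#' @return object of class `psf_model`.
#' @export
psf_model <- function(intrinsic_fwhm = 4, slope = 0.055) {
  if (intrinsic_fwhm < 0 || slope < 0) stop("psf parameters must be >= 0")
  structure(list(intrinsic_fwhm = intrinsic_fwhm, slope = slope),
            class = "psf_model")
}

#' @rdname psf_model
#' @param psf a `psf_model`.
#' @param distance source to detector-face distance (mm), vectorized.
#' @export
psf_fwhm <- function(psf, distance) {
  sqrt(psf$intrinsic_fwhm^2 + (psf$slope * pmax(distance, 0))^2)
}

#' Patient-bed support used by orbit contouring
#'
#' A rigid slab below the phantom that the detector must clear. The real
#' trajectory of a body-contouring SPECT camera is not axisymmetric because
#' of the bed and its rail system; including the bed in the orbit support is
#' what makes inferior and infero-lateral views stand farther off than
#' anterior ones.
#'
#' @param gap distance (mm) from the lowest body surface to the bed top.
#' @param thickness bed slab thickness (mm).
#' @param halfwidth bed half width (mm).
#' @param body_bottom y (mm) of the lowest body surface.
#' @return object of class `bed_spec`.
#' @export
bed_spec <- function(gap = 10, thickness = 15, halfwidth = 160,
                     body_bottom = -115) {
  structure(list(gap = gap, thickness = thickness, halfwidth = halfwidth,
                 body_bottom = body_bottom), class = "bed_spec")
}

## support function (mm) of the bed rectangle along n(theta); vectorized
bed_support <- function(bed, theta_rad) {
  ys <- c(bed$body_bottom - bed$gap, bed$body_bottom - bed$gap - bed$thickness)
  xs <- c(-bed$halfwidth, bed$halfwidth)
  corners <- as.matrix(expand.grid(x = xs, y = ys))
  proj <- corners %*% rbind(cos(theta_rad), sin(theta_rad))
  apply(proj, 2, max)
}

#' View angles for a multi-head acquisition
#'
#' Heads are spaced 180 degrees apart; each head steps through
#' `n_views_per_head` equally spaced angles over its 180-degree arc so the
#' heads jointly cover 360 degrees.
#'
#' @param n_views_per_head views acquired by each head.
#' @param n_heads number of detector heads (2 by default).
#' @param start_deg angle of the first view of head 1 (90 = anterior).
#' @return data.frame with `angle_deg` and `head`.
#' @export
view_angles <- function(n_views_per_head = 60, n_heads = 2, start_deg = 90) {
  step <- 360 / (n_heads * n_views_per_head)
  out <- do.call(rbind, lapply(seq_len(n_heads), function(h) {
    data.frame(angle_deg = (start_deg + (h - 1) * 180 +
                              (seq_len(n_views_per_head) - 1) * step) %% 360,
               head = h)
  }))
  out
}

#' Auto-contoured non-circular detector orbit
#'
#' For each view angle the detector radius (rotation axis to collimator
#' face) is the maximal extent of the support (body, optionally plus bed)
#' along the detector normal, plus a safety margin. This is the analogue of
#' body-contouring acquisition, where the camera minimizes its distance to
#' the surface at every angle.
#'
#' @param body a `voxel_phantom`, a `phantom_config` (analytic outline), or
#'   a list with elements `mask` (3-D array) and `grid` (a [voxel_grid()]).
#' @param margin clearance (mm) added to the support radius; must be >= 0.
#' @param views a data.frame from [view_angles()] (or a numeric vector of
#'   angles in degrees).
#' @param bed optional [bed_spec()] included in the support.
#' @return object of class `orbit_spec`: `angle_deg`, `head`, `radius`.
#' @export
auto_contour_orbit <- function(body, margin, views = view_angles(), bed = NULL) {
  if (margin < 0) stop("margin must be non-negative")
  if (is.numeric(views)) views <- data.frame(angle_deg = views, head = 1L)
  th <- views$angle_deg * pi / 180
  if (inherits(body, "phantom_config")) {
    supp <- body_support(body, th)
  } else {
    if (inherits(body, "voxel_phantom"))
      body <- list(mask = body$mu_map > 0, grid = body$sim_grid)
    m2 <- apply(body$mask != 0, c(1, 2), any)
    if (!any(m2)) stop("empty body support")
    idx <- which(m2, arr.ind = TRUE)
    pts <- cbind(grid_axis(body$grid, 1)[idx[, 1]],
                 grid_axis(body$grid, 2)[idx[, 2]])
    supp <- apply(pts %*% rbind(cos(th), sin(th)), 2, max)
  }
  if (!is.null(bed)) supp <- pmax(supp, bed_support(bed, th))
  structure(data.frame(angle_deg = views$angle_deg, head = views$head,
                       radius = supp + margin),
            class = c("orbit_spec", "data.frame"))
}

#' Effective scatter model
#'
#' Scatter in the photopeak window is modelled as a scaled broad-kernel
#' convolution of the primary projection; the two flanking windows are
#' populated so that the triple-energy-window (TEW) estimator recovers the
#' injected scatter without bias in expectation. Energy windows: 20% main
#' window at 208 keV and two adjacent 10% windows.
#'
#' @param k scatter-to-primary ratio in the main window.
#' @param kernel_fwhm FWHM (mm) of the Gaussian scatter kernel.
#' @param peak_kev photopeak energy (keV).
#' @param main_frac,side_frac fractional widths of the main and side windows.
#' @return object of class `scatter_model` carrying window widths in keV.
#' @export
scatter_model <- function(k = 0.2, kernel_fwhm = 60, peak_kev = 208,
                          main_frac = 0.20, side_frac = 0.10) {
  if (k < 0) stop("scatter fraction k must be >= 0")
  structure(list(k = k, kernel_fwhm = kernel_fwhm,
                 w_main = main_frac * peak_kev,
                 w_low = side_frac * peak_kev,
                 w_up = side_frac * peak_kev),
            class = "scatter_model")
}

#' Add an effective scatter component and fill the energy windows
#'
#' `scatter_true = k * (normalized Gaussian kernel) * primary`, per view.
#' The main window receives `primary + scatter_true`; the lower and upper
#' windows each receive `scatter_true * w_side / w_main`, a symmetric split
#' constructed so that the TEW trapezoid applied to the side windows returns
#' `scatter_true` exactly in expectation (the estimate remains noisy and
#' clipped at zero once Poisson noise is added).
#'
#' @param primary noise-free primary projections, `nx x nz x nviews`.
#' @param model a [scatter_model()].
#' @param bin_size detector bin size (mm).
#' @return list of arrays `main`, `lower`, `upper` and the injected
#'   `scatter_true`.
#' @export
add_scatter <- function(primary, model, bin_size) {
  if (any(primary < 0)) stop("primary projections must be non-negative")
  dims <- dim(primary)
  scatter <- array(0, dims)
  if (model$k > 0) {
    Bu <- blur_matrix(dims[1], bin_size, model$kernel_fwhm)
    Bv <- blur_matrix(dims[2], bin_size, model$kernel_fwhm)
    for (v in seq_len(dims[3]))
      scatter[, , v] <- model$k * apply_sep_blur(primary[, , v], Bu, Bv)
  }
  list(main = primary + scatter,
       lower = scatter * model$w_low / model$w_main,
       upper = scatter * model$w_up / model$w_main,
       scatter_true = scatter)
}

#' Triple-energy-window scatter estimate
#'
#' Trapezoidal interpolation of the two flanking windows under the main
#' window: `S = (C_low / w_low + C_up / w_up) * w_main / 2`, clipped at 0.
#'
#' @param counts_lower,counts_upper side-window count arrays.
#' @param w_low,w_up,w_main window widths (keV); must be positive.
#' @return scatter estimate per main-window bin, same shape as the inputs.
#' @export
tew_estimate <- function(counts_lower, counts_upper,
                         w_low = 20.8, w_up = 20.8, w_main = 41.6) {
  if (any(c(w_low, w_up, w_main) <= 0)) stop("window widths must be positive")
  s <- (counts_lower / w_low + counts_upper / w_up) * w_main / 2
  s[s < 0] <- 0
  s
}

#' Calibration factor for a target count level
#'
#' Returns the multiplicative factor (counts per forward-model unit) that
#' scales noise-free main-window projections so the mean total per view hits
#' the target, e.g. the 25 kcts per detector and projection of the protocol
#' the study emulates.
#'
#' @param main noise-free main-window projections (`nx x nz x nviews`).
#' @param target_counts_per_view desired mean counts per projection.
#' @return scalar calibration factor.
#' @export
calibrate_sensitivity <- function(main, target_counts_per_view = 25000) {
  totals <- apply(main, 3, sum)
  if (mean(totals) <= 0) stop("projections carry no signal to calibrate")
  target_counts_per_view / mean(totals)
}

#' Scale windows to counts and draw Poisson noise
#'
#' @param windows list with `main`, `lower`, `upper` noise-free projections
#'   (forward-model units).
#' @param sensitivity counts per forward-model unit per second (the product
#'   `sensitivity * exposure` is the calibration factor applied).
#' @param exposure acquisition time per view (s).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param orbit the [auto_contour_orbit()] used (stored as metadata).
#' @param bin_size detector bin size (mm).
#' @return object of class `projection_set`: integer-valued `counts_main`,
#'   `counts_lower`, `counts_upper`, the calibration factor `cal`, `orbit`,
#'   `bin_size`, `seed`.
#' @export
scale_and_poisson <- function(windows, sensitivity, exposure = 1, seed,
                              orbit = NULL, bin_size = NA_real_) {
  if (sensitivity <= 0 || exposure <= 0)
    stop("sensitivity and exposure must be positive")
  cal <- sensitivity * exposure
  draw <- function(x) {
    lam <- x * cal
    if (any(lam < 0)) stop("negative expected counts")
    array(stats::rpois(length(lam), lam), dim(lam))
  }
  counts <- withr::with_seed(as.integer(seed), {
    list(main = draw(windows$main), lower = draw(windows$lower),
         upper = draw(windows$upper))
  })
  structure(list(counts_main = counts$main, counts_lower = counts$lower,
                 counts_upper = counts$upper, cal = cal, orbit = orbit,
                 bin_size = bin_size, seed = as.integer(seed)),
            class = "projection_set")
}
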
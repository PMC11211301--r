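#' Voxel grid descriptor
#'
#' A regular axis-aligned voxel grid. World coordinates refer to voxel
#' centres; indices are 1-based in R but the world origin is the centre of
#' voxel (1,1,1). By default the grid is centred on the world origin, which
#' is also the rotation axis of the gantry (z axis).
#'
#' @param n integer triple, matrix size (nx, ny, nz).
#' @param voxel_size length-3 voxel edge lengths in mm (scalar recycled).
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1);
#'   default centres the grid on the origin.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(n, voxel_size, origin = NULL) {
  n <- as.integer(rep_len(n, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(n < 1L)) stop("matrix size must be positive")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (is.null(origin)) origin <- -(n - 1) / 2 * voxel_size
  structure(list(n = n, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %dx%dx%d @ %.2fx%.2fx%.2f mm\n",
              x$n[1], x$n[2], x$n[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

## world coordinates of voxel centres along one axis
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$n[axis]) - 1) * grid$voxel_size[axis]
}

grid_voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

#' NEMA body-phantom configuration
#'
#' Geometry of the IEC body phantom with its six-sphere insert. The PET
#' variant carries spheres of 10/13/17/22/28/37 mm diameter; the SPECT
#' variant replaces the 10 mm sphere with a 60 mm one. Sphere centres sit on
#' a circle about the phantom axis, 60 degrees apart, in a single transaxial
#' plane. Position 1 is at the top (12 o'clock) and positions advance
#' clockwise when viewed from the gantry front.
#'
#' The body cross-section is approximated as a 300 x 230 mm rounded
#' rectangle of water; the lung insert is omitted. Sphere walls are ignored
#' (thin and near-water), so a single attenuation map serves all
#' permutations of one phantom type.
#'
#' @param phantom_type `"NEMA_PET"` or `"NEMA_SPECT"`.
#' @param ring_radius radius (mm) of the circle the sphere centres lie on.
#' @param body_size transaxial body extent (mm), width x height.
#' @param corner_radius corner rounding radius (mm) of the body outline.
#' @param body_length axial body extent (mm).
#' @param sphere_plane_z z (mm) of the sphere-centre plane.
#' @param concentration activity concentration inside the spheres (MBq/mL).
#' @param background_concentration activity concentration of the body
#'   compartment (MBq/mL); the study uses spheres in a cold background.
#' @param mu_water linear attenuation coefficient of water (1/mm) at the
#'   208 keV photopeak.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(phantom_type = c("NEMA_SPECT", "NEMA_PET"),
                           ring_radius = 57.2,
                           body_size = c(300, 230),
                           corner_radius = 77,
                           body_length = 180,
                           sphere_plane_z = 0,
                           concentration = 2,
                           background_concentration = 0,
                           mu_water = 0.0137) {
  phantom_type <- match.arg(phantom_type)
  diameters <- nema_diameters(phantom_type)
  if (ring_radius <= max(diameters) / 2)
    stop("ring_radius must exceed the largest sphere radius")
  if (concentration < 0 || background_concentration < 0)
    stop("concentrations must be non-negative")
  structure(list(phantom_type = phantom_type, diameters = diameters,
                 ring_radius = ring_radius, body_size = as.numeric(body_size),
                 corner_radius = corner_radius, body_length = body_length,
                 sphere_plane_z = sphere_plane_z,
                 concentration = concentration,
                 background_concentration = background_concentration,
                 mu_water = mu_water),
            class = "phantom_config")
}

#' Sphere diameters of a NEMA phantom variant
#'
#' @param phantom_type `"NEMA_PET"` (10-37 mm) or `"NEMA_SPECT"`
#'   (10 mm replaced by 60 mm).
#' @return numeric vector of six diameters (mm), increasing.
#' @export
nema_diameters <- function(phantom_type = c("NEMA_SPECT", "NEMA_PET")) {
  phantom_type <- match.arg(phantom_type)
  if (phantom_type == "NEMA_PET") c(10, 13, 17, 22, 28, 37)
  else c(13, 17, 22, 28, 37, 60)
}

#' Sphere-centre coordinates on the insert ring
#'
#' @param config a [phantom_config()].
#' @return 6 x 3 matrix of centre coordinates (mm); row k is position k.
#'   Position 1 is at 12 o'clock, positions advance clockwise (viewed from
#'   the gantry front, x to the viewer's left at +90 deg steps of -60 deg).
#' @export
sphere_centers <- function(config) {
  ang <- (90 - 60 * (0:5)) * pi / 180
  cbind(x = config$ring_radius * cos(ang),
        y = config$ring_radius * sin(ang),
        z = rep(config$sphere_plane_z, 6))
}

#' Enumerate all sphere permutations
#'
#' Every bijection of the six diameters onto the six ring positions:
#' 6! = 720 assignments, ordered lexicographically by the diameter sequence
#' at positions 1..6. Each permutation additionally carries the id of its
#' mirror-equivalence class under sagittal reflection (x -> -x, which maps
#' positions 1,2,3,4,5,6 to 1,6,5,4,3,2): 360 classes of two. The full set
#' is kept because a real detector trajectory need not be axisymmetric.
#'
#' @param diameters six distinct sphere diameters (mm).
#' @return data.frame with one row per permutation: `index` (0-based),
#'   `pos1`..`pos6` (diameter at each position) and `mirror_class`.
#' @export
enumerate_permutations <- function(diameters = nema_diameters("NEMA_SPECT")) {
  diameters <- as.numeric(diameters)
  if (anyDuplicated(diameters))
    stop("diameters must be distinct: assignment would not be a bijection")
  k <- length(diameters)
  perm_idx <- permutations_lex(k)           # k! x k index matrix
  d_sorted <- sort(diameters)
  assign_mat <- matrix(d_sorted[perm_idx], nrow = nrow(perm_idx))
  ## lexicographic order by diameter sequence == lexicographic in indices
  out <- as.data.frame(assign_mat)
  names(out) <- paste0("pos", seq_len(k))
  out <- cbind(index = seq_len(nrow(out)) - 1L, out)
  if (k == 6L) {
    ## mirror: position p -> mirror_map[p]
    mirror_map <- c(1L, 6L, 5L, 4L, 3L, 2L)
    key <- apply(assign_mat, 1, paste, collapse = ",")
    mkey <- apply(assign_mat[, mirror_map, drop = FALSE], 1,
                  paste, collapse = ",")
    pair_min <- pmin(match(key, key), match(mkey, key))
    out$mirror_class <- match(pair_min, sort(unique(pair_min))) - 1L
  }
  out
}

## all permutations of 1..k in lexicographic order (k small)
permutations_lex <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_lex(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Volume of a sphere
#'
#' @param diameter sphere diameter (mm).
#' @return volume in mL.
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) stop("diameter must be non-negative")
  pi / 6 * diameter^3 / 1000
}

#' Diameter of a sphere of given volume
#'
#' Inverse of [sphere_volume()]; used e.g. to express a 10 mL lesion as an
#' equivalent sphere diameter.
#'
#' @param volume_ml volume in mL.
#' @return diameter in mm.
#' @export
sphere_diameter_for_volume <- function(volume_ml) {
  if (any(volume_ml < 0)) stop("volume must be non-negative")
  (6 * volume_ml * 1000 / pi)^(1 / 3)
}

## rounded-rectangle body outline test, vectorized over (x, y)
body_inside <- function(config, x, y) {
  hx <- config$body_size[1] / 2
  hy <- config$body_size[2] / 2
  rc <- config$corner_radius
  ax <- abs(x); ay <- abs(y)
  inside <- ax <= hx & ay <= hy
  corner <- ax > (hx - rc) & ay > (hy - rc)
  dx <- ax - (hx - rc); dy <- ay - (hy - rc)
  inside & (!corner | (dx^2 + dy^2 <= rc^2))
}

## support function of the body outline: max over body of (p . n(theta)),
## with n = (cos theta, sin theta). Exact for the rounded rectangle.
body_support <- function(config, theta) {
  hx <- config$body_size[1] / 2
  hy <- config$body_size[2] / 2
  rc <- config$corner_radius
  (hx - rc) * abs(cos(theta)) + (hy - rc) * abs(sin(theta)) + rc
}

#' Fractional sphere occupancy on a voxel grid
#'
#' Supersampled voxelization: each voxel in the sphere's bounding box is
#' subdivided `supersample` times per axis and the fraction of sub-centres
#' inside the sphere is recorded. Returned as a compact bounding-box
#' sub-array plus its index offset into the full grid.
#'
#' @param grid a [voxel_grid()].
#' @param center sphere centre (mm, length 3).
#' @param diameter sphere diameter (mm).
#' @param supersample subdivisions per axis (default 4).
#' @return list with `frac` (3-D array of occupancy fractions), `offset`
#'   (0-based index offset of the sub-array in the full grid), `grid`,
#'   `center`, `diameter`.
#' @export
sphere_occupancy <- function(grid, center, diameter, supersample = 4L) {
  r <- diameter / 2
  lo <- hi <- integer(3)
  for (a in 1:3) {
    ax <- grid_axis(grid, a)
    lo[a] <- max(1L, findInterval(center[a] - r - grid$voxel_size[a], ax))
    hi[a] <- min(grid$n[a],
                 findInterval(center[a] + r + grid$voxel_size[a], ax) + 1L)
  }
  nx <- hi - lo + 1L
  axes <- lapply(1:3, function(a) grid_axis(grid, a)[lo[a]:hi[a]])
  s <- as.integer(supersample)
  off1 <- (seq_len(s) - 0.5) / s - 0.5      # sub-centre offsets in voxel units
  frac <- array(0, dim = nx)
  ## accumulate fraction inside over the s^3 sub-offsets; vectorized over voxels
  cx <- axes[[1]] - center[1]
  cy <- axes[[2]] - center[2]
  cz <- axes[[3]] - center[3]
  for (ox in off1) for (oy in off1) for (oz in off1) {
    dx2 <- (cx + ox * grid$voxel_size[1])^2
    dy2 <- (cy + oy * grid$voxel_size[2])^2
    dz2 <- (cz + oz * grid$voxel_size[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    frac <- frac + inside
  }
  frac <- frac / s^3
  list(frac = frac, offset = lo - 1L, grid = grid,
       center = center, diameter = diameter)
}

#' Occupancy-based sphere volume
#'
#' @param occ result of [sphere_occupancy()].
#' @return volume in mL implied by the voxelized mask.
#' @export
occupancy_volume_ml <- function(occ) {
  sum(occ$frac) * grid_voxel_volume_ml(occ$grid)
}

## paste a bounding-box sub-array into a full-grid array (adding)
paste_bbox <- function(full, frac, offset) {
  d <- dim(frac)
  ix <- offset[1] + seq_len(d[1]); iy <- offset[2] + seq_len(d[2])
  iz <- offset[3] + seq_len(d[3])
  full[ix, iy, iz] <- full[ix, iy, iz] + frac
  full
}

#' Build a voxelized phantom for one sphere permutation
#'
#' Produces the activity field (concentration times fractional occupancy)
#' and the attenuation map on the simulation grid, plus per-sphere
#' high-resolution occupancy masks on the mask grid. The attenuation map
#' depends only on the body outline, never on the permutation, so the same
#' map serves all permutations of one phantom type.
#'
#' @param config a [phantom_config()].
#' @param perm one row of [enumerate_permutations()] (or a numeric vector of
#'   six diameters ordered by position).
#' @param sim_grid simulation [voxel_grid()].
#' @param mask_grid mask [voxel_grid()]; must be at least as fine as
#'   `sim_grid` on every axis.
#' @param supersample occupancy supersampling per axis.
#' @return object of class `voxel_phantom`: `activity` (MBq/mL, sim grid),
#'   `mu_map` (1/mm, sim grid), `spheres` (list of six: diameter, position,
#'   center, occupancy mask on mask grid, nominal activity MBq), plus the
#'   grids and config.
#' @export
build_phantom <- function(config, perm, sim_grid, mask_grid,
                          supersample = 4L) {
  d_by_pos <- perm_diameters(perm)
  if (length(d_by_pos) != 6L || anyDuplicated(d_by_pos))
    stop("permutation must assign six distinct diameters")
  if (any(mask_grid$voxel_size > sim_grid$voxel_size + 1e-9))
    stop("mask_grid must be at least as fine as sim_grid")
  centers <- sphere_centers(config)
  ## adjacent-sphere overlap would mean an invalid ring radius
  gaps <- neighbor_surface_gaps(config, perm)
  if (any(gaps$gap_mm < 0)) stop("spheres overlap: invalid ring geometry")

  activity <- array(0, dim = sim_grid$n)
  spheres <- vector("list", 6L)
  for (p in 1:6) {
    occ_sim <- sphere_occupancy(sim_grid, centers[p, ], d_by_pos[p],
                                supersample)
    activity <- paste_bbox(activity, config$concentration * occ_sim$frac,
                           occ_sim$offset)
    occ_mask <- sphere_occupancy(mask_grid, centers[p, ], d_by_pos[p],
                                 supersample)
    spheres[[p]] <- list(position = p, diameter = d_by_pos[p],
                         center = centers[p, ], mask = occ_mask,
                         nominal_mbq = config$concentration *
                           occupancy_volume_ml(occ_mask))
  }
  if (config$background_concentration > 0) {
    body <- body_mask(config, sim_grid)
    bg <- config$background_concentration * body
    ## spheres displace background
    occ_tot <- array(0, dim = sim_grid$n)
    for (p in 1:6)
      occ_tot <- paste_bbox(occ_tot,
                            sphere_occupancy(sim_grid, centers[p, ],
                                             d_by_pos[p], supersample)$frac,
                            sphere_occupancy(sim_grid, centers[p, ],
                                             d_by_pos[p], supersample)$offset)
    activity <- activity + bg * pmax(0, 1 - occ_tot)
  }
  mu_map <- config$mu_water * body_mask(config, sim_grid)
  structure(list(activity = activity, mu_map = mu_map, spheres = spheres,
                 sim_grid = sim_grid, mask_grid = mask_grid, config = config,
                 permutation = d_by_pos),
            class = "voxel_phantom")
}

## accept a permutation as a data.frame row or a plain numeric vector
perm_diameters <- function(perm) {
  if (is.data.frame(perm)) {
    as.numeric(perm[1, grep("^pos[1-6]$", names(perm))])
  } else as.numeric(perm)
}

## binary body mask (1 inside the water body, 0 outside) on a grid
body_mask <- function(config, grid) {
  x <- grid_axis(grid, 1); y <- grid_axis(grid, 2); z <- grid_axis(grid, 3)
  inz <- abs(z) <= config$body_length / 2
  xy <- outer(x, y, function(xx, yy) body_inside(config, xx, yy))
  arr <- array(0, dim = grid$n)
  for (k in which(inz)) arr[, , k] <- xy
  arr
}

#' Surface gaps between adjacent spheres
#'
#' Distance between the surfaces of each pair of ring-adjacent spheres:
#' chord between neighbouring centres minus the two radii. Used to relate
#' recovery extremes to how close large neighbours come.
#'
#' @param config a [phantom_config()].
#' @param perm permutation (row or numeric vector of diameters by position).
#' @return data.frame: `pos_a`, `pos_b`, `diam_a`, `diam_b`, `gap_mm`.
#' @export
neighbor_surface_gaps <- function(config, perm) {
  d <- perm_diameters(perm)
  chord <- 2 * config$ring_radius * sin(pi / 6)   # 60 deg separation
  a <- 1:6; b <- c(2:6, 1L)
  data.frame(pos_a = a, pos_b = b, diam_a = d[a], diam_b = d[b],
             gap_mm = chord - (d[a] + d[b]) / 2)
}
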
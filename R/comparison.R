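#' Agreement metrics between two sets of recovery curves
#'
#' For two sets of RC curves indexed by the same J configurations
#' (e.g. a measured reference set and a simulated test set), per diameter d:
#' \itemize{
#'   \item `delta(d) = (1/J) sum_j |RC_ref,j(d) - RC_test,j(d)|` -- the mean
#'     absolute deviation between paired curves;
#'   \item `Delta(d) = (1/J) sum_j |RC_ref,j(d) - mean_ref(d)|` -- the mean
#'     absolute spread of the reference set about its own mean curve.
#' }
#' `delta` is symmetric in its two arguments; `Delta` depends only on the
#' reference set.
#'
#' @param reference,test numeric matrices, configurations x diameters, with
#'   matching dimnames (rows are aligned by name when both are named).
#' @return data.frame: `diameter`, `delta`, `Delta`, `mean_reference`.
#' @export
delta_metrics <- function(reference, test) {
  reference <- as.matrix(reference); test <- as.matrix(test)
  if (!is.null(rownames(reference)) && !is.null(rownames(test))) {
    if (!setequal(rownames(reference), rownames(test)))
      stop("configuration keys of the two sets do not match")
    test <- test[rownames(reference), , drop = FALSE]
  }
  if (!all(dim(reference) == dim(test)))
    stop("the two sets must cover the same configurations and diameters")
  mean_ref <- colMeans(reference)
  delta <- colMeans(abs(reference - test))
  Delta <- colMeans(abs(sweep(reference, 2, mean_ref)))
  d <- if (!is.null(colnames(reference))) as.numeric(colnames(reference))
  else seq_len(ncol(reference))
  data.frame(diameter = d, delta = delta, Delta = Delta,
             mean_reference = mean_ref, row.names = NULL)
}

#' RC-curve matrix from an RC table (raw mode)
#'
#' One row per configuration (permutation index), one column per diameter,
#' holding the raw per-sphere RCs. This is the default evaluation mode; see
#' [rc_set_from_fits()] for the fitted-curve mode.
#'
#' @param rc_table RC table (as from [run_sweep()]), already filtered to one
#'   arm and one update count.
#' @return numeric matrix with configuration rownames, diameter colnames.
#' @export
rc_set_from_table <- function(rc_table) {
  ds <- sort(unique(rc_table$diameter))
  cfgs <- sort(unique(rc_table$perm_index))
  m <- matrix(NA_real_, length(cfgs), length(ds),
              dimnames = list(cfgs, ds))
  for (i in seq_len(nrow(rc_table)))
    m[as.character(rc_table$perm_index[i]),
      as.character(rc_table$diameter[i])] <- rc_table$rc[i]
  if (anyNA(m)) stop("RC table does not cover all configuration x diameter cells")
  m
}

#' RC-curve matrix from fitted curves (fitted mode)
#'
#' @param fits named list of `rc_fit` objects (one per configuration).
#' @param diameters diameters (cm) at which to evaluate the curves.
#' @return numeric matrix, configurations x diameters.
#' @export
rc_set_from_fits <- function(fits, diameters) {
  m <- t(vapply(fits, evaluate_fit, numeric(length(diameters)),
                d = diameters))
  colnames(m) <- diameters
  m
}

#' Named sphere-configuration presets
#'
#' The six configurations used for experimental validation of the
#' permutation study: a `standard` arrangement with alternating sphere
#' sizes (the largest sphere flanked by the two smallest, as proposed for
#' accreditation protocols) and a `switch` arrangement with diameters
#' ascending clockwise, each with the whole insert rotated by 0, 120 and
#' 210 degrees. The 210-degree variants carry an extra 30-degree offset of
#' the insert relative to the canonical position grid (recorded in
#' `offset_deg`), so they are not members of the 720 on-grid permutations.
#'
#' @param diameters the six sphere diameters (mm).
#' @return data.frame: `name`, `base`, `rotation_deg`, `offset_deg`,
#'   `pos1`..`pos6`.
#' @export
sphere_configurations <- function(diameters = nema_diameters("NEMA_SPECT")) {
  s <- sort(diameters)
  base <- list(standard = s[c(6, 2, 4, 3, 5, 1)],
               switch = s)
  rot <- c(0, 120, 210)
  rows <- list()
  for (b in names(base)) for (r in rot) {
    shift <- (r %/% 60) %% 6
    idx <- ((seq_len(6) - 1 - shift) %% 6) + 1
    rows[[length(rows) + 1]] <-
      data.frame(name = sprintf("%s_%d", b, r), base = b, rotation_deg = r,
                 offset_deg = if (r %% 60 == 0) 0 else r %% 60,
                 t(stats::setNames(base[[b]][idx], paste0("pos", 1:6))))
  }
  do.call(rbind, rows)
}
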
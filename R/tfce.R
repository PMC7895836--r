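#' Parameters for threshold-free cluster enhancement
#'
#' TFCE integrates, over all supra-threshold levels h, the quantity
#' `extent(v,h)^E * h^H * dh`, where `extent(v,h)` is the size of the
#' connected component containing voxel v in the set `{stat >= h}`. The
#' defaults (H = 2, E = 0.5, dh = max/100, 26-connectivity) are the canonical
#' volumetric TFCE settings used by FSL randomise.
#'
#' @param height_power H, exponent on the threshold height.
#' @param extent_power E, exponent on the component size (voxels).
#' @param n_steps number of integration steps (dh = map max / n_steps).
#' @param connectivity 6, 18 or 26 neighbours.
#' @param dh optional fixed step; if NULL (default) dh is recomputed from
#'   each map's maximum — including separately within every permutation, as
#'   the canonical implementation does. A fixed dh makes scores comparable
#'   across maps at the cost of a fixed resolution.
#' @return object of class `ef_tfce_params`.
#' @export
tfce_params <- function(height_power = 2, extent_power = 0.5,
                        n_steps = 100, connectivity = 26, dh = NULL) {
  if (height_power < 0 || extent_power < 0) stop("powers must be >= 0")
  if (n_steps < 10) stop("n_steps must be >= 10")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6/18/26")
  structure(list(height_power = height_power, extent_power = extent_power,
                 n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity), dh = dh),
            class = "ef_tfce_params")
}

#' Threshold-free cluster enhancement of a statistic volume
#'
#' @param stat an `ef_stat_map` or a dense 3D array.
#' @param params a [tfce_params()].
#' @param direction `"positive"` enhances the map as is; `"negative"`
#'   enhances the negated map (scores are reported positive either way).
#'   Voxels at or below 0 (after any negation) score 0.
#' @return enhanced map of the same type as the input.
#' @export
tfce_enhance <- function(stat, params = tfce_params(),
                         direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  is_map <- inherits(stat, "ef_stat_map")
  arr <- if (is_map) as_dense(stat) else stat
  if (length(dim(arr)) != 3L) stop("TFCE input must be 3D")
  if (any(!is.finite(arr))) stop("TFCE input contains non-finite values")
  if (direction == "negative") arr <- -arr
  sc <- tfce_dense_cpp(as.numeric(arr), dim(arr),
                       params$height_power, params$extent_power,
                       params$n_steps, params$connectivity,
                       if (is.null(params$dh)) -1 else params$dh)
  out <- array(sc, dim = dim(arr))
  if (is_map)
    new_stat_map(out[stat$linear_index], stat$grid, stat$mask,
                 stat$linear_index, paste0("tfce_", direction))
  else out
}

#' Connected components of a logical volume
#'
#' @param mask dense logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background), labelled in
#'   order of first encounter along the linear scan.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (length(dim(mask)) != 3L) stop("mask must be 3D")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6/18/26")
  array(label_components_cpp(as.logical(mask), dim(mask),
                             as.integer(connectivity)), dim = dim(mask))
}
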
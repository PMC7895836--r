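#' Current scaling from unit-current solve to device output
#'
#' Finite-element field solutions are computed at a reference electrode
#' current (1 mA) and, because the quasi-static field is linear in the
#' injected current, rescaled to the stimulator's output by a single factor.
#' The default 900 maps a 1 mA solve to a 0.9 A constant-current device
#' (Thymatron System IV); devices delivering 0.8 A use 800.
#'
#' @param solve_current_mA current of the field solve, mA (default 1).
#' @param device_current_mA device output current, mA (default 900).
#' @return list with the two currents and `scale_factor` (device/solve).
#' @export
scaling_spec <- function(solve_current_mA = 1, device_current_mA = 900) {
  if (solve_current_mA <= 0 || device_current_mA <= 0)
    stop("currents must be positive")
  list(solve_current_mA = solve_current_mA,
       device_current_mA = device_current_mA,
       scale_factor = device_current_mA / solve_current_mA)
}

#' Isotropic tissue conductivities used for field simulation (provenance)
#'
#' Metadata only: the conductivities (S/m) conventionally assigned to the
#' finite-element head model whose exported fields this package analyses.
#' No solving happens here.
#'
#' @return named numeric vector, S/m.
#' @export
conductivity_defaults <- function() {
  c(white_matter = 0.126, gray_matter = 0.275, csf = 1.654,
    bone = 0.01, scalp = 0.465, eyes = 0.5)
}

#' Magnitude of a vector field, scaled to device current
#'
#' Per voxel, the Euclidean norm of the 3 field components times the current
#' scale factor. Magnitude (not direction) is what enters all downstream
#' statistics.
#'
#' @param vector_field 4D array (nx, ny, nz, 3) of field components, V/m at
#'   the solve current.
#' @param scaling a [scaling_spec()].
#' @return 3D array of magnitudes, V/m at device current.
#' @examples
#' vf <- array(0, c(1, 1, 1, 3)); vf[1, 1, 1, ] <- c(0.3, 0.4, 0)
#' field_magnitude(vf)[1, 1, 1]  # 0.5 * 900 = 450 V/m
#' @export
field_magnitude <- function(vector_field, scaling = scaling_spec()) {
  dm <- dim(vector_field)
  if (length(dm) != 4L || dm[4] != 3L)
    stop("vector_field must be a 4D array with 3 components")
  if (any(!is.finite(vector_field)))
    stop("vector field has non-finite components")
  mag <- sqrt(vector_field[, , , 1]^2 + vector_field[, , , 2]^2 +
              vector_field[, , , 3]^2)
  array(mag * scaling$scale_factor, dim = dm[1:3])
}

#' Voxel-wise group mean and SD maps of a field stack
#'
#' @param stack an `ef_field_stack` with at least 2 subjects.
#' @return list of `ef_stat_map`s: `mean` and `sd` (sample SD, n-1
#'   denominator).
#' @export
group_maps <- function(stack) {
  n <- nrow(stack$data)
  if (n < 2L) stop("group maps need at least 2 subjects")
  mu <- colMeans(stack$data)
  ss <- colSums(stack$data^2)
  v <- pmax(0, (ss - n * mu^2) / (n - 1))
  list(mean = stat_map_like(stack, mu, "mean_field"),
       sd = stat_map_like(stack, sqrt(v), "sd_field"))
}

#' Within-subject field difference (e.g. bilateral minus right unilateral)
#'
#' For subjects simulated under two electrode placements, forms the paired
#' per-voxel difference `a - b` so that each subject is their own control;
#' positive values mark voxels where the first placement's field is larger.
#'
#' @param stack_a,stack_b `ef_field_stack`s with identical subjects (same
#'   order), grid and mask.
#' @return an `ef_field_stack` of signed differences.
#' @export
paired_difference <- function(stack_a, stack_b) {
  if (!identical(stack_a$subject_ids, stack_b$subject_ids))
    stop("paired stacks must have identical subjects in identical order")
  stop_if_grid_mismatch(stack_b$grid, stack_a$grid, "second stack")
  if (!identical(stack_a$mask, stack_b$mask))
    stop("paired stacks must share one mask")
  new_field_stack(stack_a$data - stack_b$data, stack_a$mask, stack_a$grid,
                  stack_a$subject_ids, nonnegative = FALSE)
}
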
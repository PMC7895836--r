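#' Read a NIfTI volume with its grid
#'
#' Reads a 3D volume (field magnitude, mask, statistic map) or a 4D vector
#' field with exactly 3 components in the 4th axis. The sform affine is
#' preferred over the quaternion form because it can carry the full linear
#' part.
#'
#' @param path path to a NIfTI-1/2 file (optionally gzipped).
#' @param expect_grid optional `ef_grid`; if given, the file's grid must be
#'   identical (shape bitwise, affine within 1e-6) or an error is raised —
#'   the guard against non-co-registered subjects.
#' @return list with `values` (3D or 4D array, file order) and `grid`.
#' @export
read_volume <- function(path, expect_grid = NULL) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (!(length(dm) == 3L || (length(dm) == 4L && dm[4] == 3L)))
    stop("expected a 3D volume or a 4D vector field with 3 components: ",
         path)
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   imagedim = NULL, code = NULL)
  grid <- ef_grid(dm[1:3], matrix(as.numeric(aff), 4, 4))
  if (!is.null(expect_grid)) stop_if_grid_mismatch(grid, expect_grid, path)
  list(values = array(as.numeric(img), dim = dm), grid = grid)
}

#' Write a volume array to NIfTI
#'
#' @param values 3D or 4D numeric array.
#' @param grid `ef_grid` giving the affine for the first three axes.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path) {
  dm <- dim(values)
  if (is.null(dm) || !(length(dm) %in% c(3L, 4L)))
    stop("values must be a 3D or 4D array")
  if (!identical(as.integer(dm[1:3]), grid$shape))
    stop("array dimensions do not match grid shape")
  img <- RNifti::asNifti(values)
  vox <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- if (length(dm) == 4L) c(vox, 1) else vox
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble per-subject magnitude volumes into an analysis stack
#'
#' The stack is the unit of analysis: an n_subjects x n_voxels matrix of
#' field magnitudes restricted to an analysis mask, all on one grid. Columns
#' are ordered lexicographically by 0-based voxel index (i, then j, then k).
#'
#' @param paths character vector of NIfTI paths (3D magnitude volumes), or a
#'   list of arrays when volumes are already in memory (then `grid` must be
#'   given).
#' @param mask_policy `"explicit"` (default; supply `mask`) or
#'   `"intersection_nonzero"`, which keeps voxels strictly positive in every
#'   subject.
#' @param mask explicit mask: a NIfTI path or a logical/0-1 array on the
#'   same grid. Required for the explicit policy.
#' @param subject_ids optional unique identifiers; defaults to file basenames
#'   or `S1..Sn`.
#' @param grid required when `paths` is a list of arrays.
#' @return An `ef_field_stack`: list with `data` (subjects x masked voxels),
#'   `grid`, `mask` (logical 3D array), `voxel_index` (masked column ->
#'   0-based (i,j,k)), `subject_ids`.
#' @export
build_stack <- function(paths, mask_policy = c("explicit",
                                               "intersection_nonzero"),
                        mask = NULL, subject_ids = NULL, grid = NULL) {
  mask_policy <- match.arg(mask_policy)
  from_files <- is.character(paths)
  n <- length(paths)
  if (n < 2L) stop("a stack needs at least 2 subjects")
  vols <- vector("list", n)
  for (s in seq_len(n)) {
    if (from_files) {
      v <- read_volume(paths[[s]], expect_grid = grid)
      if (is.null(grid)) grid <- v$grid
      vols[[s]] <- v$values
    } else {
      if (is.null(grid)) stop("grid must be supplied with in-memory arrays")
      vols[[s]] <- paths[[s]]
    }
    if (length(dim(vols[[s]])) != 3L)
      stop("stacks are built from 3D magnitude volumes; convert vector ",
           "fields with field_magnitude() first")
  }
  if (is.null(subject_ids))
    subject_ids <- if (from_files) basename(unlist(paths))
                   else paste0("S", seq_len(n))

  if (mask_policy == "explicit") {
    if (is.null(mask)) stop("explicit mask_policy requires a mask")
    if (is.character(mask)) {
      m <- read_volume(mask, expect_grid = grid)
      mask <- m$values
    }
    if (!identical(as.integer(dim(mask)), grid$shape))
      stop("mask is not on the stack grid")
    mask <- array(as.logical(mask != 0), dim = grid$shape)
  } else {
    mask <- array(TRUE, dim = grid$shape)
    for (s in seq_len(n)) mask <- mask & (vols[[s]] > 0)
  }
  if (!any(mask)) stop("analysis mask is empty")

  idx <- which(mask, arr.ind = TRUE) - 1L          # 0-based triples
  ord <- order(idx[, 1], idx[, 2], idx[, 3])       # (i,j,k) lexicographic
  idx <- idx[ord, , drop = FALSE]
  lin <- linear_index(grid, idx)
  data <- matrix(NA_real_, n, nrow(idx))
  for (s in seq_len(n)) {
    vals <- vols[[s]][lin]
    if (any(!is.finite(vals)))
      stop("non-finite voxel inside the mask for subject ", subject_ids[s])
    data[s, ] <- vals
  }
  new_field_stack(data, mask, grid, subject_ids)
}

# Internal constructor; nonnegative = FALSE for difference stacks.
new_field_stack <- function(data, mask, grid, subject_ids,
                            nonnegative = TRUE) {
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (nrow(data) != length(subject_ids))
    stop("data rows and subject_ids differ in length")
  if (any(!is.finite(data))) stop("stack data must be finite")
  if (nonnegative && any(data < 0))
    stop("field magnitudes must be nonnegative")
  idx <- which(mask, arr.ind = TRUE) - 1L
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  if (ncol(data) != nrow(idx))
    stop("data columns do not match mask voxel count")
  structure(list(data = data, grid = grid, mask = mask,
                 voxel_index = unname(idx),
                 linear_index = linear_index(grid, idx),
                 subject_ids = as.character(subject_ids)),
            class = "ef_field_stack")
}

#' @export
print.ef_field_stack <- function(x, ...) {
  cat("<ef_field_stack> ", nrow(x$data), " subjects x ", ncol(x$data),
      " masked voxels on ", paste(x$grid$shape, collapse = "x"),
      " grid\n", sep = "")
  invisible(x)
}

# Per-voxel statistic map on a stack's grid/mask.
new_stat_map <- function(values, grid, mask, linear_index, name = "stat") {
  stopifnot(length(values) == length(linear_index))
  structure(list(values = as.numeric(values), grid = grid, mask = mask,
                 linear_index = linear_index, name = name),
            class = "ef_stat_map")
}

stat_map_like <- function(stack, values, name = "stat") {
  new_stat_map(values, stack$grid, stack$mask, stack$linear_index, name)
}

#' @export
print.ef_stat_map <- function(x, ...) {
  cat("<ef_stat_map> '", x$name, "', ", length(x$values),
      " masked voxels, range [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Embed a masked statistic map as a dense 3D array
#'
#' @param map an `ef_stat_map`.
#' @return 3D array with map values at masked voxels and 0 elsewhere.
#' @export
as_dense <- function(map) {
  arr <- array(0, dim = map$grid$shape)
  arr[map$linear_index] <- map$values
  arr
}

#' Write a statistic map to NIfTI
#'
#' Masked values are embedded in a dense volume (0 outside the mask) with the
#' grid's affine.
#'
#' @param map an `ef_stat_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  write_volume(as_dense(map), map$grid, path)
}
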
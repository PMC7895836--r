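#' Extract significant clusters from a permutation result
#'
#' Connected components of the FWER-significant voxel set, reported the way
#' cluster tables are printed in field studies: size in mm^3, peak world
#' (MNI-like) coordinate, peak corrected p, and mean effect sizes over the
#' cluster. The peak is the member voxel with the smallest corrected p,
#' tie-broken by largest |t| and then by lexicographic voxel index.
#'
#' Effect sizes averaged over voxels selected by the significance procedure
#' are optimistically biased towards that selection; the returned table
#' carries a `selection_biased` attribute as a standing caveat.
#'
#' @param result an `ef_perm_result`.
#' @param fit optional `ef_voxel_fit` from the same analysis (supplies |t|
#'   tie-breaks and effect-size maps; defaults to `result$fit` if present).
#' @param connectivity component connectivity; defaults to the TFCE
#'   connectivity used in `result`.
#' @param direction `"positive"` (default) or `"negative"`.
#' @return data.frame of class `ef_cluster_table`, one row per cluster
#'   sorted by size descending, with columns cluster_id, n_voxels, size_mm3,
#'   peak_i/j/k (0-based), peak_x/y/z (mm), peak_p_corrected, peak_t,
#'   mean_sp_r2, mean_r2_full, label (free text, empty); attribute
#'   `label_map` holds the dense integer cluster-label volume.
#' @export
extract_clusters <- function(result, fit = result$fit, connectivity = NULL,
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (is.null(connectivity)) connectivity <- result$tfce$connectivity
  sig <- result$significant[[direction]]
  pmap <- result$p_corrected[[direction]]
  grid <- pmap$grid
  labs <- label_components(sig, connectivity)
  ncl <- max(labs)
  empty <- data.frame(cluster_id = integer(), n_voxels = integer(),
                      size_mm3 = numeric(), peak_i = integer(),
                      peak_j = integer(), peak_k = integer(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_p_corrected = numeric(),
                      peak_t = numeric(), mean_sp_r2 = numeric(),
                      mean_r2_full = numeric(), label = character())
  if (ncl == 0) {
    attr(empty, "label_map") <- labs
    attr(empty, "selection_biased") <- TRUE
    class(empty) <- c("ef_cluster_table", class(empty))
    return(empty)
  }
  # per masked voxel: its label, p, t, effect sizes
  vlab <- labs[pmap$linear_index]
  tvals <- if (!is.null(fit)) fit$t_map$values else
    result$observed_t$values
  rows <- lapply(seq_len(ncl), function(cl) {
    mem <- which(vlab == cl)
    idx3 <- which_voxels(pmap, mem)
    ord <- order(pmap$values[mem], -abs(tvals[mem]),
                 idx3[, 1], idx3[, 2], idx3[, 3])
    pk <- mem[ord[1]]
    pk3 <- which_voxels(pmap, pk)
    world <- voxel_to_world(grid, pk3)
    data.frame(cluster_id = cl, n_voxels = length(mem),
               size_mm3 = length(mem) * grid$voxel_volume,
               peak_i = pk3[1], peak_j = pk3[2], peak_k = pk3[3],
               peak_x = world[1], peak_y = world[2], peak_z = world[3],
               peak_p_corrected = pmap$values[pk],
               peak_t = tvals[pk],
               mean_sp_r2 = if (!is.null(fit))
                 mean(fit$sp_r2_map$values[mem]) else NA_real_,
               mean_r2_full = if (!is.null(fit))
                 mean(fit$r2_full_map$values[mem]) else NA_real_,
               label = "")
  })
  tab <- do.call(rbind, rows)
  ord_cl <- order(-tab$n_voxels, tab$cluster_id)    # size descending
  tab <- tab[ord_cl, , drop = FALSE]
  old_id <- tab$cluster_id
  tab$cluster_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  # relabel the map to match the size-sorted ids
  relab <- array(0L, dim = dim(labs))
  for (r in seq_len(nrow(tab))) relab[labs == old_id[r]] <- r
  attr(tab, "label_map") <- relab
  attr(tab, "membership") <- lapply(seq_len(nrow(tab)), function(r)
    which(relab[pmap$linear_index] == r))
  attr(tab, "selection_biased") <- TRUE
  class(tab) <- c("ef_cluster_table", class(tab))
  tab
}

# 0-based (i,j,k) triples of masked-column indices of a stat map
which_voxels <- function(map, cols) {
  lin <- map$linear_index[cols] - 1L
  nx <- map$grid$shape[1]; ny <- map$grid$shape[2]
  cbind(lin %% nx, (lin %/% nx) %% ny, lin %/% (nx * ny))
}

#' @export
print.ef_cluster_table <- function(x, ...) {
  cat("<ef_cluster_table> ", nrow(x), " significant cluster(s)\n", sep = "")
  if (nrow(x))
    print.data.frame(x[, c("cluster_id", "n_voxels", "size_mm3", "peak_x",
                           "peak_y", "peak_z", "peak_p_corrected",
                           "mean_sp_r2", "mean_r2_full")], digits = 4)
  cat("note: effect sizes are computed on voxels selected for significance",
      "\nand are optimistically biased towards that selection\n")
  invisible(x)
}

#' Effect-size summary and adjusted scatter data for one cluster
#'
#' Averages the fit's R^2 and semi-partial R^2 maps over the cluster's
#' member voxels, and produces the covariate-adjusted scatter pairs (mean
#' cluster field vs outcome, both residualized on the covariates) used for
#' visualization.
#'
#' @param clusters an `ef_cluster_table` from [extract_clusters()].
#' @param cluster_id which cluster (row) to summarize.
#' @param stack the analysis `ef_field_stack`.
#' @param cohort the (imputed) cohort data.frame.
#' @param design the [design_spec()] of the analysis.
#' @param fit the `ef_voxel_fit` of the analysis.
#' @return list with `mean_sp_r2`, `mean_r2_full`, `mean_field_per_subject`
#'   and `scatter` (data.frame of adjusted pairs).
#' @export
cluster_effect_summary <- function(clusters, cluster_id, stack, cohort,
                                   design, fit) {
  mem <- attr(clusters, "membership")[[cluster_id]]
  if (is.null(mem)) stop("cluster membership not available")
  mf <- rowMeans(stack$data[, mem, drop = FALSE])
  y <- cohort[[design$outcome]]
  covs <- if (length(design$covariates))
    cohort[, design$covariates, drop = FALSE] else NULL
  list(mean_sp_r2 = mean(fit$sp_r2_map$values[mem]),
       mean_r2_full = mean(fit$r2_full_map$values[mem]),
       mean_field_per_subject = setNames(mf, stack$subject_ids),
       scatter = residualize_pair(mf, y, covs,
                                  design$include_intercept))
}
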
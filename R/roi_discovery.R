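# Two-phase ROI discovery on a reference image: equal-width intensity
# binning of masked voxels, then spatial mixture clustering (with model
# selection) inside each bin. Clusters are therefore homogeneous in
# intensity by construction and geometrically compact by the spatial fit.

#' Equal-width intensity bins of masked voxels
#'
#' Bin edges are equally spaced over the min-max range of masked
#' intensities; intervals are half-open on the right except the last, which
#' is closed so the maximum value belongs to the final bin. Empty bins are
#' retained (with zero voxels) so bin indices are stable. A constant image
#' degenerates to a single bin holding every masked voxel.
#'
#' @param reference 3D numeric array (typically the mean normal-control
#'   image).
#' @param mask Logical 3D array of brain voxels.
#' @param n_bins Number of bins (>= 1).
#' @return An object of class `intensity_bins`: a list with `edges`,
#'   `n_bins`, `width`, and `bins`, where each bin is a list with `index`,
#'   `lo`, `hi`, `coords` (n x 3 integer matrix of 1-based voxel indices)
#'   and `intensity`.
#' @export
make_bins <- function(reference, mask, n_bins) {
  stop_if_not_volume(reference)
  if (!identical(dim(reference), dim(mask)))
    stop("mask shape mismatch", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  coords <- voxel_coords(mask)
  if (!nrow(coords)) stop("empty mask", call. = FALSE)
  vals <- reference[mask]
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) {
    bins <- list(list(index = 1L, lo = lo, hi = hi, coords = coords,
                      intensity = vals))
    return(structure(list(edges = c(lo, hi), n_bins = 1L, width = 0,
                          bins = bins, constant = TRUE),
                     class = "intensity_bins"))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  bins <- lapply(seq_len(n_bins), function(b) {
    sel <- idx == b
    list(index = b, lo = edges[b], hi = edges[b + 1L],
         coords = coords[sel, , drop = FALSE], intensity = vals[sel])
  })
  structure(list(edges = edges, n_bins = n_bins,
                 width = (hi - lo) / n_bins, bins = bins, constant = FALSE),
            class = "intensity_bins")
}

#' Candidate component-count range for a bin
#'
#' Clusters are required to hold at most 1000 and at least 30 voxels; the
#' candidate number of components for a bin of `n_voxels` voxels is
#' therefore the integer interval from `ceiling(n_voxels / 1000)` up to
#' `floor(n_voxels / 30)` (floored at 1). Bins too small to support more
#' than one admissible cluster get the degenerate range (1, 1).
#'
#' @param n_voxels Number of voxels in the bin (>= 1).
#' @param max_size,min_size Cluster size bounds (defaults 1000 and 30).
#' @return Integer vector `c(k_min, k_max)`.
#' @export
k_range <- function(n_voxels, max_size = 1000L, min_size = 30L) {
  if (n_voxels < 1) stop("n_voxels must be >= 1", call. = FALSE)
  k_min <- max(1L, as.integer(ceiling(n_voxels / max_size)))
  k_max <- max(1L, as.integer(floor(n_voxels / min_size)))
  if (k_max < k_min) return(c(1L, 1L))
  c(k_min, k_max)
}

#' Cluster one intensity bin spatially
#'
#' Fits Gaussian mixtures to the bin's voxel (x, y, z) coordinates over the
#' [k_range()] of admissible component counts, selects K by the criterion,
#' and hard-assigns each voxel to its maximum-posterior component. A bin
#' whose range degenerates to (1, 1) — or whose fits all fail — becomes a
#' single cluster (the latter with a warning).
#'
#' @param bin A single bin from [make_bins()].
#' @param criterion `"bic"` or `"aic"`.
#' @param seed Integer seed.
#' @param k_stride Stride through the candidate-K interval (default 1:
#'   every integer K is scanned).
#' @param ... Passed to [select_k()].
#' @return List of clusters; each is a list with `bin_index`,
#'   `component_index`, `coords`, and `intensity`.
#' @export
cluster_bin <- function(bin, criterion = "bic", seed = 1L, k_stride = 1L,
                        ...) {
  n <- nrow(bin$coords)
  if (!n) stop("empty bin", call. = FALSE)
  one_cluster <- function() list(list(bin_index = bin$index,
                                      component_index = 1L,
                                      coords = bin$coords,
                                      intensity = bin$intensity,
                                      chosen_k = 1L))
  kr <- k_range(n)
  if (kr[2L] <= 1L) return(one_cluster())
  kg <- unique(c(seq(kr[1L], kr[2L], by = as.integer(k_stride)), kr[2L]))
  kg <- kg[kg <= n]
  X <- matrix(as.double(bin$coords), ncol = 3L)
  sel <- tryCatch(select_k(X, kg, criterion = criterion, seed = seed, ...),
                  error = function(e) {
                    warning(sprintf("bin %d falls back to one cluster: %s",
                                    bin$index, conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
  if (is.null(sel)) return(one_cluster())
  fit <- sel$fits[[match(sel$chosen_k, sel$k_grid)]]
  lab <- assign_labels(X, fit$params)
  keep <- sort(unique(lab))
  lapply(seq_along(keep), function(j) {
    s <- lab == keep[j]
    list(bin_index = bin$index, component_index = keep[j],
         coords = bin$coords[s, , drop = FALSE],
         intensity = bin$intensity[s], chosen_k = sel$chosen_k)
  })
}

#' Discover whole-brain clusters on a reference image
#'
#' Bins the masked voxels of the reference image by intensity, clusters
#' every non-empty bin spatially with mixture model selection, and collects
#' all resulting clusters. The clusters exactly partition the mask.
#'
#' @inheritParams make_bins
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param seed Integer seed; each bin receives a derived sub-seed, so the
#'   result is deterministic.
#' @param k_stride Passed to [cluster_bin()].
#' @param ... Passed to [select_k()].
#' @return An object of class `cluster_map`: `n_bins`, `criterion`, `seed`,
#'   `shape`, `bin_edges`, `chosen_k` (per non-empty bin), and `clusters`
#'   (each with `id`, `bin_index`, `component_index`, `coords`, `idx`
#'   linear indices, `intensity`).
#' @export
discover_clusters <- function(reference, mask, n_bins, criterion = c("bic", "aic"),
                              seed = 1L, k_stride = 1L, ...) {
  criterion <- match.arg(criterion)
  binning <- make_bins(reference, mask, n_bins)
  shape <- dim(reference)
  clusters <- list()
  chosen_k <- integer(0)
  for (bin in binning$bins) {
    if (!nrow(bin$coords)) next  # empty bin: skipped, indices stay stable
    cl <- cluster_bin(bin, criterion = criterion,
                      seed = derive_seed(seed, bin$index),
                      k_stride = k_stride, ...)
    chosen_k[as.character(bin$index)] <- cl[[1L]]$chosen_k
    clusters <- c(clusters, cl)
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i
    clusters[[i]]$idx <- linear_index(clusters[[i]]$coords, shape)
  }
  structure(list(n_bins = as.integer(n_bins), criterion = criterion,
                 seed = seed, shape = shape, bin_edges = binning$edges,
                 bin_width = binning$width, chosen_k = chosen_k,
                 clusters = clusters),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) nrow(cl$coords), integer(1))
  cat(sprintf(
    "Cluster map: %d clusters from %d intensity bins (%s, seed %d)\n",
    length(x$clusters), x$n_bins, toupper(x$criterion), x$seed))
  cat(sprintf("  %d voxels, cluster sizes %d..%d (median %.0f)\n",
              sum(sizes), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' @export
summary.cluster_map <- function(object, ...) {
  print(object)
  sizes <- vapply(object$clusters, function(cl) nrow(cl$coords), integer(1))
  bins <- vapply(object$clusters, function(cl) cl$bin_index, integer(1))
  tab <- data.frame(bin = sort(unique(bins)),
                    clusters = as.integer(table(bins)),
                    voxels = as.integer(tapply(sizes, bins, sum)))
  print(tab, row.names = FALSE)
  invisible(object)
}

#' Render a cluster map as a label volume
#'
#' @param map A `cluster_map`.
#' @return 3D integer array: 0 outside clusters, otherwise the cluster id.
#' @export
cluster_map_volume <- function(map) {
  out <- array(0L, dim = map$shape)
  for (cl in map$clusters) out[cl$idx] <- cl$id
  out
}

#' Write a cluster map as TSV (one voxel per row) plus a JSON sidecar
#'
#' @param map A `cluster_map`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cluster_map <- function(map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(map$clusters, function(cl)
    data.frame(cluster_id = cl$id, bin_index = cl$bin_index,
               x = cl$coords[, 1L], y = cl$coords[, 2L],
               z = cl$coords[, 3L])))
  utils::write.table(rows, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- sprintf(
    '{"n_bins": %d, "criterion": "%s", "seed": %d, "n_clusters": %d, "chosen_k": {%s}}',
    map$n_bins, map$criterion, map$seed, length(map$clusters),
    paste(sprintf('"%s": %d', names(map$chosen_k), map$chosen_k),
          collapse = ", "))
  writeLines(meta, file.path(dir, "clusters.json"))
  invisible(dir)
}

#' Number of discovered clusters as a function of the bin count
#'
#' Diagnostic curve: runs the discovery once per grid point and tabulates
#' the resulting cluster counts. The count generally decreases as bins grow
#' finer, since small bins fall below the minimum cluster size and collapse
#' to single clusters.
#'
#' @inheritParams discover_clusters
#' @param bin_grid Integer vector of bin counts (default 50 to 150 by 10).
#' @return `data.frame` with columns `n_bins` and `n_clusters`.
#' @export
cluster_count_curve <- function(reference, mask,
                                bin_grid = seq(50L, 150L, by = 10L),
                                criterion = "bic", seed = 1L, ...) {
  if (!length(bin_grid)) stop("bin_grid is empty", call. = FALSE)
  counts <- vapply(bin_grid, function(b) {
    length(discover_clusters(reference, mask, b, criterion = criterion,
                             seed = seed, ...)$clusters)
  }, integer(1))
  data.frame(n_bins = as.integer(bin_grid), n_clusters = counts)
}
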
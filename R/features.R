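# Per-subject feature extraction over discovered clusters or atlas regions,
# feature ranking, and the voxel-wise t-test baseline.

.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Cluster mean/SD features of a subject volume
#'
#' For every cluster in the map, the mean and sample standard deviation
#' (n - 1 denominator; 0 for singleton clusters) of the subject's
#' intensities at the cluster's voxels. Feature order is cluster by
#' cluster, mean before SD, so a map with M clusters yields a 2M-vector.
#'
#' @param v 3D numeric array with the map's shape.
#' @param map A `cluster_map` from [discover_clusters()].
#' @return Named numeric vector of length `2 * length(map$clusters)`.
#' @export
extract_features <- function(v, map) {
  stop_if_not_volume(v)
  if (!identical(dim(v), map$shape))
    stop("volume shape does not match the cluster map", call. = FALSE)
  out <- numeric(2L * length(map$clusters))
  nms <- character(length(out))
  for (i in seq_along(map$clusters)) {
    vals <- v[map$clusters[[i]]$idx]
    out[2L * i - 1L] <- mean(vals)
    out[2L * i] <- .sd0(vals)
    id <- map$clusters[[i]]$id
    nms[2L * i - 1L] <- sprintf("cluster%d_mean", id)
    nms[2L * i] <- sprintf("cluster%d_sd", id)
  }
  stats::setNames(out, nms)
}

#' Atlas-region mean/SD features of a subject volume
#'
#' The anatomical baseline: mean and sample SD per atlas region, in
#' ascending region-code order (116 regions give a 232-vector). A region
#' with no voxels yields the pair (0, 0) with a warning.
#'
#' @param v 3D numeric array with the atlas shape.
#' @param atlas A [brain_atlas].
#' @return Named numeric vector of length `2 * n_regions`.
#' @export
atlas_features <- function(v, atlas) {
  stop_if_not_volume(v)
  stopifnot(inherits(atlas, "brain_atlas"))
  if (!identical(dim(v), dim(atlas$labels)))
    stop("volume shape does not match the atlas", call. = FALSE)
  codes <- sort(as.integer(names(atlas$names)))
  out <- numeric(2L * length(codes))
  nms <- character(length(out))
  for (i in seq_along(codes)) {
    vals <- v[atlas$labels == codes[i]]
    if (!length(vals)) {
      warning(sprintf("atlas region %d ('%s') has no voxels; features set to 0",
                      codes[i], atlas$names[[as.character(codes[i])]]),
              call. = FALSE)
      vals <- numeric(0)
      out[2L * i - 1L] <- 0
      out[2L * i] <- 0
    } else {
      out[2L * i - 1L] <- mean(vals)
      out[2L * i] <- .sd0(vals)
    }
    rn <- atlas$names[[as.character(codes[i])]]
    nms[2L * i - 1L] <- paste0(rn, "_mean")
    nms[2L * i] <- paste0(rn, "_sd")
  }
  stats::setNames(out, nms)
}

#' Feature matrix for a list of subject volumes
#'
#' @param volumes List of 3D arrays.
#' @param map_or_atlas A `cluster_map` or a [brain_atlas].
#' @return Numeric matrix, one row per subject.
#' @export
feature_matrix <- function(volumes, map_or_atlas) {
  f <- if (inherits(map_or_atlas, "brain_atlas")) atlas_features else
    extract_features
  t(vapply(volumes, f, numeric(length(f(volumes[[1L]], map_or_atlas))),
           map_or_atlas))
}

# Vectorized two-sample pooled-variance t statistics and p-values for the
# rows of two matrices (rows = variables, columns = subjects). Zero pooled
# variance: equal means give p = 1; unequal means fall back to a variance
# floor so the variable still dominates the ranking.
.row_ttest <- function(A, B, var_floor = 1e-12) {
  na <- ncol(A); nb <- ncol(B)
  ma <- .rowMeans(A, nrow(A), na)
  mb <- .rowMeans(B, nrow(B), nb)
  va <- .rowSums((A - ma)^2, nrow(A), na) / (na - 1)
  vb <- .rowSums((B - mb)^2, nrow(B), nb) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  zero <- sp2 <= 0
  sp2[zero] <- var_floor
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & ma == mb] <- 1
  t[zero & ma == mb] <- 0
  list(t = t, p = p)
}

#' Voxel-wise two-sample t-test feature selection (baseline)
#'
#' Mass-univariate baseline: an equal-variance two-tailed t-test at every
#' masked voxel, no multiple-comparison correction. Voxels with p below
#' `alpha` are kept and the `top_m` lowest-p voxels among them returned;
#' their raw intensities serve as the baseline's features.
#'
#' @param volumes_a,volumes_b Lists of 3D arrays (>= 2 per group).
#' @param mask Logical 3D array.
#' @param alpha Significance threshold (default 0.001).
#' @param top_m Maximum number of voxels kept (default 150).
#' @return `data.frame` with columns `x`, `y`, `z`, `t`, `p`, ordered by
#'   increasing p. May have zero rows if nothing passes `alpha`.
#' @export
ttest_voxel_selection <- function(volumes_a, volumes_b, mask,
                                  alpha = 0.001, top_m = 150L) {
  if (length(volumes_a) < 2L || length(volumes_b) < 2L)
    stop("need at least two subjects per group", call. = FALSE)
  coords <- voxel_coords(mask)
  A <- vapply(volumes_a, function(v) v[mask], numeric(nrow(coords)))
  B <- vapply(volumes_b, function(v) v[mask], numeric(nrow(coords)))
  tt <- .row_ttest(A, B)
  keep <- which(tt$p < alpha)
  keep <- keep[order(tt$p[keep])]
  keep <- utils::head(keep, top_m)
  data.frame(x = coords[keep, 1L], y = coords[keep, 2L],
             z = coords[keep, 3L], t = tt$t[keep], p = tt$p[keep])
}

# Information gain of the best single threshold split of x w.r.t. binary y.
.best_split_gain <- function(x, y01) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y01[ord]
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  ent <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
  h0 <- ent(n1 / n)
  cut_ok <- which(diff(xs) > 0)
  if (!length(cut_ok)) return(0)
  nl <- cut_ok
  pl <- cum1[cut_ok] / nl
  pr <- (n1 - cum1[cut_ok]) / (n - nl)
  gain <- h0 - (nl / n) * ent(pl) - ((n - nl) / n) * ent(pr)
  max(gain)
}

#' Rank features by univariate relevance on training rows
#'
#' Default score is the absolute two-sample (pooled-variance) t statistic
#' of each feature between the two classes; `"infogain"` scores each
#' feature by the information gain of its best single-threshold split.
#' Constant features score 0 and rank last. Only the rows passed in are
#' used, so ranking on training rows can never leak test information.
#'
#' @param values N x F feature matrix (training rows only).
#' @param labels Length-N class labels (exactly two classes).
#' @param method `"tstat"` (default) or `"infogain"`.
#' @return An object of class `feature_ranking`: `order` (a permutation of
#'   all feature indices, most relevant first), `scores` (non-increasing),
#'   and `method`.
#' @export
rank_features <- function(values, labels, method = c("tstat", "infogain")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("feature ranking requires exactly two classes", call. = FALSE)
  a <- labels == levels(labels)[1L]
  if (method == "tstat") {
    tt <- .row_ttest(t(values[a, , drop = FALSE]),
                     t(values[!a, , drop = FALSE]))
    score <- abs(tt$t)
    const <- apply(values, 2, function(col) length(unique(col)) == 1L)
    score[const] <- 0
  } else {
    y01 <- as.integer(labels == levels(labels)[2L])
    score <- apply(values, 2, .best_split_gain, y01 = y01)
  }
  ord <- order(-score)  # stable: ties keep original feature order
  structure(list(order = ord, scores = score[ord], method = method,
                 feature_names = colnames(values)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("Feature ranking (%s) over %d features; top scores: %s\n",
              x$method, length(x$order),
              paste(sprintf("%.3g", utils::head(x$scores, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Keep the top-m features of a ranking
#'
#' @param ranking A `feature_ranking`.
#' @param m Number of features to keep (clipped to the total with a
#'   warning). Typical values: 150 with BIC-selected clusters, 400 with
#'   AIC-selected ones.
#' @return Integer vector of the first `m` ranked feature indices.
#' @export
select_top_m <- function(ranking, m) {
  stopifnot(inherits(ranking, "feature_ranking"))
  total <- length(ranking$order)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (m > total) {
    warning(sprintf("m = %d exceeds the %d available features; clipped",
                    m, total), call. = FALSE)
    m <- total
  }
  ranking$order[seq_len(m)]
}
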
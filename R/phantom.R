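# Seeded synthetic data: mixture point clouds for the clustering core, and
# multi-region brain phantoms with planted regional hypometabolism for the
# full pipeline.

#' Sample a Gaussian-mixture point cloud
#'
#' @param K Number of components.
#' @param weights Length-K mixing proportions (summing to 1).
#' @param means K x D matrix of component means.
#' @param covs D x D x K array (or list of K matrices) of covariances.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return List with `X` (n x D matrix) and `labels` (true component of
#'   each point).
#' @export
gmm_point_cloud <- function(K, weights, means, covs, n, seed = 1L) {
  means <- as.matrix(means)
  d <- ncol(means)
  stopifnot(length(weights) == K, nrow(means) == K,
            abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  if (is.list(covs)) covs <- array(unlist(covs), dim = c(d, d, K))
  chols <- lapply(seq_len(K), function(k)
    tryCatch(chol(covs[, , k]), error = function(e)
      stop(sprintf("component %d covariance is not positive definite", k),
           call. = FALSE)))
  with_seed(seed, {
    lab <- sample.int(K, n, replace = TRUE, prob = weights)
    X <- matrix(stats::rnorm(n * d), n, d)
    for (k in seq_len(K)) {
      s <- lab == k
      if (any(s))
        X[s, ] <- X[s, , drop = FALSE] %*% chols[[k]] +
          matrix(means[k, ], sum(s), d, byrow = TRUE)
    }
    list(X = X, labels = lab)
  })
}

#' Specification of a synthetic brain phantom
#'
#' Describes an ellipsoidal "brain" partitioned into contiguous regions by
#' a seeded Voronoi tessellation, with a constant baseline uptake per
#' region, group-specific fractional intensity reductions (hypometabolism)
#' planted in chosen regions, i.i.d. Gaussian voxel noise, and an optional
#' Gaussian blur that induces the spatial correlation real smoothing
#' produces.
#'
#' Defaults encode the simulation regime the package is validated under:
#' 12 regions on a 20 x 24 x 20 grid, 2 affected regions, effects of -7%
#' (MCI-like) and -15% (AD-like), and voxel noise with SD equal to 10% of
#' the local baseline.
#'
#' @param shape Volume dimensions (3 positive integers).
#' @param n_regions Number of atlas regions.
#' @param n_affected Number of affected (hypometabolic) regions; the
#'   regions themselves are drawn from the spec seed.
#' @param effect Named fractional intensity reductions per group, in
#'   `[0, 1)`; the NC effect is 0 by construction.
#' @param noise_sd Voxel noise SD as a fraction of the local baseline.
#' @param baseline_range Range the per-region baseline uptakes are drawn
#'   from (relative-uptake units, so centred near 1).
#' @param blur_sigma Gaussian blur SD in voxels (0 disables blurring).
#' @param seed Integer seed controlling geometry, baselines and affected
#'   regions.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(20L, 24L, 20L), n_regions = 12L,
                         n_affected = 2L,
                         effect = c(NC = 0, MCI = 0.07, AD = 0.15),
                         noise_sd = 0.10, baseline_range = c(0.7, 1.3),
                         blur_sigma = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 4L), n_regions >= 1L,
            n_affected >= 0L, n_affected <= n_regions,
            all(effect >= 0), all(effect < 1), noise_sd >= 0,
            all(baseline_range > 0), blur_sigma >= 0)
  if (is.null(names(effect)) || !"NC" %in% names(effect))
    stop("'effect' must be a named vector including an NC entry", call. = FALSE)
  if (effect[["NC"]] != 0)
    stop("the NC group must have zero effect", call. = FALSE)
  structure(list(shape = as.integer(shape), n_regions = as.integer(n_regions),
                 n_affected = as.integer(n_affected), effect = effect,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Phantom spec: %s grid, %d regions (%d affected), noise SD %.0f%%, seed %d\n",
    paste(x$shape, collapse = "x"), x$n_regions, x$n_affected,
    100 * x$noise_sd, x$seed))
  cat("  effects:", paste(sprintf("%s %.0f%%", names(x$effect),
                                  -100 * x$effect), collapse = ", "), "\n")
  invisible(x)
}

# Ellipsoidal mask centred in the grid; semi-axes leave a 2-voxel margin.
.ellipsoid_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- pmax((shape - 4) / 2, 1)
  x <- ((seq_len(shape[1L]) - ctr[1L]) / ax[1L])^2
  y <- ((seq_len(shape[2L]) - ctr[2L]) / ax[2L])^2
  z <- ((seq_len(shape[3L]) - ctr[3L]) / ax[3L])^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  r2 <= 1
}

#' Build the phantom atlas, mask and baseline volume
#'
#' The ellipsoidal mask is partitioned into `n_regions` contiguous regions
#' by a Voronoi tessellation of randomly chosen interior sites (distance
#' ties break toward the lower region index); each region gets a constant
#' baseline uptake drawn from `baseline_range`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `atlas` (a [brain_atlas]), `mask`, `baseline`
#'   (3D array, 0 outside the mask), `baselines` (per-region values) and
#'   `affected` (names of the affected regions).
#' @export
make_atlas_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- .ellipsoid_mask(spec$shape)
  coords <- voxel_coords(mask)
  if (spec$n_regions > nrow(coords))
    stop("more regions than mask voxels", call. = FALSE)
  with_seed(derive_seed(spec$seed, 1L), {
    sites <- coords[sample.int(nrow(coords), spec$n_regions), , drop = FALSE]
    d2 <- matrix(0, nrow(coords), spec$n_regions)
    for (k in seq_len(spec$n_regions))
      d2[, k] <- (coords[, 1L] - sites[k, 1L])^2 +
        (coords[, 2L] - sites[k, 2L])^2 + (coords[, 3L] - sites[k, 3L])^2
    region <- max.col(-d2, ties.method = "first")
    labels <- array(0L, dim = spec$shape)
    labels[mask] <- region
    baselines <- stats::runif(spec$n_regions, spec$baseline_range[1L],
                              spec$baseline_range[2L])
    affected_codes <- if (spec$n_affected > 0L)
      sort(sample.int(spec$n_regions, spec$n_affected)) else integer(0)
    nm <- stats::setNames(sprintf("Region_%02d", seq_len(spec$n_regions)),
                          seq_len(spec$n_regions))
    baseline <- array(0, dim = spec$shape)
    baseline[mask] <- baselines[region]
    list(atlas = brain_atlas(labels, nm), mask = mask, baseline = baseline,
         baselines = baselines, affected = unname(nm[affected_codes]),
         affected_codes = affected_codes)
  })
}

# Separable 3D Gaussian blur with replicated edges.
.gauss_blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    out <- array(0, dim = dim(a))
    n <- dim(a)[axis]
    for (off in seq(-r, r)) {
      w <- k[off + r + 1L]
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      idx <- switch(axis, `1` = list(src, TRUE, TRUE),
                    `2` = list(TRUE, src, TRUE),
                    `3` = list(TRUE, TRUE, src))
      out <- out + w * a[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    }
    out
  }
  conv_axis(conv_axis(conv_axis(arr, 1L), 2L), 3L)
}

#' Simulate one phantom subject volume
#'
#' Baseline uptake, reduced by the group's fractional effect in the
#' affected regions, plus i.i.d. Gaussian voxel noise with SD proportional
#' to the local baseline, then optional Gaussian blur.
#'
#' @param spec A [phantom_spec()].
#' @param group Group name; must appear in `spec$effect` (e.g. `"NC"`,
#'   `"MCI"`, `"AD"`).
#' @param seed Integer seed for this subject's noise.
#' @param geometry Optional precomputed [make_atlas_phantom()] result
#'   (recomputed from the spec when omitted).
#' @return 3D numeric array.
#' @export
simulate_subject <- function(spec, group, seed = 1L, geometry = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!group %in% names(spec$effect))
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  if (is.null(geometry)) geometry <- make_atlas_phantom(spec)
  v <- geometry$baseline
  eff <- spec$effect[[group]]
  if (eff > 0 && length(geometry$affected_codes)) {
    hit <- geometry$atlas$labels %in% geometry$affected_codes
    v[hit] <- v[hit] * (1 - eff)
  }
  if (spec$noise_sd > 0) {
    v <- v + with_seed(seed, array(stats::rnorm(length(v)), dim = dim(v))) *
      (spec$noise_sd * geometry$baseline)
  }
  if (spec$blur_sigma > 0) v <- .gauss_blur3d(v, spec$blur_sigma)
  v
}

#' Simulate a phantom cohort
#'
#' Independent subjects per group with seeds derived deterministically from
#' the spec seed, so the same spec always yields the same cohort and
#' distinct subjects get distinct noise.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_group Named integer vector of group sizes, e.g.
#'   `c(NC = 20, MCI = 20, AD = 20)`; names must appear in `spec$effect`.
#' @return An object of class `phantom_cohort`: `volumes`, `labels`,
#'   `spec`, `atlas`, `mask`, `baseline`, `affected` (ground-truth
#'   affected region names).
#' @export
simulate_cohort <- function(spec, n_per_group = c(NC = 20L, MCI = 20L, AD = 20L)) {
  stopifnot(inherits(spec, "phantom_spec"), all(n_per_group >= 1L))
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(spec$effect)))
    stop("n_per_group must be named with groups present in spec$effect",
         call. = FALSE)
  geometry <- make_atlas_phantom(spec)
  volumes <- list()
  labels <- character(0)
  subj <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group[[g]])) {
      subj <- subj + 1L
      volumes[[subj]] <- simulate_subject(spec, g,
                                          seed = derive_seed(spec$seed, 2L, subj),
                                          geometry = geometry)
      labels[subj] <- g
    }
  }
  names(volumes) <- sprintf("%s_%02d", labels,
                            stats::ave(seq_along(labels), labels,
                                       FUN = seq_along))
  structure(list(volumes = volumes, labels = labels, spec = spec,
                 atlas = geometry$atlas, mask = geometry$mask,
                 baseline = geometry$baseline, affected = geometry$affected),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Phantom cohort: %s (%s grid, %d regions, affected: %s)\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              paste(x$spec$shape, collapse = "x"), x$spec$n_regions,
              paste(x$affected, collapse = ", ")))
  invisible(x)
}
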
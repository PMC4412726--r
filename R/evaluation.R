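# Repeated stratified nested cross-validation of the cluster-feature
# pipeline and its two baselines, with pooled-ROC metrics, the corrected
# resampled t-test for method comparison, a weighted-distance error
# analysis, and the informative-regions report.

#' Repeated stratified k-fold cross-validation plan
#'
#' Within each repeat the folds partition the subjects and each class is
#' spread so per-class fold sizes differ by at most one. Deterministic
#' given the seed.
#'
#' @param labels Class label per subject; every class needs at least
#'   `n_folds` members.
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @return An object of class `cv_plan` with a `folds` matrix (subjects x
#'   repeats, entries in `1..n_folds`).
#' @export
stratified_folds <- function(labels, n_folds = 10L, n_repeats = 10L,
                             seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  cnt <- table(labels)
  if (any(cnt < n_folds))
    stop(sprintf("every class needs at least %d members for %d folds",
                 n_folds, n_folds), call. = FALSE)
  folds <- matrix(0L, n, n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx, r] <- rep(seq_len(n_folds), length.out = length(idx))
      }
    }
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), labels = labels,
                 seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("CV plan: %d x %d-fold stratified (%d subjects: %s; seed %d)\n",
              x$n_repeats, x$n_folds, length(x$labels),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "), x$seed))
  invisible(x)
}

# One stratified holdout split of `idx` by `labels[idx]`; both parts keep
# at least one member of every class.
.stratified_split <- function(labels, idx, frac = 0.8, seed = 1L) {
  with_seed(seed, {
    tr <- integer(0)
    for (cl in unique(labels[idx])) {
      cidx <- idx[labels[idx] == cl]
      n_tr <- max(1L, min(length(cidx) - 1L, round(frac * length(cidx))))
      tr <- c(tr, cidx[sample.int(length(cidx))][seq_len(n_tr)])
    }
    list(train = sort(tr), test = sort(setdiff(idx, tr)))
  })
}

# Standardize train/test feature blocks by training statistics.
.standardize <- function(xtr, xte) {
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  list(train = scale(xtr, ctr, scl), test = scale(xte, ctr, scl))
}

# Linear SVM scores oriented so larger means "more like the positive
# class". Signed decision values are used (rank-equivalent to calibrated
# probabilities for ROC purposes and fully deterministic).
.svm_scores <- function(fit, x, positive) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lhs <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- as.numeric(dv)
  if (!identical(lhs, positive)) score <- -score
  list(pred = as.character(pr), score = score)
}

# Stratified k-fold CV accuracy of a linear SVM at one cost value.
.cv_accuracy <- function(x, y, cost, seed, k = 5L) {
  k <- min(k, min(table(y)))
  if (k < 2L) return(NA_real_)
  plan <- stratified_folds(y, n_folds = k, n_repeats = 1L, seed = seed)
  hits <- 0L
  for (f in seq_len(k)) {
    te <- which(plan$folds[, 1L] == f)
    tr <- setdiff(seq_along(y), te)
    std <- .standardize(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    fit <- e1071::svm(x = std$train, y = y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    hits <- hits + sum(as.character(stats::predict(fit, std$test)) ==
                         as.character(y[te]))
  }
  hits / length(y)
}

#' Train a linear classifier on one fold and predict its test subjects
#'
#' Feature ranking (when `n_top` is given), cost selection and model
#' fitting use the training rows only; the held-out rows are touched once,
#' for prediction. The penalty parameter is grid-searched by stratified
#' cross-validation within the training rows (ties toward the smaller
#' cost).
#'
#' @param features Subjects x features matrix (all subjects).
#' @param labels Class label per subject (two classes).
#' @param train,test Integer row indices of the fold's training and test
#'   subjects.
#' @param cost_grid Candidate SVM penalty values (default `2^(-5), 2^(-3),
#'   ..., 2^5`).
#' @param n_top Number of top-ranked features to keep (`NULL` keeps all,
#'   e.g. for the atlas baseline).
#' @param rank_method Passed to [rank_features()].
#' @param seed Integer seed (inner splits).
#' @param positive Name of the positive (disease) class; defaults to the
#'   alphabetically second label.
#' @return An object of class `fold_result` with predictions, oriented
#'   decision scores, the chosen cost, the training-row feature ranking,
#'   and the fitted weight vector (standardized scale).
#' @export
train_eval_fold <- function(features, labels, train, test,
                            cost_grid = 2^seq(-5, 5, by = 2), n_top = NULL,
                            rank_method = "tstat", seed = 1L,
                            positive = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  ytr <- labels[train]
  if (length(unique(ytr)) < 2L)
    stop("degenerate training set: only one class present", call. = FALSE)
  lev <- sort(unique(labels[c(train, test)]))
  if (is.null(positive)) positive <- lev[length(lev)]
  lev <- c(setdiff(lev, positive), positive)

  ranking <- NULL
  cols <- seq_len(ncol(features))
  if (!is.null(n_top)) {
    ranking <- rank_features(features[train, , drop = FALSE], ytr,
                             method = rank_method)
    cols <- select_top_m(ranking, min(n_top, ncol(features)))
  }
  std <- .standardize(features[train, cols, drop = FALSE],
                      features[test, cols, drop = FALSE])
  yf <- factor(ytr, levels = lev)

  chosen_cost <- cost_grid[1L]
  if (length(cost_grid) > 1L) {
    accs <- vapply(seq_along(cost_grid), function(i)
      .cv_accuracy(std$train, yf, cost_grid[i],
                   seed = derive_seed(seed, 23L, i)), numeric(1))
    if (!all(is.na(accs)))
      chosen_cost <- cost_grid[which.max(accs)]  # ties: smaller cost
  }
  fit <- e1071::svm(x = std$train, y = yf, kernel = "linear",
                    cost = chosen_cost, scale = FALSE)
  sc <- .svm_scores(fit, std$test, positive)
  structure(list(train = train, test = test, truth = labels[test],
                 pred = sc$pred, score = sc$score,
                 chosen_cost = chosen_cost, ranking = ranking,
                 feature_cols = cols,
                 weights = drop(crossprod(fit$coefs, fit$SV)),
                 positive = positive),
            class = "fold_result")
}

#' Inner selection of the bin count on training subjects
#'
#' For each candidate bin count the training rows are split once into
#' stratified sub-training and sub-test parts — the same split for every
#' candidate — features are ranked and selected on the sub-training rows,
#' a linear SVM is fitted on them and scored on the sub-test rows; the bin
#' count with the highest sub-test accuracy wins (ties toward fewer bins).
#'
#' @param features_by_bin List of subjects x features matrices, one per
#'   candidate bin count, aligned with `bin_grid`.
#' @param labels Class label per subject.
#' @param train_idx Training-row indices (the fold's 9 folds).
#' @param bin_grid Candidate bin counts (ascending).
#' @param n_top Features kept after ranking (default 150).
#' @param cost SVM penalty used for the inner comparison.
#' @param rank_method Passed to [rank_features()].
#' @param frac Sub-training fraction (default 0.8).
#' @param seed Integer seed (controls the single shared split).
#' @return The chosen bin count, with the per-candidate inner accuracies
#'   as attribute `"accuracy"`.
#' @export
inner_select_bins <- function(features_by_bin, labels, train_idx, bin_grid,
                              n_top = 150L, cost = 1, rank_method = "tstat",
                              frac = 0.8, seed = 1L) {
  stopifnot(length(features_by_bin) == length(bin_grid),
            length(bin_grid) >= 1L)
  if (length(bin_grid) == 1L)
    return(structure(bin_grid[1L], accuracy = NA_real_))
  labels <- as.character(labels)
  split <- .stratified_split(labels, train_idx, frac = frac, seed = seed)
  accs <- vapply(features_by_bin, function(feat) {
    rec <- train_eval_fold(feat, labels, split$train, split$test,
                           cost_grid = cost, n_top = n_top,
                           rank_method = rank_method, seed = seed)
    mean(rec$pred == rec$truth)
  }, numeric(1))
  chosen <- bin_grid[which.max(accs)]  # ties: first = fewest bins
  structure(chosen, accuracy = stats::setNames(accs, bin_grid))
}

#' Pooled cross-validation AUC
#'
#' Scores from every test prediction across all repeats and folds are
#' pooled and the area under the ROC curve computed as the Mann-Whitney
#' rank statistic (ties count one half).
#'
#' @param scores Numeric prediction scores, larger meaning more
#'   positive-like.
#' @param truth True class label per score.
#' @param positive Name of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_pooled <- function(scores, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: a class is absent from the pooled scores",
         call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from pooled scores
#'
#' @inheritParams auc_pooled
#' @return `data.frame` with columns `fpr` and `tpr`.
#' @export
roc_points <- function(scores, truth, positive) {
  ord <- order(-scores)
  t <- truth[ord] == positive
  data.frame(fpr = c(0, cumsum(!t) / sum(!t)),
             tpr = c(0, cumsum(t) / sum(t)))
}

#' Summarize fold results into evaluation metrics
#'
#' Accuracy, sensitivity (true-positive rate on the disease class) and
#' specificity are aggregated by instance within each repeat and then
#' averaged over repeats; AUC is computed once from the scores pooled over
#' every repeat and fold.
#'
#' @param folds List of `fold_result` records carrying `repeat_` indices.
#' @param positive Name of the positive class.
#' @return An object of class `eval_summary` with `accuracy`, `auc`,
#'   `sensitivity`, `specificity`, a `per_repeat` data frame, and the
#'   pooled `scores`/`truth` used for the ROC.
#' @export
summarize_folds <- function(folds, positive) {
  reps <- vapply(folds, function(f) as.integer(f$repeat_), integer(1))
  truth <- unlist(lapply(folds, `[[`, "truth"))
  pred <- unlist(lapply(folds, `[[`, "pred"))
  score <- unlist(lapply(folds, `[[`, "score"))
  rep_of <- rep(reps, vapply(folds, function(f) length(f$truth), integer(1)))
  per_rep <- do.call(rbind, lapply(sort(unique(rep_of)), function(r) {
    s <- rep_of == r
    tp <- sum(pred[s] == positive & truth[s] == positive)
    fn <- sum(pred[s] != positive & truth[s] == positive)
    tn <- sum(pred[s] != positive & truth[s] != positive)
    fp <- sum(pred[s] == positive & truth[s] != positive)
    data.frame(repeat_ = r, accuracy = (tp + tn) / sum(s),
               sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp) tn / (tn + fp) else NA_real_)
  }))
  structure(list(accuracy = mean(per_rep$accuracy),
                 auc = auc_pooled(score, truth, positive),
                 sensitivity = mean(per_rep$sensitivity),
                 specificity = mean(per_rep$specificity),
                 per_repeat = per_rep, scores = score, truth = truth,
                 positive = positive),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "Accuracy %.1f%%  AUC %.2f  Sensitivity %.2f  Specificity %.2f (positive: %s)\n",
    100 * x$accuracy, x$auc, x$sensitivity, x$specificity, x$positive))
  invisible(x)
}

#' Corrected resampled paired t-test for comparing classifiers
#'
#' The classical paired t statistic over per-run accuracy differences is
#' corrected for the overlap of cross-validation training sets by
#' inflating the variance term with the test/train size ratio:
#' `t = mean(d) / sqrt((1/R + n_test/n_train) * var(d))` on `R - 1`
#' degrees of freedom. Without the `n_test/n_train` term this reduces to
#' the classical paired t-test.
#'
#' @param diffs Per-run (e.g. per fold x repeat) accuracy differences.
#' @param n_train,n_test Training and test set sizes per run.
#' @return An object of class `htest` (two-tailed p-value).
#' @export
corrected_resampled_ttest <- function(diffs, n_train, n_test) {
  R <- length(diffs)
  if (R < 2L) stop("need at least two runs", call. = FALSE)
  m <- mean(diffs)
  v <- stats::var(diffs)
  if (v == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    if (m != 0)
      warning("zero variance with nonzero mean difference; p reported as 0",
              call. = FALSE)
  } else {
    t <- m / sqrt((1 / R + n_test / n_train) * v)
    p <- 2 * stats::pt(-abs(t), df = R - 1)
  }
  structure(list(statistic = c(t = t), parameter = c(df = R - 1),
                 p.value = p, estimate = c(`mean difference` = m),
                 method = "Corrected resampled paired t-test",
                 data.name = deparse(substitute(diffs))),
            class = "htest")
}

#' Compare two evaluations run under the same CV plan
#'
#' @param a,b `pet_eval` objects from [evaluate_cohort()] with identical
#'   plans.
#' @return [corrected_resampled_ttest()] result on per-fold accuracy
#'   differences (a minus b).
#' @export
compare_evaluations <- function(a, b) {
  stopifnot(inherits(a, "pet_eval"), inherits(b, "pet_eval"))
  if (!identical(a$plan$folds, b$plan$folds))
    stop("evaluations must share the same CV plan", call. = FALSE)
  acc <- function(e) vapply(e$folds, function(f) mean(f$pred == f$truth),
                            numeric(1))
  d <- acc(a) - acc(b)
  n_test <- length(a$folds[[1L]]$test)
  n_train <- length(a$folds[[1L]]$train)
  out <- corrected_resampled_ttest(d, n_train = n_train, n_test = n_test)
  out$data.name <- "per-fold accuracy differences (a - b)"
  out
}

#' Weighted-distance dissimilarity ratio for one test subject
#'
#' Error-analysis diagnostic: every feature row is multiplied elementwise
#' by the classifier weight vector, the mean Euclidean distance from the
#' weighted test row to each weighted group is computed, and the relative
#' ratio `rho = (D_a - D_b) / D_b` reported. The greater `rho`, the more
#' similar the test subject is to group b (e.g. the AD group).
#'
#' @param test_row Feature vector of the test subject.
#' @param rows_a,rows_b Feature matrices of the two training groups.
#' @param weights Classifier weight vector (same length as the features).
#' @return List with `D_a`, `D_b` and `rho`.
#' @export
dissimilarity_ratio <- function(test_row, rows_a, rows_b, weights) {
  w <- as.numeric(weights)
  rows_a <- as.matrix(rows_a); rows_b <- as.matrix(rows_b)
  stopifnot(length(test_row) == length(w), ncol(rows_a) == length(w),
            ncol(rows_b) == length(w))
  if (all(w == 0))
    stop("all weights are zero: weighted distances degenerate to 0",
         call. = FALSE)
  tw <- as.numeric(test_row) * w
  mdist <- function(rows) {
    rw <- sweep(rows, 2L, w, `*`)
    mean(sqrt(.rowSums((rw - matrix(tw, nrow(rw), length(w), byrow = TRUE))^2,
                       nrow(rw), length(w))))
  }
  D_a <- mdist(rows_a)
  D_b <- mdist(rows_b)
  if (D_b <= 0)
    stop("reference group distance is zero; ratio undefined", call. = FALSE)
  list(D_a = D_a, D_b = D_b, rho = (D_a - D_b) / D_b)
}

#' Evaluate a cohort with repeated stratified nested cross-validation
#'
#' Runs the full workflow for one two-class contrast: cluster discovery on
#' the mean reference (normal-control) image, per-subject cluster mean/SD
#' features, inner selection of the bin count on training subjects,
#' training-row feature ranking, linear-SVM cost grid search, and held-out
#' prediction — or one of the two baselines (`"atlas"`: region mean/SD
#' features; `"ttest"`: raw intensities of the top voxel-wise t-test
#' voxels selected on training subjects).
#'
#' When the reference group is not one of the classified groups, cluster
#' maps depend only on the reference cohort and are computed once and
#' reused across folds. If the reference group is itself classified, the
#' reference image — and hence the cluster maps — are recomputed per fold
#' from training subjects only, so no test information ever reaches the
#' clustering.
#'
#' @param volumes Named list of subject volumes (all subjects, including
#'   the reference group).
#' @param labels Group label per volume.
#' @param groups Length-2 character vector: the two groups to classify.
#' @param mask Logical 3D brain mask.
#' @param method `"gmm"` (cluster features; default), `"atlas"`, or
#'   `"ttest"`.
#' @param atlas A [brain_atlas]; required for `method = "atlas"`.
#' @param reference_group Group whose mean image drives cluster discovery
#'   (default `"NC"`).
#' @param bin_grid Candidate bin counts for the inner selection.
#' @param criterion `"bic"` or `"aic"` for the per-bin model selection.
#' @param n_top_features Features kept after ranking; defaults to 150 for
#'   BIC and 400 for AIC.
#' @param cluster_maps Optional precomputed list of `cluster_map`s (one
#'   per bin count), e.g. to reuse discovery across contrasts.
#' @param n_repeats,n_folds CV geometry (defaults 10 x 10).
#' @param cost_grid SVM penalty grid.
#' @param rank_method Passed to [rank_features()].
#' @param alpha,top_voxels t-test baseline parameters (defaults 0.001 and
#'   150).
#' @param inner_frac Sub-training fraction for the inner bin selection.
#' @param seed Integer seed for everything downstream.
#' @param positive Positive (disease) class for sensitivity; defaults to
#'   the second element of `groups`.
#' @param k_stride Passed to [discover_clusters()].
#' @return An object of class `pet_eval`: `summary` (an `eval_summary`),
#'   `folds` (per-fold records), `plan`, `maps` (when shared), and
#'   `settings`.
#' @export
evaluate_cohort <- function(volumes, labels, groups, mask,
                            method = c("gmm", "atlas", "ttest"),
                            atlas = NULL, reference_group = "NC",
                            bin_grid = seq(50L, 150L, by = 10L),
                            criterion = c("bic", "aic"),
                            n_top_features = NULL, cluster_maps = NULL,
                            n_repeats = 10L, n_folds = 10L,
                            cost_grid = 2^seq(-5, 5, by = 2),
                            rank_method = "tstat", alpha = 0.001,
                            top_voxels = 150L, inner_frac = 0.8,
                            seed = 1L, positive = groups[2L],
                            k_stride = 1L) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  labels <- as.character(labels)
  stopifnot(length(groups) == 2L, positive %in% groups,
            length(volumes) == length(labels))
  if (is.null(n_top_features))
    n_top_features <- if (criterion == "bic") 150L else 400L

  cls <- which(labels %in% groups)
  y <- labels[cls]
  vols_c <- volumes[cls]
  plan <- stratified_folds(y, n_folds = n_folds, n_repeats = n_repeats,
                           seed = derive_seed(seed, 11L))

  per_fold_ref <- FALSE
  feats_by_bin <- maps <- NULL
  featA <- NULL
  Vmask <- NULL
  if (method == "gmm") {
    if (is.null(cluster_maps)) {
      ref_all <- volumes[labels == reference_group]
      if (!length(ref_all))
        stop(sprintf("no '%s' volumes available as clustering reference",
                     reference_group), call. = FALSE)
      per_fold_ref <- reference_group %in% groups
      if (!per_fold_ref) {
        reference <- mean_reference_image(ref_all)
        cluster_maps <- lapply(bin_grid, function(b)
          discover_clusters(reference, mask, b, criterion = criterion,
                            seed = derive_seed(seed, 12L, b),
                            k_stride = k_stride))
      }
    }
    if (!per_fold_ref) {
      maps <- cluster_maps
      bin_grid <- vapply(maps, `[[`, integer(1), "n_bins")
      feats_by_bin <- lapply(maps, function(m) feature_matrix(vols_c, m))
    }
  } else if (method == "atlas") {
    if (is.null(atlas)) stop("method 'atlas' needs an atlas", call. = FALSE)
    featA <- feature_matrix(vols_c, atlas)
  } else {
    Vmask <- vapply(vols_c, function(v) v[mask], numeric(sum(mask)))
  }

  records <- vector("list", n_repeats * n_folds)
  ri <- 0L
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(n_folds)) {
      test <- which(plan$folds[, r] == f)
      train <- setdiff(seq_along(y), test)
      fseed <- derive_seed(seed, 13L, (r - 1L) * n_folds + f)
      chosen_bins <- NA_integer_
      map_used <- NULL
      if (method == "gmm") {
        if (per_fold_ref) {
          ref_tr <- vols_c[train][y[train] == reference_group]
          reference <- mean_reference_image(ref_tr)
          maps_f <- lapply(bin_grid, function(b)
            discover_clusters(reference, mask, b, criterion = criterion,
                              seed = derive_seed(seed, 12L, b),
                              k_stride = k_stride))
          feats_f <- lapply(maps_f, function(m) feature_matrix(vols_c, m))
        } else {
          maps_f <- maps
          feats_f <- feats_by_bin
        }
        chosen_bins <- as.integer(inner_select_bins(
          feats_f, y, train, bin_grid, n_top = n_top_features,
          rank_method = rank_method, frac = inner_frac, seed = fseed))
        bi <- match(chosen_bins, bin_grid)
        features <- feats_f[[bi]]
        map_used <- maps_f[[bi]]
        n_top <- n_top_features
      } else if (method == "atlas") {
        features <- featA
        n_top <- NULL
      } else {
        a_tr <- train[y[train] == groups[1L]]
        b_tr <- train[y[train] == groups[2L]]
        tt <- .row_ttest(Vmask[, a_tr, drop = FALSE],
                         Vmask[, b_tr, drop = FALSE])
        keep <- which(tt$p < alpha)
        if (!length(keep)) {
          warning(sprintf(
            "repeat %d fold %d: no voxel passed alpha = %g; using lowest-p voxels",
            r, f, alpha), call. = FALSE)
          keep <- seq_along(tt$p)
        }
        keep <- utils::head(keep[order(tt$p[keep])], top_voxels)
        features <- t(Vmask[keep, , drop = FALSE])
        colnames(features) <- sprintf("voxel%d", keep)
        n_top <- NULL
      }
      rec <- train_eval_fold(features, y, train, test,
                             cost_grid = cost_grid, n_top = n_top,
                             rank_method = rank_method, seed = fseed,
                             positive = positive)
      rec$repeat_ <- r
      rec$fold <- f
      rec$chosen_bins <- chosen_bins
      if (method == "gmm" && !is.null(rec$ranking)) {
        cl_of_feature <- ceiling(rec$ranking$order / 2)
        rec$cluster_rank <- cl_of_feature[!duplicated(cl_of_feature)]
      }
      ri <- ri + 1L
      records[[ri]] <- rec
    }
  }
  summary <- summarize_folds(records, positive)
  structure(list(summary = summary, folds = records, plan = plan,
                 maps = if (method == "gmm" && !per_fold_ref) maps,
                 settings = list(method = method, groups = groups,
                                 positive = positive, criterion = criterion,
                                 bin_grid = bin_grid,
                                 n_top_features = n_top_features,
                                 cost_grid = cost_grid,
                                 rank_method = rank_method,
                                 reference_group = reference_group,
                                 score_type = "decision_value",
                                 seed = seed)),
            class = "pet_eval")
}

#' @export
print.pet_eval <- function(x, ...) {
  s <- x$settings
  cat(sprintf("PET cohort evaluation: %s vs %s, method '%s' (%s)\n",
              s$groups[1L], s$groups[2L], s$method,
              if (s$method == "gmm") toupper(s$criterion) else "-"))
  cat(sprintf("  %d x %d-fold stratified CV, seed %d\n",
              x$plan$n_repeats, x$plan$n_folds, s$seed))
  cat("  ")
  print(x$summary)
  invisible(x)
}

#' @export
summary.pet_eval <- function(object, ...) {
  print(object)
  cat("\nPer-repeat metrics:\n")
  print(object$summary$per_repeat, row.names = FALSE)
  if (!is.null(object$maps)) {
    bins <- vapply(object$folds, function(f) f$chosen_bins, integer(1))
    cat("\nChosen bin counts across folds:\n")
    print(table(bins))
  }
  invisible(object)
}

#' Plot the pooled ROC curve of an evaluation
#'
#' @param x A `pet_eval`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pet_eval <- function(x, ...) {
  s <- x$summary
  rp <- roc_points(s$scores, s$truth, s$positive)
  graphics::plot(rp$fpr, rp$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", sprintf("AUC = %.3f", s$auc), bty = "n")
  invisible(x)
}

#' Report the atlas regions behind the most informative clusters
#'
#' In every fold the ten best clusters (by the position of each cluster's
#' best-ranked feature) receive 10 down to 1 points; points are summed
#' over all repeats and folds, the overall top-ten clusters pooled, and
#' their voxels attributed to atlas regions. Regions are ranked by their
#' percentage share of the pooled voxels, so the reported percentages sum
#' to at most 100.
#'
#' @param eval A `pet_eval` from [evaluate_cohort()] run with
#'   `method = "gmm"` and a shared reference (cluster maps retained).
#' @param atlas A [brain_atlas] on the same grid.
#' @param top_n Number of regions to report (default 10).
#' @return `data.frame` with columns `region`, `code`, `voxels`,
#'   `percent`, ordered by decreasing share.
#' @export
informative_regions_report <- function(eval, atlas, top_n = 10L) {
  stopifnot(inherits(eval, "pet_eval"), inherits(atlas, "brain_atlas"))
  if (is.null(eval$maps))
    stop("region report needs an evaluation with retained cluster maps",
         call. = FALSE)
  map_bins <- vapply(eval$maps, `[[`, integer(1), "n_bins")
  scores <- numeric(0)
  for (rec in eval$folds) {
    if (is.null(rec$cluster_rank)) next
    top <- utils::head(rec$cluster_rank, 10L)
    pts <- (10:1)[seq_along(top)]
    keys <- sprintf("%d:%d", rec$chosen_bins, top)
    for (i in seq_along(keys))
      scores[keys[i]] <- sum(scores[keys[i]], pts[i], na.rm = TRUE)
  }
  if (!length(scores)) stop("no cluster rankings recorded", call. = FALSE)
  ord <- order(-scores, names(scores))
  top_keys <- utils::head(names(scores)[ord], 10L)
  idx <- unlist(lapply(top_keys, function(key) {
    parts <- as.integer(strsplit(key, ":", fixed = TRUE)[[1L]])
    eval$maps[[match(parts[1L], map_bins)]]$clusters[[parts[2L]]]$idx
  }))
  codes <- atlas$labels[idx]
  tab <- table(codes[codes > 0L])
  out <- data.frame(region = unname(atlas$names[names(tab)]),
                    code = as.integer(names(tab)),
                    voxels = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(idx))
  out <- out[order(-out$percent, out$code), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
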
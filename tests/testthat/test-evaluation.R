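# Fabricated fold records for summarize/report tests.
fake_record <- function(repeat_, truth, pred, score,
                        cluster_rank = NULL, chosen_bins = NA_integer_) {
  structure(list(repeat_ = repeat_, fold = 1L, truth = truth, pred = pred,
                 score = score, cluster_rank = cluster_rank,
                 chosen_bins = chosen_bins),
            class = "fold_result")
}

test_that("stratified folds balance classes within one subject", {
  y <- rep(c("MCI", "AD"), each = 30)
  plan <- stratified_folds(y, 10, 10, seed = 1)
  expect_s3_class(plan, "cv_plan")
  for (r in 1:10) {
    f <- plan$folds[, r]
    expect_identical(sort(unique(f)), 1:10)
    for (k in 1:10) {
      expect_identical(sum(f == k & y == "MCI"), 3L)
      expect_identical(sum(f == k & y == "AD"), 3L)
      expect_identical(sum(f != k), 54L)  # training size per fold
    }
  }
  # 10 + 10 subjects, 10 folds: one of each class per fold
  p2 <- stratified_folds(rep(c("A", "B"), each = 10), 10, 2, seed = 2)
  expect_true(all(table(p2$folds[, 1], rep(c("A", "B"), each = 10)) == 1L))
  expect_error(stratified_folds(rep(c("A", "B"), c(5, 30)), 10),
               "at least 10")
  # deterministic given seed
  expect_identical(stratified_folds(y, 10, 3, seed = 9)$folds,
                   stratified_folds(y, 10, 3, seed = 9)$folds)
})

test_that("pooled AUC equals exhaustive pair counting", {
  truth <- rep(c("pos", "neg"), each = 4)
  expect_equal(auc_pooled(c(4, 3.5, 3, 2.9, 2, 1, 0.5, 0), truth, "pos"), 1)
  expect_equal(auc_pooled(rep(1, 8), truth, "pos"), 0.5)
  set.seed(50)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    truth <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    sc <- sample(round(rnorm(n), 1))  # ties likely
    expect_equal(auc_pooled(sc, truth, "b"), naive_auc(sc, truth, "b"))
  }
  expect_error(auc_pooled(1:3, rep("a", 3), "b"), "absent")
})

test_that("summary metrics match hand-computed confusion counts", {
  # 12 test instances over 2 repeats, positive class "AD"
  recs <- list(
    fake_record(1L, truth = c("AD", "AD", "MCI", "MCI", "AD", "MCI"),
                pred = c("AD", "MCI", "MCI", "AD", "AD", "MCI"),
                score = c(2, -1, -2, 1, 3, -3)),
    fake_record(2L, truth = c("AD", "MCI", "AD", "MCI", "AD", "MCI"),
                pred = c("AD", "MCI", "AD", "MCI", "MCI", "MCI"),
                score = c(1, -1, 2, -2, -0.5, -1.5)))
  s <- summarize_folds(recs, positive = "AD")
  # repeat 1: TP 2, FN 1, TN 2, FP 1 -> acc 4/6, sens 2/3, spec 2/3
  # repeat 2: TP 2, FN 1, TN 3, FP 0 -> acc 5/6, sens 2/3, spec 1
  expect_equal(s$accuracy, mean(c(4 / 6, 5 / 6)))
  expect_equal(s$sensitivity, mean(c(2 / 3, 2 / 3)))
  expect_equal(s$specificity, mean(c(2 / 3, 1)))
  expect_equal(s$auc, naive_auc(c(recs[[1]]$score, recs[[2]]$score),
                                c(recs[[1]]$truth, recs[[2]]$truth), "AD"))
  # all-correct and majority-vote degenerate summaries
  all_right <- list(fake_record(1L, c("AD", "MCI"), c("AD", "MCI"),
                                c(1, -1)))
  sr <- summarize_folds(all_right, "AD")
  expect_equal(c(sr$accuracy, sr$auc, sr$sensitivity, sr$specificity),
               rep(1, 4))
  all_maj <- list(fake_record(1L, rep(c("AD", "MCI"), 15),
                              rep("AD", 30), rep(0, 30)))
  sm <- summarize_folds(all_maj, "AD")
  expect_equal(sm$accuracy, 0.5)
  expect_equal(sm$sensitivity, 1)
  expect_equal(sm$specificity, 0)
})

test_that("corrected resampled t-test behaves across its regimes", {
  # all differences zero
  r0 <- corrected_resampled_ttest(rep(0, 10), 54, 6)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)
  # dropping the test/train term recovers the classical paired t-test
  set.seed(51)
  d <- rnorm(10, 0.05, 0.03)
  rc <- corrected_resampled_ttest(d, n_train = 1e9, n_test = 1e-9)
  tt <- t.test(d)
  expect_equal(unname(rc$statistic), unname(tt$statistic), tolerance = 1e-4)
  expect_equal(rc$p.value, tt$p.value, tolerance = 1e-4)
  # p increases monotonically with the test/train ratio
  ratios <- c(0.01, 0.1, 0.5, 1, 2)
  ps <- vapply(ratios, function(rr)
    corrected_resampled_ttest(d, n_train = 100, n_test = 100 * rr)$p.value,
    numeric(1))
  expect_true(all(diff(ps) > 0))
  # zero variance, nonzero mean
  expect_warning(rz <- corrected_resampled_ttest(rep(0.1, 5), 54, 6),
                 "zero variance")
  expect_equal(rz$p.value, 0)
  expect_error(corrected_resampled_ttest(0.1, 54, 6), "two runs")
})

test_that("dissimilarity ratio reproduces its defining arithmetic", {
  # engineered so D_a = 1.26 and D_b = 1.00 exactly
  w <- c(1, 1)
  test_row <- c(0, 0)
  rows_a <- rbind(c(1.26, 0), c(0, 1.26))
  rows_b <- rbind(c(1, 0), c(0, 1))
  r <- dissimilarity_ratio(test_row, rows_a, rows_b, w)
  expect_equal(r$D_a, 1.26)
  expect_equal(r$D_b, 1)
  expect_equal(r$rho, 0.26)
  # equal distances give rho = 0
  r0 <- dissimilarity_ratio(test_row, rows_b, rows_b, w)
  expect_equal(r0$rho, 0)
  expect_error(dissimilarity_ratio(test_row, rows_a, rows_b, c(0, 0)),
               "zero")
})

test_that("train_eval_fold is perfect on separable features, chance on noise", {
  set.seed(52)
  n <- 40
  y <- rep(c("MCI", "AD"), each = n / 2)
  X <- cbind(sep = ifelse(y == "AD", 5, -5) + rnorm(n, sd = 0.1),
             noise = rnorm(n))
  rec <- train_eval_fold(X, y, train = c(1:16, 21:36),
                         test = c(17:20, 37:40), positive = "AD")
  expect_identical(mean(rec$pred == rec$truth), 1)
  expect_true(all(rec$score[rec$truth == "AD"] >
                    rec$score[rec$truth == "MCI"]))
  expect_error(train_eval_fold(X, y, train = 1:10, test = 30:40),
               "one class")

  # label-independent features: mean CV accuracy near one half
  set.seed(53)
  n2 <- 200
  y2 <- rep(c("A", "B"), each = n2 / 2)
  X2 <- matrix(rnorm(n2 * 10), n2)
  plan <- stratified_folds(y2, 10, 2, seed = 3)
  accs <- c()
  for (r in 1:2) for (f in 1:10) {
    te <- which(plan$folds[, r] == f)
    rec <- train_eval_fold(X2, y2, setdiff(seq_len(n2), te), te,
                           cost_grid = 1, seed = f, positive = "B")
    accs <- c(accs, mean(rec$pred == rec$truth))
  }
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("fold training never sees the held-out rows", {
  set.seed(54)
  n <- 40
  y <- rep(c("A", "B"), 20)
  X <- matrix(rnorm(n * 12), n)
  tr <- 1:30
  te <- 31:40
  rec1 <- train_eval_fold(X, y, tr, te, n_top = 6, seed = 7, positive = "B")
  Xm <- X
  Xm[te, ] <- Xm[te, ] + 100  # mutate test rows
  rec2 <- train_eval_fold(Xm, y, tr, te, n_top = 6, seed = 7, positive = "B")
  expect_identical(rec1$ranking$order, rec2$ranking$order)
  expect_identical(rec1$feature_cols, rec2$feature_cols)
  expect_identical(rec1$chosen_cost, rec2$chosen_cost)
  expect_equal(rec1$weights, rec2$weights)
})

test_that("inner bin selection picks the informative granularity", {
  set.seed(55)
  n <- 40
  y <- rep(c("MCI", "AD"), each = n / 2)
  # candidate 1 carries the signal, candidate 2 is pure noise
  f_good <- cbind(ifelse(y == "AD", 2, -2) + rnorm(n, sd = 0.3),
                  rnorm(n))
  f_bad <- matrix(rnorm(n * 2), n)
  chosen <- inner_select_bins(list(f_good, f_bad), y, train_idx = 1:n,
                              bin_grid = c(50L, 150L), n_top = 2,
                              seed = 4)
  expect_identical(as.integer(chosen), 50L)
  rev_chosen <- inner_select_bins(list(f_bad, f_good), y, train_idx = 1:n,
                                  bin_grid = c(50L, 150L), n_top = 2,
                                  seed = 4)
  expect_identical(as.integer(rev_chosen), 150L)
  # single candidate: returned as-is
  expect_identical(as.integer(inner_select_bins(list(f_bad), y, 1:n, 70L)),
                   70L)
  # chosen value always lies in the grid
  expect_true(as.integer(chosen) %in% c(50L, 150L))
})

test_that("roc_points trace a valid monotone curve", {
  truth <- c("p", "p", "n", "p", "n", "n")
  sc <- c(3, 2.5, 2, 1, 0.5, 0)
  rp <- roc_points(sc, truth, "p")
  expect_equal(rp$fpr[1], 0)
  expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
})

test_that("informative region report attributes clusters to regions", {
  at <- slab_atlas(c(6, 5, 4), 3)
  idx_r1 <- which(at$labels == 1L)
  map <- list(n_bins = 10L, criterion = "bic", seed = 1L,
              shape = dim(at$labels), bin_edges = c(0, 1), bin_width = 1,
              chosen_k = c(`1` = 1L),
              clusters = list(list(id = 1L, bin_index = 1L,
                                   component_index = 1L,
                                   coords = NULL, idx = idx_r1,
                                   intensity = rep(0, length(idx_r1)))))
  class(map) <- "cluster_map"
  ev <- structure(list(
    folds = list(fake_record(1L, "AD", "AD", 1, cluster_rank = 1L,
                             chosen_bins = 10L)),
    maps = list(map),
    plan = NULL, summary = NULL,
    settings = list(method = "gmm")), class = "pet_eval")
  rep_tab <- informative_regions_report(ev, at)
  expect_identical(rep_tab$region[1], "Slab_1")
  expect_equal(rep_tab$percent[1], 100)
  expect_lte(sum(rep_tab$percent), 100 + 1e-9)
})
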
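# Fisher-criterion SFS, the linear maximum-margin classifier, and
# cross-validated classification.

test_that("fisher_ratio matches hand arithmetic and its properties", {
  expect_equal(fisher_ratio(c(0, 1, 2, 4, 5, 6), rep(1:2, each = 3)), 8)
  # identical means -> 0 regardless of variances
  expect_equal(fisher_ratio(c(-1, 0, 1, -5, 0, 5), rep(1:2, each = 3)), 0)
  # scale invariance
  x <- c(0.3, 1.1, 2.2, 4.5, 5.1, 6.9)
  lab <- rep(1:2, each = 3)
  expect_equal(fisher_ratio(7 * x, lab), fisher_ratio(x, lab),
               tolerance = 1e-12)
  expect_warning(j <- fisher_ratio(c(1, 1, 2, 2), c(1, 1, 2, 2)), "Inf")
  expect_equal(j, Inf)
  expect_error(fisher_ratio(c(1, 2, 3), c(1, 2, 2)), ">= 2")
})

test_that("sfs_select picks the dominant feature first (brute force)", {
  tab <- random_table(n_per_class = 15, p = 20, seed = 5,
                      informative = "NPQ_L2", shift = 4)
  cols <- setdiff(names(tab), c("sample_id", "label"))
  brute <- vapply(cols, function(nm) fisher_ratio(tab[[nm]], tab$label),
                  numeric(1))
  sel <- sfs_select(tab, k = 4)
  expect_equal(sel$selected[1], names(which.max(brute)))
  expect_equal(sel$selected[1], "NPQ_L2")
  expect_length(sel$selected, 4)
  expect_length(sel$criterion, 4)
  expect_false(anyDuplicated(sel$selected) > 0)
  expect_true(all(diff(sel$criterion) >= 0))
})

test_that("sfs_select edge cases: k = all, k too large, determinism", {
  tab <- random_table(n_per_class = 10, p = 6, seed = 2)
  all6 <- sfs_select(tab, k = 6)
  expect_setequal(all6$selected,
                  setdiff(names(tab), c("sample_id", "label")))
  expect_error(sfs_select(tab, k = 7), "exceeds")
  expect_identical(sfs_select(tab, k = 3), sfs_select(tab, k = 3))
  # a duplicated feature adds nothing after whitening
  tab2 <- random_table(n_per_class = 15, p = 5, seed = 8,
                       informative = "Fo", shift = 5)
  tab2$Fm <- tab2$Fo    # exact duplicate of the best feature
  sel2 <- sfs_select(tab2, k = 2)
  expect_equal(sel2$selected[1], "Fm")  # tie broken by name order
  expect_false(sel2$selected[2] == "Fo")
})

test_that("linear_svm solves a separable problem like the analytic SVM", {
  # 1-D: support vectors at -1 and +1 -> w = 1, b = 0
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(1, 1, 2, 2)
  fit <- linear_svm(x, y, C = 100)
  expect_equal(fit$w, 1, tolerance = 1e-3)
  expect_equal(fit$b, 0, tolerance = 1e-3)
  expect_equal(as.numeric(predict(fit, x)), y)
  # well-separated 2-D clouds classify perfectly
  xy <- with_seed(13, rbind(matrix(stats::rnorm(60, 0), ncol = 2),
                            matrix(stats::rnorm(60, 6), ncol = 2)))
  lab <- rep(1:2, each = 30)
  fit2 <- linear_svm(xy, lab)
  expect_equal(as.numeric(predict(fit2, xy)), lab)
  expect_error(linear_svm(xy, rep(1, 60)), "two classes")
})

test_that("cv_classify is stratified, deterministic and accurate when
           separable", {
  tab <- random_table(n_per_class = 25, p = 10, seed = 9,
                      informative = c("Fo", "Fm"), shift = 8)
  rep1 <- cv_classify(tab, c("Fo", "Fm"), folds = 10, seed = 3)
  expect_equal(rep1$overall, 100)
  expect_equal(rep1$control, 100)
  expect_equal(rep1$drought, 100)
  # folds are stratified: each fold has samples of both classes
  for (f in unique(rep1$fold)) {
    expect_setequal(unique(tab$label[rep1$fold == f]), 1:2)
  }
  rep2 <- cv_classify(tab, c("Fo", "Fm"), folds = 10, seed = 3)
  expect_identical(rep1$fold, rep2$fold)
  expect_identical(rep1$predicted, rep2$predicted)
  rep3 <- cv_classify(tab, c("Fo", "Fm"), folds = 10, seed = 4)
  expect_false(identical(rep1$fold, rep3$fold))
})

test_that("cv_classify on permuted labels stays near chance", {
  # null features, fixed pre-specified feature list (no selection step)
  tab <- random_table(n_per_class = 50, p = 12, seed = 17)
  rep0 <- cv_classify(tab, c("Fo", "Fm", "Fv"), folds = 10, seed = 17)
  # 99% binomial band around 50% for n = 100
  half_width <- 100 * 2.576 * sqrt(0.25 / 100)
  expect_gt(rep0$overall, 50 - half_width)
  expect_lt(rep0$overall, 50 + half_width)
})

test_that("cv_classify input validation", {
  tab <- random_table(n_per_class = 6, p = 4, seed = 1)
  one_class <- tab[tab$label == 1, ]
  expect_error(cv_classify(one_class, "Fo", seed = 1), "two classes")
  expect_error(cv_classify(tab, "nope", seed = 1), "unknown feature")
  expect_warning(cv_classify(tab, "Fo", folds = 10, seed = 1), "fewer")
})

test_that("feature_table validates inputs", {
  expect_error(feature_table(data.frame(a = c(1, NA)), c(1, 2)),
               "missing")
  expect_error(feature_table(data.frame(a = 1:3), c(1, 2)), "match")
  tab <- feature_table(data.frame(a = 1:4), c(1, 1, 2, 2), day = "day3")
  expect_s3_class(tab, "feature_table")
  expect_equal(tab$day, rep("day3", 4))
})

test_that("accuracy rises with preset severity and severe SFS is stable", {
  sev <- fx_severe_table()
  mod <- fx_moderate_table()
  sel_s <- sfs_select(sev, 9)
  sel_m <- sfs_select(mod, 9)
  mild <- fx_mild_table()
  acc_s <- cv_classify(sev, sel_s, folds = 7, seed = 1)$overall
  acc_m <- cv_classify(mod, sel_m, folds = 7, seed = 1)$overall
  acc_w <- cv_classify(mild, sfs_select(mild, 9), folds = 7,
                       seed = 1)$overall
  expect_gte(acc_s, acc_m)
  expect_gte(acc_m, acc_w)
  # decorrelated subset criterion is monotone non-decreasing
  expect_true(all(diff(sel_s$criterion) >= -1e-9))
  # bootstrap stability smoke test, on the ranking criterion (the
  # decorrelated criterion keeps one representative per correlated block,
  # so its name-level overlap is low by construction; see the vignette)
  sel_r <- sfs_select(sev, 9, criterion = "ranking")
  idx <- with_seed(77, c(sample(which(sev$label == 1), 14, replace = TRUE),
                         sample(which(sev$label == 2), 14, replace = TRUE)))
  boot <- sev[idx, ]
  boot$sample_id <- sprintf("b%03d", seq_len(nrow(boot)))
  sel_b <- sfs_select(boot, 9, criterion = "ranking")
  expect_gte(length(intersect(sel_b$selected, sel_r$selected)), 5)
})
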
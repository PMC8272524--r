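test_that("feature assembly yields the documented 17/27 column layouts", {
  coh <- gen_cohort(cohort_config(n_timepoints = 40, seed = 13))
  nw <- network_summary(cohort_seed_maps(coh))
  std <- assemble_features(coh, networks = nw)
  expect_identical(setdiff(names(std), c("subject_id", "group")),
                   feature_cols("standard"))
  expect_length(feature_cols("standard"), 17L)
  ext <- assemble_features(coh, include_cognitive = TRUE, networks = nw)
  expect_identical(setdiff(names(ext), c("subject_id", "group")),
                   feature_cols("extended"))
  expect_length(feature_cols("extended"), 27L)
  expect_length(feature_cols("neuro"), 13L)
  # column order is stable across runs
  expect_identical(names(std), names(assemble_features(coh, networks = nw)))
  bad <- coh; bad$fa <- bad$fa[-3, ]
  expect_error(assemble_features(bad, networks = nw),
               coh$subjects$subject_id[3])
})

test_that("the stratified splitter holds out 20% and partitions exactly", {
  tab <- separable_features(19)  # 38 subjects
  sp <- split_train_test(tab, 0.2, seed = 4)
  expect_identical(nrow(sp$test), 8L)
  expect_true(all(table(sp$test$group) == c(4, 4)))
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  tab$subject_id)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  sp2 <- split_train_test(tab, 0.2, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_train_test(tab, 1.2), "test_fraction")
  expect_error(split_train_test(tab[c(1:3, 20:22), ], 0.2), ">= 5 subjects")
})

test_that("tuning finds a near-perfect model on separable data", {
  tab <- separable_features(19, seed = 6)
  sp <- split_train_test(tab, 0.2, seed = 1)
  model <- tune_gbm(sp$train, positive = "FLE",
                    features = paste0("x", 1:5), n_bayes_iter = 10, seed = 1)
  expect_gt(model$cv_auc, 0.9)
  expect_identical(evaluate(model, sp$test)$auc, 1)
  # the planted feature dominates the tuned model's importance ranking
  expect_identical(feature_importance(model)$feature[1], "x1")
  # a confident, unregularized fit on the same data is a perfect predictor
  fixed <- lapply(default_search_space(), function(s) s)
  vals <- list(eta = 0.3, max_depth = 2, nrounds = 200, subsample = 1,
               colsample_bytree = 1, alpha = 0, lambda = 0.01)
  for (nm in names(fixed)) fixed[[nm]]$lower <- fixed[[nm]]$upper <- vals[[nm]]
  model <- tune_gbm(sp$train, positive = "FLE",
                    features = c("x_exact", "x2"),
                    n_bayes_iter = 1, search_space = fixed, seed = 1)
  rep <- evaluate(model, sp$test)
  expect_identical(rep$accuracy, 1)
  expect_identical(rep$auc, 1)
  expect_identical(unname(rep$confusion["pos", "neg"]), 0L)
  expect_identical(unname(rep$confusion["neg", "pos"]), 0L)
  # internal consistency of confusion-derived rates
  cm <- rep$confusion
  expect_equal(rep$sensitivity, cm[1, 1] / (cm[1, 1] + cm[2, 1]))
  expect_equal(rep$specificity, cm[2, 2] / (cm[2, 2] + cm[1, 2]))
  expect_true(all(is.finite(rep$importance$gain) & rep$importance$gain >= 0))
})

test_that("tuning is deterministic and guards against leakage", {
  tab <- separable_features(10, seed = 3)
  sp <- split_train_test(tab, 0.2, seed = 2)
  m1 <- tune_gbm(sp$train, "FLE", features = paste0("x", 1:5),
                 n_bayes_iter = 8, seed = 7)
  m2 <- tune_gbm(sp$train, "FLE", features = paste0("x", 1:5),
                 n_bayes_iter = 8, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  # normalization statistics come from the training set only
  expect_equal(unname(m1$center),
               unname(colMeans(as.matrix(sp$train[paste0("x", 1:5)]))))
  expect_error(evaluate(m1, sp$train), "leakage")
  one_class <- sp$test[sp$test$group == "FLE", ]
  expect_error(evaluate(m1, one_class), "single-class")
  expect_error(tune_gbm(sp$train, "FLE", k_folds = 10), "exceeds")
})

test_that("label-permuted training stays near chance", {
  set.seed(15)
  aucs <- vapply(1:8, function(s) {
    tab <- separable_features(12, seed = 100 + s)
    tab$group <- sample(tab$group)  # break the label-feature link
    sp <- split_train_test(tab, 0.2, seed = s)
    m <- tune_gbm(sp$train, "FLE", features = paste0("x", 1:5),
                  n_bayes_iter = 4, seed = s)
    m$cv_auc
  }, 0)
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("ablation uses identical splits and reveals behavioral signal", {
  # cohort where only behavior separates FLE: neuro-only should fall off
  cfg <- cohort_config(n_timepoints = 20, d_behavior = 2.5, d_atr = 0,
                       delta_coupling = 0, rho_neuro_behavior = 0, seed = 33)
  coh <- gen_cohort(cfg)
  nw <- network_summary(cohort_seed_maps(coh))
  feats <- assemble_features(coh, include_cognitive = TRUE, networks = nw)
  abl <- ablation_suite(feats, tasks = "FLE-vs-CTL", seeds = 1:4,
                        n_bayes_iter = 4)
  runs <- abl$runs
  acc <- tapply(runs$accuracy, runs$variant, mean)
  expect_gt(acc[["standard"]], acc[["neuro"]])
  expect_lt(acc[["neuro"]], 0.7)  # toward chance without behavior
  # identical splits per seed across variants
  for (s in 1:4) {
    ids <- lapply(c("standard", "neuro", "extended"), function(v)
      sort(abl$reports[[paste("FLE-vs-CTL", s, v, sep = "/")]]$model$train_ids))
    expect_identical(ids[[1]], ids[[2]])
    expect_identical(ids[[1]], ids[[3]])
  }
  # uninformative cognitive subtests stay out of the top of the ranking
  top3 <- lapply(1:4, function(s)
    head(abl$reports[[paste("FLE-vs-CTL", s, "extended",
                            sep = "/")]]$importance$feature, 3))
  cog <- setdiff(feature_cols("extended"), feature_cols("standard"))
  frac_cog_top <- mean(vapply(top3, function(tp) any(tp %in% cog), TRUE))
  expect_lt(frac_cog_top, 0.5)
})
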
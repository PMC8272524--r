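#' Assemble the classification feature table
#'
#' Builds the subject x feature table used by the classifiers: the four
#' behavioral condition scores, the 10 tract FA values, and the three
#' network-level wSDM summaries (17 standard columns), optionally extended
#' with the 10 cognitive subtest scores (5 MoCA-like domain-general and 5
#' IFS-like executive measures). Column order is fixed: behavior, tracts,
#' networks, then cognitive subtests.
#'
#' @param cohort A [gen_cohort()] object.
#' @param include_cognitive Add the 10 cognitive subtest columns.
#' @param networks Optional precomputed network-summary table (from
#'   [network_summary()]); computed from the cohort's time series when
#'   `NULL`.
#' @return Data frame with `subject_id`, `group`, and the feature columns.
#' @export
assemble_features <- function(cohort, include_cognitive = FALSE,
                              networks = NULL) {
  if (is.null(networks))
    networks <- network_summary(cohort_seed_maps(cohort))
  beh <- cohort$behavior; fa <- cohort$fa; subj <- cohort$subjects
  miss <- c(setdiff(subj$subject_id, beh$subject_id),
            setdiff(subj$subject_id, fa$subject_id),
            setdiff(subj$subject_id, networks$subject_id))
  if (length(miss))
    stop("subjects missing from a source table: ",
         paste(unique(miss), collapse = ", "))
  beh <- beh[match(subj$subject_id, beh$subject_id), ]
  fa <- fa[match(subj$subject_id, fa$subject_id), ]
  networks <- networks[match(subj$subject_id, networks$subject_id), ]
  out <- data.frame(subject_id = subj$subject_id, group = subj$group,
                    stringsAsFactors = FALSE)
  for (cl in c("at_verb", "at_circ", "nt_verb", "nt_circ"))
    out[[cl]] <- beh[[cl]]
  for (tr in tract_names()) out[[tr]] <- fa[[tr]]
  for (nw in setdiff(names(networks), "subject_id"))
    out[[nw]] <- networks[[nw]]
  if (include_cognitive) {
    cog <- grep("^(moca|ifs)_", names(subj), value = TRUE)
    for (cl in cog) out[[cl]] <- subj[[cl]]
  }
  out
}

#' Feature-column subsets of the assembled table
#'
#' `feature_cols("standard")` = 4 behavioral + 10 tract + 3 network columns;
#' `"neuro"` drops the behavioral conditions; `"extended"` adds the 10
#' cognitive subtests.
#'
#' @param set One of `"standard"`, `"neuro"`, `"extended"`.
#' @return Character vector of column names.
#' @export
feature_cols <- function(set = c("standard", "neuro", "extended")) {
  set <- match.arg(set)
  beh <- c("at_verb", "at_circ", "nt_verb", "nt_circ")
  nets <- names(default_networks())
  cog <- c("moca_visuospatial", "moca_attention", "moca_language",
           "moca_abstraction", "moca_recall",
           "ifs_motor_prog", "ifs_conflict", "ifs_inhibition",
           "ifs_proverbs", "ifs_working_mem")
  switch(set,
    standard = c(beh, tract_names(), nets),
    neuro = c(tract_names(), nets),
    extended = c(beh, tract_names(), nets, cog))
}

#' Stratified train/test split
#'
#' Random division into 80\% training and 20\% testing (by default),
#' stratified by class so that neither side loses a class at these sample
#' sizes; the per-class test count is `round(test_fraction * n_class)`, at
#' least 1.
#'
#' @param table Feature table with a `group` column.
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Optional integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(table, test_fraction = 0.2, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must lie in (0, 1)")
  if (any(table(table$group) < 5)) stop("need >= 5 subjects per class")
  if (!is.null(seed)) set.seed(seed)
  test_idx <- integer(0)
  for (g in unique(table$group)) {
    ig <- which(table$group == g)
    nt <- max(1L, round(test_fraction * length(ig)))
    test_idx <- c(test_idx, sample(ig, nt))
  }
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

#' Default hyperparameter search space for the gradient-boosting tuner
#'
#' Learning rate 0.01-0.3 (log scale), tree depth 2-6, boosting rounds
#' 50-500 (log scale), row/column subsampling 0.5-1, and L1/L2
#' regularization weights 0-5.
#'
#' @return Named list of `c(lower, upper)` ranges with attributes marking
#'   log-scale and integer parameters.
#' @export
default_search_space <- function() {
  list(
    eta = list(lower = 0.01, upper = 0.3, log = TRUE, integer = FALSE),
    max_depth = list(lower = 2, upper = 6, log = FALSE, integer = TRUE),
    nrounds = list(lower = 50, upper = 500, log = TRUE, integer = TRUE),
    subsample = list(lower = 0.5, upper = 1, log = FALSE, integer = FALSE),
    colsample_bytree = list(lower = 0.5, upper = 1, log = FALSE,
                            integer = FALSE),
    alpha = list(lower = 0, upper = 5, log = FALSE, integer = FALSE),
    lambda = list(lower = 0, upper = 5, log = FALSE, integer = FALSE)
  )
}

.decode_params <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    s <- space[[i]]
    val <- if (s$log) {
      exp(log(s$lower) + u[i] * (log(s$upper) - log(s$lower)))
    } else {
      s$lower + u[i] * (s$upper - s$lower)
    }
    if (s$integer) val <- as.integer(round(val))
    out[[names(space)[i]]] <- val
  }
  out
}

.auc_score <- function(y, scores) {
  as.numeric(pROC::auc(pROC::roc(y, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

.xgb_fit <- function(x, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  pars <- list(objective = "binary:logistic", eval_metric = "auc",
               nthread = 1, seed = seed,
               eta = params$eta, max_depth = params$max_depth,
               subsample = params$subsample,
               colsample_bytree = params$colsample_bytree,
               alpha = params$alpha, lambda = params$lambda)
  xgboost::xgb.train(params = pars, data = dtrain,
                     nrounds = params$nrounds, verbose = 0)
}

.cv_auc <- function(x, y, folds, params, seed) {
  aucs <- vapply(sort(unique(folds)), function(k) {
    tr <- folds != k
    fit <- .xgb_fit(x[tr, , drop = FALSE], y[tr], params, seed)
    sc <- predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
    .auc_score(y[!tr], sc)
  }, 0)
  mean(aucs)
}

# squared-exponential GP posterior on the unit cube, fixed hyperparameters
.gp_posterior <- function(X, y, Xnew, lengthscale = 0.3, nugget = 1e-2) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  mu <- mean(y); s <- sd(y); if (s == 0) s <- 1
  ys <- (y - mu) / s
  K <- k(X, X) + diag(nugget, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Ks <- k(Xnew, X)
  m <- as.numeric(Ks %*% alpha)
  v <- 1 + nugget - rowSums((Ks %*% chol2inv(L)) * Ks)
  list(mean = m * s + mu, sd = pmax(sqrt(pmax(v, 1e-12)) * s, 1e-9))
}

#' Bayesian-tuned gradient-boosting classifier
#'
#' Tunes an XGBoost binary classifier by Bayesian optimization of the mean
#' k-fold cross-validated AUC on the training set: a Latin-hypercube initial
#' design over the (unit-cube-encoded) search space, followed by a Gaussian
#' process surrogate with expected-improvement acquisition. Features are
#' standardized with training-set statistics only; those statistics travel
#' with the model and are applied to any data scored later. The full budget
#' is `n_bayes_iter` objective evaluations.
#'
#' @param train Training feature table (`subject_id`, `group`, features).
#' @param positive The class treated as positive (e.g. `"FLE"`).
#' @param features Feature columns to use; default [feature_cols()]
#'   `"standard"` set intersected with `train`'s columns.
#' @param k_folds Cross-validation folds (must not exceed the smallest class
#'   count in `train`).
#' @param n_bayes_iter Total tuning evaluations (Latin-hypercube warm-up
#'   plus expected-improvement steps).
#' @param search_space See [default_search_space()].
#' @param seed Integer seed controlling folds, design, and XGBoost.
#' @return Object of class `"flemark_gbm"`; supports [predict()],
#'   [feature_importance()], and [evaluate()].
#' @export
tune_gbm <- function(train, positive, features = NULL, k_folds = 5,
                     n_bayes_iter = 25, search_space = default_search_space(),
                     seed = 1L) {
  if (is.null(features))
    features <- intersect(feature_cols("standard"), names(train))
  cls <- table(train$group)
  if (length(cls) != 2) stop("training data must contain exactly two classes")
  if (!positive %in% names(cls)) stop("'positive' not found in training data")
  if (k_folds > min(cls))
    stop("k_folds (", k_folds, ") exceeds smallest class count (", min(cls),
         ")")
  set.seed(seed)
  x <- as.matrix(train[, features, drop = FALSE])
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  x <- scale(x, ctr, scl)
  y <- as.integer(train$group == positive)
  # stratified fold assignment
  folds <- integer(nrow(train))
  for (g in names(cls)) {
    ig <- which(train$group == g)
    folds[ig] <- sample(rep(seq_len(k_folds), length.out = length(ig)))
  }
  if (any(vapply(seq_len(k_folds),
                 function(k) length(unique(y[folds == k])) < 2, TRUE)))
    stop("degenerate single-class fold; reduce k_folds")
  d <- length(search_space)
  n_init <- min(n_bayes_iter, max(6L, min(10L, n_bayes_iter)))
  U <- lhs::randomLHS(n_init, d)
  objective <- function(u) {
    .cv_auc(x, y, folds, .decode_params(u, search_space), seed)
  }
  scores <- apply(U, 1, objective)
  while (nrow(U) < n_bayes_iter) {
    post <- .gp_posterior(U, scores, Xc <- matrix(runif(256 * d), ncol = d))
    z <- (post$mean - max(scores)) / post$sd
    ei <- post$sd * (z * pnorm(z) + dnorm(z))
    u_new <- Xc[which.max(ei), , drop = FALSE]
    U <- rbind(U, u_new)
    scores <- c(scores, objective(as.numeric(u_new)))
  }
  best <- .decode_params(U[which.max(scores), ], search_space)
  booster <- .xgb_fit(x, y, best, seed)
  structure(
    list(booster = booster, params = best, cv_auc = max(scores),
         history = data.frame(U, cv_auc = scores),
         center = ctr, scale = scl, features = features,
         positive = positive, negative = setdiff(names(cls), positive),
         train_ids = train$subject_id, k_folds = k_folds, seed = seed),
    class = "flemark_gbm"
  )
}

#' @export
print.flemark_gbm <- function(x, ...) {
  cat(sprintf("Tuned gradient-boosting classifier (%s vs %s)\n",
              x$positive, x$negative))
  cat(sprintf("  %d features, %d-fold CV AUC = %.3f\n",
              length(x$features), x$k_folds, x$cv_auc))
  cat("  params:",
      paste(names(x$params), vapply(x$params, format, "", digits = 3),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
predict.flemark_gbm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  x <- scale(x, object$center, object$scale)
  predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Evaluate a tuned classifier on a held-out test set
#'
#' Scores the test subjects, thresholds the predicted probability at 0.5,
#' and reports accuracy, ROC AUC, sensitivity, specificity, and the 2x2
#' confusion matrix, together with gain-based feature importance. The test
#' set must be disjoint from the training subjects (asserted here: any
#' overlap is an error, guarding against leakage).
#'
#' @param model A [tune_gbm()] model.
#' @param test Test feature table.
#' @return Object of class `"flemark_report"`.
#' @export
evaluate <- function(model, test) {
  overlap <- intersect(model$train_ids, test$subject_id)
  if (length(overlap))
    stop("train/test leakage: ", paste(overlap, collapse = ", "))
  if (length(unique(test$group)) < 2)
    stop("single-class test set: AUC undefined")
  scores <- predict(model, test)
  y <- as.integer(test$group == model$positive)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0); tn <- sum(pred == 0 & y == 0)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(predicted = c("pos", "neg"),
                                      truth = c("pos", "neg")))
  structure(
    list(accuracy = (tp + tn) / length(y),
         auc = .auc_score(y, scores),
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         confusion = confusion,
         importance = feature_importance(model),
         params = model$params, positive = model$positive,
         negative = model$negative, n_test = length(y), scores = scores),
    class = "flemark_report"
  )
}

#' @export
print.flemark_report <- function(x, ...) {
  cat(sprintf("Classification report: %s vs %s (n_test = %d)\n",
              x$positive, x$negative, x$n_test))
  cat(sprintf(
    "  accuracy %.3f  AUC %.3f  sensitivity %.3f  specificity %.3f\n",
    x$accuracy, x$auc, x$sensitivity, x$specificity))
  cat("  top features:",
      paste(utils::head(x$importance$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Gain-based feature importance
#'
#' Total loss-reduction (gain) contributed by each feature across the
#' boosted ensemble's splits, in descending order; features never used get
#' zero gain, and ties are broken by the model's column order.
#'
#' @param model A [tune_gbm()] model.
#' @return Data frame: `feature`, `gain`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "flemark_gbm")) stop("'model' must be a tuned model")
  imp <- xgboost::xgb.importance(feature_names = model$features,
                                 model = model$booster)
  gain <- setNames(rep(0, length(model$features)), model$features)
  if (!is.null(imp) && nrow(imp) > 0) gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, seq_along(gain))
  data.frame(feature = names(gain)[ord], gain = unname(gain)[ord],
             stringsAsFactors = FALSE)
}

#' Run one pairwise classification task end to end
#'
#' Subsets the feature table to the task's two groups, splits 80/20
#' stratified, tunes on the training part, and evaluates on the held-out
#' part. The patient group of each task is the positive class.
#'
#' @param features Assembled feature table.
#' @param task `"FLE-vs-CTL"`, `"PCE-vs-CTL"`, or `"FLE-vs-PCE"`.
#' @param feature_set Passed to [feature_cols()].
#' @param seed Integer seed (controls split and tuning).
#' @param test_fraction,k_folds,n_bayes_iter See [split_train_test()] and
#'   [tune_gbm()].
#' @return A `"flemark_report"` (with the fitted model in `$model`).
#' @export
classify_task <- function(features,
                          task = c("FLE-vs-CTL", "PCE-vs-CTL", "FLE-vs-PCE"),
                          feature_set = "standard", seed = 1L,
                          test_fraction = 0.2, k_folds = 5,
                          n_bayes_iter = 25) {
  task <- match.arg(task)
  gs <- strsplit(task, "-vs-")[[1]]
  sub <- features[features$group %in% gs, , drop = FALSE]
  sp <- split_train_test(sub, test_fraction, seed = seed)
  cols <- intersect(feature_cols(feature_set), names(features))
  model <- tune_gbm(sp$train, positive = gs[1], features = cols,
                    k_folds = k_folds, n_bayes_iter = n_bayes_iter,
                    seed = seed)
  rep <- evaluate(model, sp$test)
  rep$task <- task
  rep$model <- model
  rep
}

#' Ablation analyses over the three pairwise tasks
#'
#' For each task and seed, runs three controlled variants on identical
#' train/test splits: the standard 17-feature model, a neuro-only model (10
#' tract FAs + 3 network summaries), and an extended 27-feature model that
#' adds the 10 cognitive subtest scores. Reports per-run accuracy and AUC
#' and the paired deltas against the standard model.
#'
#' @param features Feature table assembled with `include_cognitive = TRUE`.
#' @param tasks Tasks to run (default all three).
#' @param seeds Integer vector of seeds (one split per seed).
#' @param test_fraction,k_folds,n_bayes_iter Passed to [classify_task()].
#' @return Object of class `"flemark_ablation"`: data frame of runs plus a
#'   paired-delta summary.
#' @export
ablation_suite <- function(features,
                           tasks = c("FLE-vs-CTL", "PCE-vs-CTL",
                                     "FLE-vs-PCE"),
                           seeds = 1:5, test_fraction = 0.2, k_folds = 5,
                           n_bayes_iter = 10) {
  cog <- setdiff(feature_cols("extended"), feature_cols("standard"))
  if (!all(cog %in% names(features)))
    stop("ablation needs a feature table with include_cognitive = TRUE")
  rows <- list(); reports <- list()
  for (task in tasks) for (seed in seeds) {
    for (variant in c("standard", "neuro", "extended")) {
      rep <- classify_task(features, task, feature_set = variant,
                           seed = seed, test_fraction = test_fraction,
                           k_folds = k_folds, n_bayes_iter = n_bayes_iter)
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, seed = seed, variant = variant,
        accuracy = rep$accuracy, auc = rep$auc, stringsAsFactors = FALSE)
      reports[[paste(task, seed, variant, sep = "/")]] <- rep
    }
  }
  runs <- do.call(rbind, rows)
  wide <- stats::reshape(runs, idvar = c("task", "seed"),
                         timevar = "variant", direction = "wide")
  delta <- data.frame(
    task = wide$task, seed = wide$seed,
    d_acc_neuro = wide$accuracy.neuro - wide$accuracy.standard,
    d_auc_neuro = wide$auc.neuro - wide$auc.standard,
    d_acc_extended = wide$accuracy.extended - wide$accuracy.standard,
    d_auc_extended = wide$auc.extended - wide$auc.standard)
  structure(list(runs = runs, deltas = delta, reports = reports),
            class = "flemark_ablation")
}

#' @export
print.flemark_ablation <- function(x, ...) {
  cat("Ablation suite (", length(unique(x$runs$seed)), " seed(s))\n",
      sep = "")
  agg <- stats::aggregate(cbind(accuracy, auc) ~ task + variant,
                          data = x$runs, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
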
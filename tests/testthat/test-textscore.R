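test_that("questionnaire sheets are scored one point per correct item", {
  expect_equal(score_sheet(make_sheet(10, 10)),
               c(verb = 10, circ = 10, total = 20))
  expect_equal(score_sheet(make_sheet(10, 10, dont_remember = TRUE)),
               c(verb = 0, circ = 0, total = 0))
  expect_equal(score_sheet(make_sheet(7, 4)),
               c(verb = 7, circ = 4, total = 11))
  expect_error(score_sheet(make_sheet()[1:19, ]), "exactly 20")
  bad <- make_sheet(); bad$item_type <- rep("verb", 20)
  expect_error(score_sheet(bad), "10 items of each type")
})

test_that("conditions aggregate over the two texts of each type", {
  sheets <- rbind(make_sheet(10, 10, text_id = "AT1"),
                  make_sheet(10, 10, text_id = "AT2"),
                  make_sheet(10, 10, text_id = "NT1"),
                  make_sheet(10, 10, text_id = "NT2"))
  expect_equal(aggregate_conditions(sheets),
               c(at_verb = 20, at_circ = 20, nt_verb = 20, nt_circ = 20))
  sheets2 <- rbind(make_sheet(6, 3, text_id = "AT1"),
                   make_sheet(9, 5, text_id = "AT2"),
                   make_sheet(2, 8, text_id = "NT1"),
                   make_sheet(1, 7, text_id = "NT2"))
  expect_equal(aggregate_conditions(sheets2),
               c(at_verb = 15, at_circ = 8, nt_verb = 3, nt_circ = 15))
  expect_error(aggregate_conditions(sheets[0, ]), "empty")
  expect_error(aggregate_conditions(sheets[sheets$text_id != "NT2", ]),
               "one sheet per text")
})

test_that("effect sizes match their defining formulas", {
  expect_identical(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(cohens_d(c(1, 2, 3), c(0, 1, 2)), 1)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
  expect_equal(partial_eta2(30, 70), 0.3)
})

test_that("split-plot F statistics match a least-squares projection oracle", {
  # tiny balanced 2x2 design (2 groups x 2 information levels, 4 per cell)
  set.seed(14)
  n <- 8
  scores <- data.frame(
    subject_id = sprintf("S%d", 1:n),
    at_verb = c(12, 14, 11, 15, 8, 9, 7, 10),
    at_circ = c(13, 15, 12, 14, 12, 13, 11, 14),
    nt_verb = 10 + rpois(n, 2), nt_circ = 10 + rpois(n, 2))
  groups <- rep(c("CTL", "FLE"), each = 4)
  cov <- list(moca = rnorm(n, 26), ifs = rnorm(n, 25))
  fit <- fit_group_by_information(scores, groups, cov, "AT")

  # independent oracle: classical balanced split-plot sums of squares
  y <- cbind(scores$at_circ, scores$at_verb)  # subject x condition
  gm <- mean(y)
  subj_m <- rowMeans(y); grp_m <- tapply(subj_m, groups, mean)
  info_m <- colMeans(y)
  cell_m <- rbind(tapply(y[, 1], groups, mean), tapply(y[, 2], groups, mean))
  ss_group <- 2 * sum(4 * (grp_m - gm)^2)
  ss_subj <- 2 * sum((subj_m - grp_m[groups])^2)
  ss_info <- n * sum((info_m - gm)^2)
  ss_cells <- 4 * sum((t(cell_m) - gm)^2)
  ss_int <- ss_cells - ss_group - ss_info
  ss_tot <- sum((y - gm)^2)
  ss_werr <- ss_tot - ss_group - ss_subj - ss_info - ss_int
  F_group <- (ss_group / 1) / (ss_subj / (n - 2))
  F_info <- (ss_info / 1) / (ss_werr / (n - 2))
  F_int <- (ss_int / 1) / (ss_werr / (n - 2))

  eff <- fit$effects[!fit$effects$adjusted, ]
  expect_equal(eff$F[eff$effect == "group"], F_group, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "info"], F_info, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "group:info"], F_int, tolerance = 1e-8)
  expect_equal(eff$partial_eta2[eff$effect == "group:info"],
               ss_int / (ss_int + ss_werr), tolerance = 1e-8)
})

test_that("F is invariant to constant shifts and to zero-variance covariates", {
  coh <- gen_cohort(cohort_config(n_timepoints = 8, seed = 17))
  g <- coh$subjects$group
  cov <- coh$subjects[c("moca", "ifs")]
  f1 <- fit_group_by_information(coh$behavior, g, cov, "AT")
  shifted <- coh$behavior
  for (cl in c("at_verb", "at_circ")) shifted[[cl]] <- shifted[[cl]] + 5
  f2 <- fit_group_by_information(shifted, g, cov, "AT")
  expect_equal(f1$effects$F, f2$effects$F, tolerance = 1e-10)
  flat <- list(moca = rep(26, nrow(coh$subjects)),
               ifs = rep(25, nrow(coh$subjects)))
  f3 <- fit_group_by_information(coh$behavior, g, flat, "AT")
  raw <- f3$effects[!f3$effects$adjusted, ]
  adj <- f3$effects[f3$effects$adjusted, ]
  expect_equal(adj$F, raw$F, tolerance = 1e-10)
})

test_that("Tukey HSD behaves like a studentized-range correction", {
  set.seed(20)
  same <- list(a = rnorm(19), b = rnorm(19))
  same$b <- same$a  # identical cells
  expect_gt(tukey_hsd(same)$p_tukey, 0.99)
  sep <- list(a = rnorm(19), b = rnorm(19) + 4)  # d > 3
  expect_lt(tukey_hsd(sep)$p_tukey, 0.01)
  # adjusted p never smaller than the pooled-variance pairwise t test p
  for (i in 1:10) {
    cells <- list(a = rnorm(10), b = rnorm(10, 0.5), c = rnorm(10, 1))
    th <- tukey_hsd(cells)
    for (k in seq_len(nrow(th))) {
      pr <- strsplit(th$pair[k], " - ")[[1]]
      praw <- t.test(cells[[pr[1]]], cells[[pr[2]]], var.equal = TRUE)$p.value
      expect_gte(th$p_tukey[k] + 1e-12, praw * 0.999)
    }
  }
  expect_error(tukey_hsd(list(a = 1, b = c(1, 2))), "at least 2 observations")
})
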
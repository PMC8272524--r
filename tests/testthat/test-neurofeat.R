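test_that("tract means average labeled elements and flag empty tracts", {
  m <- data.frame(tract_label = rep("ATR", 3), fa = c(0.4, 0.5, 0.6))
  out <- tract_mean_fa(m)
  expect_equal(out[["ATR"]], 0.5)
  expect_true(all(is.na(out[setdiff(tract_names(), "ATR")])))
  const <- data.frame(tract_label = rep("CST", 5), fa = rep(0.37, 5))
  expect_equal(tract_mean_fa(const)[["CST"]], 0.37)
  empty <- data.frame(tract_label = character(), fa = numeric())
  expect_true(all(is.na(tract_mean_fa(empty))))
  expect_error(tract_mean_fa(data.frame(tract_label = "ATR", fa = 1.3)),
               "\\[0, 1\\]")
  expect_error(tract_mean_fa(data.frame(tract_label = "XX", fa = 0.5)),
               "unknown tract")
})

test_that("per-tract group comparison is a one-tailed Welch t with BH-FDR", {
  cfg <- cohort_config(n_timepoints = 8, seed = 5)
  fa <- gen_fa(cfg)
  # identical groups: t = 0, one-tailed p = 0.5
  fa_same <- fa
  fa_same[fa_same$group == "FLE", tract_names()] <-
    fa_same[fa_same$group == "CTL", tract_names()]
  same <- group_fa_compare(fa_same, fa_same$group)
  expect_equal(same$t, rep(0, 10), tolerance = 1e-12)
  expect_equal(same$p, rep(0.5, 10), tolerance = 1e-12)
  # toy data vs the closed-form Welch statistic
  a <- c(0.50, 0.52, 0.48); b <- c(0.40, 0.42, 0.38)
  toy <- data.frame(subject_id = sprintf("S%d", 1:6),
                    group = rep(c("CTL", "FLE"), each = 3))
  for (tr in tract_names()) toy[[tr]] <- c(a, b)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  cmp <- group_fa_compare(toy, toy$group)
  expect_equal(cmp$t, rep(t_hand, 10), tolerance = 1e-12)
  # label swap negates t
  cmp_sw <- group_fa_compare(toy, toy$group, "FLE", "CTL")
  expect_equal(cmp_sw$t, -cmp$t, tolerance = 1e-12)
  # FDR rejections are a subset of uncorrected rejections
  real <- group_fa_compare(fa, fa$group)
  expect_true(all(real$p_fdr >= real$p - 1e-15))
  expect_true(all(which(real$p_fdr < 0.05) %in% which(real$p < 0.05)))
})

test_that("max-statistic FWE p equals exhaustive enumeration for 4 vs 4", {
  set.seed(8)
  feats <- matrix(rnorm(8 * 5), 8, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  feats[1:4, 2] <- feats[1:4, 2] + 2
  labels <- rep(c("A", "B"), each = 4)
  res <- permutation_maxstat(feats, labels, exact = TRUE)

  # independent oracle: explicit loop over all 70 labelings
  welch_t <- function(x, g1) {
    a <- x[g1]; b <- x[!g1]
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  combs <- combn(8, 4)
  maxs <- apply(combs, 2, function(ii) {
    g <- rep(FALSE, 8); g[ii] <- TRUE
    max(abs(apply(feats, 2, welch_t, g1 = g)))
  })
  obs <- abs(apply(feats, 2, welch_t, g1 = labels == "A"))
  p_oracle <- vapply(obs, function(t0) mean(maxs >= t0 - 1e-12), 0)
  expect_equal(res$p_fwe, unname(p_oracle), tolerance = 1e-15)
})

test_that("max-statistic FWE has a p floor and is monotone in |t|", {
  set.seed(12)
  feats <- matrix(rnorm(30 * 6), 30, 6)
  feats[1:15, 3] <- feats[1:15, 3] + 5
  labels <- rep(c("A", "B"), each = 15)
  res <- permutation_maxstat(feats, labels, n_perm = 199, seed = 1)
  expect_equal(res$p_fwe[3], 1 / 200)
  ord <- order(abs(res$t))
  expect_true(all(diff(res$p_fwe[ord]) <= 1e-12))
  expect_error(permutation_maxstat(feats, rep("A", 30)), "two groups")
  expect_error(permutation_maxstat(feats, labels, n_perm = 10), "100")
})

test_that("seed maps report wSDM per target in [0, 1]", {
  set.seed(4)
  seed_series <- rnorm(150)
  targets <- rbind(T1 = seed_series, T2 = rnorm(150), T3 = rnorm(150))
  sm <- seed_connectivity_map(seed_series, targets)
  expect_gt(sm[["T1"]], 0.9)
  expect_lt(sm[["T2"]], 0.3)
  # the finite-sample self-dependence estimate may overshoot 1 by O(1/n)
  expect_true(all(sm >= 0 & sm <= 1 + 0.01))
})

test_that("group map comparison flags the planted hypoconnectivity", {
  coh <- gen_cohort(cohort_config(seed = 42))
  keep <- coh$subjects$group %in% c("FLE", "CTL")
  sub <- coh
  sub$timeseries <- coh$timeseries[keep]
  maps <- cohort_seed_maps(sub, seeds = c("M1-L", "M1-R"))
  mn <- (maps[["M1-L"]] + maps[["M1-R"]]) / 2
  cmp <- group_map_compare(mn, coh$subjects$group[keep])
  expect_true(cmp$peak$target %in% c("ParOp-L", "SMG-L"))
  # reported d is consistent with the effect-size routine on the same data
  g <- coh$subjects$group[keep]
  expect_equal(cmp$peak$d,
               cohens_d(mn[g == "CTL", cmp$peak$target],
                        mn[g == "FLE", cmp$peak$target]),
               tolerance = 1e-12)
  # identical groups: nothing survives
  fake <- mn; fake[g == "FLE", ] <- fake[g == "CTL", ][1:sum(g == "FLE"), ]
  cmp0 <- group_map_compare(fake + matrix(rnorm(length(fake), sd = 1e-3),
                                          nrow(fake)), g)
  expect_gt(min(cmp0$table$p_fdr), 0.05)
})

test_that("network summaries average each network's seed maps", {
  maps <- list(
    "M1-L" = matrix(0.5, 3, 2, dimnames = list(paste0("S", 1:3), c("a", "b"))),
    "M1-R" = matrix(0.5, 3, 2, dimnames = list(paste0("S", 1:3), c("a", "b"))),
    "V1-L" = matrix(c(0.2, 0.4, 0.6, 0.2, 0.4, 0.6), 3, 2,
                    dimnames = list(paste0("S", 1:3), c("a", "b"))))
  nw <- network_summary(maps, list(MN = c("M1-L", "M1-R"), VN = "V1-L"))
  expect_equal(nw$MN, rep(0.5, 3))
  expect_equal(nw$VN, c(0.2, 0.4, 0.6))  # single-seed network = its row mean
  expect_error(network_summary(maps, list(MN = "nope")), "unknown seed")
})
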
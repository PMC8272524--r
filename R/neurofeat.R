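#' Tract-level mean FA from a labeled FA map
#'
#' Averages fractional anisotropy over the elements (voxels or parcels)
#' labeled with each of the 10 JHU white-matter tracts. Tracts with no
#' labeled elements are returned as `NA` (missing).
#'
#' @param fa_map Data frame with columns `tract_label` and `fa`
#'   (one row per labeled element); `fa` must lie in \[0, 1\].
#' @return Named numeric vector over the 10 tracts ([tract_names()]).
#' @export
tract_mean_fa <- function(fa_map) {
  if (nrow(fa_map) > 0) {
    if (any(!is.finite(fa_map$fa)) || any(fa_map$fa < 0 | fa_map$fa > 1))
      stop("FA values must lie in [0, 1]")
    bad <- setdiff(unique(fa_map$tract_label), tract_names())
    if (length(bad))
      stop("unknown tract labels: ", paste(bad, collapse = ", "))
  }
  out <- setNames(rep(NA_real_, 10), tract_names())
  if (nrow(fa_map) > 0) {
    m <- tapply(fa_map$fa, factor(fa_map$tract_label, tract_names()), mean)
    out[names(m)] <- as.numeric(m)
  }
  out
}

#' Per-tract group comparison of FA with BH-FDR
#'
#' Welch (unequal-variance) two-sample t-tests per tract, one-tailed in the
#' hypothesized direction (`group_a` greater than `group_b` by default, i.e.
#' reduced integrity in the patient group), Benjamini-Hochberg corrected
#' across the 10 tracts, with Cohen's d attached.
#'
#' @param fa FA table: data frame with `subject_id` and the 10 tract columns.
#' @param groups Group label per row of `fa`.
#' @param group_a,group_b The two groups to compare; the alternative is
#'   mean(`group_a`) > mean(`group_b`) when `tail = "one_tailed"`.
#' @param tail `"one_tailed"` (default) or `"two_tailed"`.
#' @return Data frame with one row per tract: `tract`, `t`, `df`, `p`, `d`,
#'   `p_fdr`.
#' @export
group_fa_compare <- function(fa, groups, group_a = "CTL", group_b = "FLE",
                             tail = c("one_tailed", "two_tailed")) {
  tail <- match.arg(tail)
  ia <- groups == group_a; ib <- groups == group_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("need >= 2 subjects per group")
  alt <- if (tail == "one_tailed") "greater" else "two.sided"
  rows <- lapply(tract_names(), function(tr) {
    a <- fa[[tr]][ia]; b <- fa[[tr]][ib]
    if (var(a) == 0 && var(b) == 0) stop("zero variance in both groups: ", tr)
    tt <- t.test(a, b, alternative = alt)
    data.frame(tract = tr, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               d = cohens_d(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, "BH")
  out
}

# vectorized Welch t across columns of a feature matrix
.welch_t_cols <- function(x, lab1) {
  x1 <- x[lab1, , drop = FALSE]; x2 <- x[!lab1, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, var); v2 <- apply(x2, 2, var)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

#' Max-statistic permutation test with family-wise error control
#'
#' Compares each feature between two groups with a Welch t statistic and
#' adjusts for multiplicity by the permutation distribution of the maximum
#' absolute statistic across features: the adjusted p of a feature is the
#' proportion of (random or exhaustive) group relabelings whose maximum |t|
#' reaches that feature's observed |t|. In random mode the observed labeling
#' is included, so the smallest attainable p is 1/(n_perm + 1). This is the
#' parcel/tract-level counterpart of voxelwise permutation FWE inference.
#'
#' @param features Subject x feature numeric matrix.
#' @param labels Two-level group label per subject.
#' @param n_perm Number of random permutations (>= 100).
#' @param seed Optional integer seed for the permutations.
#' @param exact If `TRUE`, enumerate all distinct group assignments instead
#'   of sampling (feasible for small samples; capped at 200000 labelings).
#' @return Data frame: `feature`, `t`, `p_fwe`.
#' @export
permutation_maxstat <- function(features, labels, n_perm = 1000, seed = NULL,
                                exact = FALSE) {
  features <- as.matrix(features)
  lv <- unique(labels)
  if (length(lv) != 2) stop("'labels' must contain exactly two groups")
  if (!exact && n_perm < 100) stop("'n_perm' must be >= 100")
  lab1 <- labels == lv[1]
  t_obs <- .welch_t_cols(features, lab1)
  n <- length(labels); n1 <- sum(lab1)
  if (exact) {
    if (choose(n, n1) > 2e5) stop("exhaustive enumeration infeasible: ",
                                  choose(n, n1), " labelings")
    idx <- combn(n, n1)
    maxs <- apply(idx, 2, function(ii) {
      l <- rep(FALSE, n); l[ii] <- TRUE
      max(abs(.welch_t_cols(features, l)))
    })
  } else {
    if (!is.null(seed)) set.seed(seed)
    maxs <- c(max(abs(t_obs)), replicate(n_perm, {
      l <- rep(FALSE, n); l[sample.int(n, n1)] <- TRUE
      max(abs(.welch_t_cols(features, l)))
    }))
  }
  p_fwe <- vapply(abs(t_obs), function(tv) mean(maxs >= tv - 1e-12), 0)
  data.frame(feature = colnames(features) %||% seq_along(t_obs),
             t = t_obs, p_fwe = p_fwe, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed-based wSDM connectivity map
#'
#' The wSDM between one seed series and each target series.
#'
#' @param seed_series Numeric series (length >= 8).
#' @param target_series_set Target x time numeric matrix with row names.
#' @param factor Passed to [wsdm()].
#' @return Named numeric vector of wSDM values, one per target.
#' @export
seed_connectivity_map <- function(seed_series, target_series_set,
                                  factor = c("phi2", "phi")) {
  factor <- match.arg(factor)
  apply(target_series_set, 1,
        function(tg) wsdm(seed_series, tg, factor)$wsdm)
}

#' Seed maps for every subject of a cohort
#'
#' Computes, for each requested seed parcel, the subject x target matrix of
#' wSDM values against the target parcel set.
#'
#' @param cohort A [gen_cohort()] object (or any list with a `timeseries`
#'   element of region x time matrices).
#' @param seeds Character vector of seed parcel names (default: all seeds of
#'   [default_networks()]).
#' @param targets Character vector of target parcel names.
#' @return Named list (one element per seed) of subject x target matrices.
#' @export
cohort_seed_maps <- function(cohort, seeds = unlist(default_networks()),
                             targets = default_targets()) {
  seeds <- unname(seeds)
  subj <- names(cohort$timeseries)
  out <- lapply(seeds, function(sd) {
    m <- t(vapply(cohort$timeseries, function(ts) {
      seed_connectivity_map(ts[sd, ], ts[targets, , drop = FALSE])
    }, numeric(length(targets))))
    dimnames(m) <- list(subj, targets)
    m
  })
  names(out) <- seeds
  out
}

#' Group comparison of seed maps with BH-FDR and peak report
#'
#' Two-sample Welch t per target parcel between two groups of subjects,
#' Benjamini-Hochberg corrected across the targets of the map; the target
#' with the smallest p is reported as the peak.
#'
#' @param maps Subject x target matrix of map values (e.g. the average of
#'   the two M1 seed maps).
#' @param groups Group label per subject (two levels compared as
#'   `group_a` vs `group_b`).
#' @param group_a,group_b Groups to compare (t > 0 means `group_a` higher).
#' @return List of class `"flemark_map_compare"`: `table` (per-target t, p,
#'   p_fdr, d) and `peak` (the row with smallest p).
#' @export
group_map_compare <- function(maps, groups, group_a = "CTL",
                              group_b = "FLE") {
  ia <- groups == group_a; ib <- groups == group_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("need >= 2 subjects per group")
  rows <- lapply(colnames(maps), function(tg) {
    a <- maps[ia, tg]; b <- maps[ib, tg]
    tt <- t.test(a, b)
    data.frame(target = tg, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               d = cohens_d(a, b), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- p.adjust(tab$p, "BH")
  structure(list(table = tab, peak = tab[which.min(tab$p), ],
                 contrast = paste(group_a, "vs", group_b)),
            class = "flemark_map_compare")
}

#' @export
print.flemark_map_compare <- function(x, ...) {
  cat("Seed-map group comparison:", x$contrast, "\n")
  tab <- x$table
  tab[c("t", "d")] <- round(tab[c("t", "d")], 3)
  tab[c("p", "p_fdr")] <- round(tab[c("p", "p_fdr")], 4)
  print(tab, row.names = FALSE)
  cat("peak target:", x$peak$target, "\n")
  invisible(x)
}

#' Network-level wSDM summaries per subject
#'
#' The subject-level mean of the wSDM seed-map entries over each network's
#' seeds (all targets pooled): one value per subject per network.
#'
#' @param seed_maps Named list of subject x target matrices, as returned by
#'   [cohort_seed_maps()].
#' @param networks Named list of seed-name vectors, e.g.
#'   [default_networks()].
#' @return Data frame: `subject_id` plus one column per network.
#' @export
network_summary <- function(seed_maps, networks = default_networks()) {
  unknown <- setdiff(unlist(networks), names(seed_maps))
  if (length(unknown))
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "))
  subj <- rownames(seed_maps[[1]])
  out <- data.frame(subject_id = subj, stringsAsFactors = FALSE)
  for (nw in names(networks)) {
    mats <- seed_maps[networks[[nw]]]
    out[[nw]] <- rowMeans(do.call(cbind, mats))
  }
  out
}
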
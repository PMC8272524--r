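#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample with 3 <= n <= 5000 and nonzero variance.
#' @return List with elements `W` and `p`.
#' @export
normality_check <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (var(x) == 0) stop("degenerate (constant) sample: W undefined")
  s <- shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Pearson correlation with t-distributed p-value
#'
#' @param x,y Numeric vectors of equal length n >= 3 with nonzero variance.
#' @return List with elements `r` and `p` (two-sided).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH adjustment with the usual monotonicity enforcement, plus the
#' rejection set at level `q`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `p_adj` (adjusted p-values) and `rejected` (indices).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- p.adjust(pvals, "BH")
  list(p_adj = p_adj, rejected = which(p_adj <= q))
}

#' Brain-behavior correlation screen with FDR
#'
#' For each group separately, Pearson-correlates the four condition scores
#' of the naturalistic text task (AT-V, AT-C, NT-V, NT-C) with (a) the mean
#' FA of each of the 10 tracts and (b) the three network-level wSDM
#' summaries, then applies Benjamini-Hochberg FDR within the chosen family.
#' The default family is per group per modality (FA correlations and
#' connectivity correlations corrected separately within each group).
#'
#' @param behavior Condition-score table (`subject_id`, `at_verb`, `at_circ`,
#'   `nt_verb`, `nt_circ`).
#' @param fa FA table (`subject_id` + 10 tract columns).
#' @param networks Network-summary table (`subject_id` + one column per
#'   network), e.g. from [network_summary()].
#' @param groups Group label per subject, aligned with `behavior`.
#' @param q FDR level.
#' @param family FDR family definition: `"per-group-per-modality"`
#'   (default), `"per-group"`, or `"global"`.
#' @return Data frame of class `"flemark_screen"`, one row per
#'   group x condition x measure, sorted by p: columns `group`, `condition`,
#'   `modality`, `measure`, `r`, `p`, `p_fdr`.
#' @export
correlation_screen <- function(behavior, fa, networks, groups, q = 0.05,
                               family = c("per-group-per-modality",
                                          "per-group", "global")) {
  family <- match.arg(family)
  miss <- c(setdiff(behavior$subject_id, fa$subject_id),
            setdiff(behavior$subject_id, networks$subject_id))
  if (length(miss))
    stop("subjects missing from fa/network tables: ",
         paste(unique(miss), collapse = ", "))
  fa <- fa[match(behavior$subject_id, fa$subject_id), ]
  networks <- networks[match(behavior$subject_id, networks$subject_id), ]
  conds <- c("AT-V" = "at_verb", "AT-C" = "at_circ",
             "NT-V" = "nt_verb", "NT-C" = "nt_circ")
  nw_cols <- setdiff(names(networks), "subject_id")
  measures <- rbind(
    data.frame(modality = "FA", measure = tract_names(),
               stringsAsFactors = FALSE),
    data.frame(modality = "rsFC", measure = nw_cols,
               stringsAsFactors = FALSE)
  )
  rows <- list()
  for (g in unique(groups)) {
    ig <- groups == g
    for (ci in seq_along(conds)) {
      y <- behavior[[conds[ci]]][ig]
      for (mi in seq_len(nrow(measures))) {
        src <- if (measures$modality[mi] == "FA") fa else networks
        x <- src[[measures$measure[mi]]][ig]
        pc <- pearson_corr(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, condition = names(conds)[ci],
          modality = measures$modality[mi], measure = measures$measure[mi],
          r = pc$r, p = pc$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  fam <- switch(family,
    "global" = rep("all", nrow(out)),
    "per-group" = out$group,
    "per-group-per-modality" = paste(out$group, out$modality)
  )
  out$p_fdr <- NA_real_
  for (f in unique(fam)) {
    i <- fam == f
    out$p_fdr[i] <- p.adjust(out$p[i], "BH")
  }
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "q") <- q
  class(out) <- c("flemark_screen", "data.frame")
  out
}

#' @export
print.flemark_screen <- function(x, n = 10, ...) {
  cat("Brain-behavior correlation screen (", nrow(x), " records, q = ",
      attr(x, "q"), ")\n", sep = "")
  y <- as.data.frame(x)
  y$r <- round(y$r, 3); y[c("p", "p_fdr")] <- round(y[c("p", "p_fdr")], 4)
  print(utils::head(y, n), row.names = FALSE)
  nsig <- sum(x$p_fdr <= attr(x, "q"))
  cat(nsig, "record(s) FDR-significant\n")
  invisible(x)
}
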
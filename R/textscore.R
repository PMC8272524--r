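#' Score one comprehension questionnaire
#'
#' Each naturalistic text comes with a 20-item multiple-choice questionnaire:
#' 10 items probe verb-related information and 10 probe circumstantial
#' information. A correct choice earns one point; incorrect choices and
#' "I don't remember" earn zero, so each sheet scores 0-20 (0-10 per item
#' type).
#'
#' @param sheet Data frame with one row per item and columns `item_type`
#'   (`"verb"` or `"circumstantial"`), `chosen_option`, `correct_option`,
#'   and `is_dont_remember` (logical). Exactly 20 rows, 10 per item type.
#' @return Named numeric vector `c(verb, circ, total)`.
#' @export
score_sheet <- function(sheet) {
  req <- c("item_type", "chosen_option", "correct_option", "is_dont_remember")
  if (!all(req %in% names(sheet)))
    stop("sheet must have columns: ", paste(req, collapse = ", "))
  if (nrow(sheet) != 20L)
    stop("a response sheet must have exactly 20 items, got ", nrow(sheet))
  tt <- table(factor(sheet$item_type, c("verb", "circumstantial")))
  if (any(tt != 10L))
    stop("a response sheet must have exactly 10 items of each type")
  ok <- !sheet$is_dont_remember & sheet$chosen_option == sheet$correct_option
  verb <- sum(ok[sheet$item_type == "verb"])
  circ <- sum(ok[sheet$item_type == "circumstantial"])
  c(verb = verb, circ = circ, total = verb + circ)
}

#' Aggregate four questionnaires into condition scores
#'
#' Sums the verb and circumstantial scores of the two action texts (AT1, AT2)
#' and the two neutral texts (NT1, NT2), yielding the four condition scores
#' (each 0-20) used by every downstream analysis.
#'
#' @param sheets Data frame of item-level responses for one subject with a
#'   `text_id` column in `{AT1, AT2, NT1, NT2}` plus the columns required by
#'   [score_sheet()]; exactly one 20-item sheet per text.
#' @return Named numeric vector `c(at_verb, at_circ, nt_verb, nt_circ)`.
#' @export
aggregate_conditions <- function(sheets) {
  if (is.null(sheets) || nrow(sheets) == 0L) stop("empty sheet set")
  ids <- c("AT1", "AT2", "NT1", "NT2")
  got <- unique(sheets$text_id)
  if (!setequal(got, ids))
    stop("need exactly one sheet per text id (AT1, AT2, NT1, NT2); got: ",
         paste(sort(got), collapse = ", "))
  sc <- sapply(ids, function(id) score_sheet(sheets[sheets$text_id == id, ]))
  c(at_verb = sc["verb", "AT1"] + sc["verb", "AT2"],
    at_circ = sc["circ", "AT1"] + sc["circ", "AT2"],
    nt_verb = sc["verb", "NT1"] + sc["verb", "NT2"],
    nt_circ = sc["circ", "NT1"] + sc["circ", "NT2"])
}

#' Cohen's d for two independent samples
#'
#' Mean difference divided by the pooled standard deviation.
#'
#' @param a,b Numeric samples, each with n >= 2.
#' @return Cohen's d (a minus b).
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each sample")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Partial eta-squared from sums of squares
#'
#' @param ss_effect,ss_error Sums of squares of the effect and of the error
#'   term it is tested against.
#' @return `ss_effect / (ss_effect + ss_error)`.
#' @export
partial_eta2 <- function(ss_effect, ss_error) {
  ss_effect / (ss_effect + ss_error)
}

#' Tukey HSD pairwise comparisons over a set of cells
#'
#' Studentized-range adjusted p-values for all pairwise mean differences
#' among a set of cells, using the pooled within-cell mean square unless an
#' error term is supplied. Unbalanced designs use the harmonic mean of the
#' pair's cell sizes. Cohen's d is attached to each pair.
#'
#' @param cells Named list of numeric vectors (each >= 2 observations).
#' @param mse,df Optional error mean square and its degrees of freedom, e.g.
#'   from a mixed-design ANOVA; default is the pooled within-cell MSE with
#'   N - k df.
#' @return Data frame with one row per pair: `pair`, `diff`, `p_tukey`,
#'   `cohen_d`.
#' @export
tukey_hsd <- function(cells, mse = NULL, df = NULL) {
  if (length(cells) < 2) stop("need at least 2 cells")
  if (any(vapply(cells, length, 0L) < 2))
    stop("every cell needs at least 2 observations")
  k <- length(cells)
  ns <- vapply(cells, length, 0L)
  if (is.null(mse)) {
    ssw <- sum(vapply(cells, function(x) sum((x - mean(x))^2), 0))
    df <- sum(ns) - k
    mse <- ssw / df
  } else if (is.null(df)) stop("supply 'df' together with 'mse'")
  if (mse <= 0) stop("non-positive error mean square")
  prs <- combn(names(cells), 2)
  out <- apply(prs, 2, function(pr) {
    a <- cells[[pr[1]]]; b <- cells[[pr[2]]]
    nh <- 2 / (1 / length(a) + 1 / length(b))
    q <- abs(mean(a) - mean(b)) / sqrt(mse / nh)
    c(diff = mean(a) - mean(b),
      p_tukey = ptukey(q, k, df, lower.tail = FALSE),
      cohen_d = cohens_d(a, b))
  })
  data.frame(pair = paste(prs[1, ], prs[2, ], sep = " - "),
             t(out), row.names = NULL)
}

# pull one effect's row out of a summary.aov stratum table
.aov_effect_row <- function(tab, name) {
  rn <- trimws(rownames(tab))
  i <- match(name, rn)
  if (is.na(i)) return(NULL)
  resid <- match("Residuals", rn)
  data.frame(
    effect = name, F = tab[i, "F value"],
    df1 = tab[i, "Df"], df2 = tab[resid, "Df"],
    p = tab[i, "Pr(>F)"],
    partial_eta2 = partial_eta2(tab[i, "Sum Sq"], tab[resid, "Sum Sq"]),
    stringsAsFactors = FALSE
  )
}

.fit_split_plot <- function(dat, with_cov) {
  fml <- if (with_cov) {
    y ~ moca + ifs + group * info + Error(id / info)
  } else {
    y ~ group * info + Error(id / info)
  }
  fit <- aov(fml, data = dat)
  s <- summary(fit)
  between <- s[["Error: id"]][[1]]
  within <- s[["Error: id:info"]][[1]]
  rbind(
    .aov_effect_row(between, "group"),
    .aov_effect_row(within, "info"),
    .aov_effect_row(within, "group:info")
  )
}

#' Mixed-design Group x Information ANOVA for one text type
#'
#' Fits the split-plot ANOVA with one between-subject factor (Group: FLE,
#' CTL, PCE), one within-subject factor (Information type: verb-related vs
#' circumstantial), and the subject as the repeated unit, separately for the
#' action or neutral texts. Results are reported both without and with the
#' MoCA and IFS covariates entered as continuous between-subject regressors.
#' Tukey HSD post-hocs with Cohen's d are computed over the six
#' group-by-information cells.
#'
#' @param scores Condition-score data frame with columns `subject_id`,
#'   `at_verb`, `at_circ`, `nt_verb`, `nt_circ` (e.g. from [gen_behavior()]
#'   or [aggregate_conditions()]).
#' @param groups Character/factor vector of group labels, one per subject.
#' @param covariates Data frame or list with numeric `moca` and `ifs`
#'   vectors, one value per subject.
#' @param text_type `"AT"` (action texts) or `"NT"` (neutral texts).
#' @return An object of class `"flemark_anova"`: list with `text_type`,
#'   `effects` (a data frame of F, df, p and partial eta-squared for the
#'   Group and Information main effects and their interaction, unadjusted
#'   and covariate-adjusted), and `posthoc` (Tukey table over the 6 cells).
#' @export
fit_group_by_information <- function(scores, groups, covariates,
                                     text_type = c("AT", "NT")) {
  text_type <- match.arg(text_type)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 subjects per group")
  n <- nrow(scores)
  if (length(groups) != n) stop("'groups' length must match 'scores' rows")
  if (is.null(covariates$moca) || is.null(covariates$ifs) ||
      anyNA(covariates$moca) || anyNA(covariates$ifs))
    stop("'covariates' must provide complete moca and ifs vectors")
  cols <- if (text_type == "AT") c("at_verb", "at_circ")
          else c("nt_verb", "nt_circ")
  dat <- data.frame(
    id = factor(rep(scores$subject_id, 2)),
    group = rep(groups, 2),
    info = factor(rep(c("verb", "circ"), each = n), c("circ", "verb")),
    moca = rep(as.numeric(covariates$moca), 2),
    ifs = rep(as.numeric(covariates$ifs), 2),
    y = c(scores[[cols[1]]], scores[[cols[2]]])
  )
  eff_raw <- .fit_split_plot(dat, with_cov = FALSE)
  eff_adj <- tryCatch(.fit_split_plot(dat, with_cov = TRUE),
                      error = function(e)
                        stop("singular covariate-adjusted design: ",
                             conditionMessage(e)))
  eff_raw$adjusted <- FALSE
  eff_adj$adjusted <- TRUE
  cells <- split(dat$y, interaction(dat$group, dat$info, sep = ":"))
  structure(
    list(text_type = text_type, effects = rbind(eff_raw, eff_adj),
         posthoc = tukey_hsd(cells), n = n),
    class = "flemark_anova"
  )
}

#' @export
print.flemark_anova <- function(x, ...) {
  cat(sprintf("Group x Information mixed-design ANOVA (%s texts, n = %d)\n",
              x$text_type, x$n))
  e <- x$effects
  e$F <- round(e$F, 3); e$p <- round(e$p, 4)
  e$partial_eta2 <- round(e$partial_eta2, 3)
  print(e, row.names = FALSE)
  cat("\nTukey HSD over group:information cells (top rows):\n")
  ph <- x$posthoc[order(x$posthoc$p_tukey), ]
  print(utils::head(ph, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.flemark_anova <- function(object, ...) {
  object$effects
}
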
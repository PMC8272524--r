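#' Configuration of a full pipeline run
#'
#' A single master seed determines every stochastic stage: the cohort draw,
#' the permutation test, and each classifier's split and tuning (stage seeds
#' are derived as fixed offsets of the master seed).
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (its
#'   `seed` is overridden by `master_seed`).
#' @param out_dir Output directory (created if absent).
#' @param n_perm Permutations for the max-statistic FWE test.
#' @param fdr_family FDR family for the correlation screen.
#' @param ml_seeds Seeds (splits) per classification task.
#' @param k_folds,n_bayes_iter Classifier tuning settings.
#' @param ablation Run the three-variant ablation suite.
#' @param master_seed Integer master seed.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_config(), out_dir = tempfile("flemark_"),
                       n_perm = 1000, fdr_family = "per-group-per-modality",
                       ml_seeds = 1L, k_folds = 5, n_bayes_iter = 10,
                       ablation = FALSE, master_seed = 1L) {
  cohort$seed <- as.integer(master_seed)
  structure(list(cohort = cohort, out_dir = out_dir, n_perm = n_perm,
                 fdr_family = fdr_family, ml_seeds = as.integer(ml_seeds),
                 k_folds = k_folds, n_bayes_iter = n_bayes_iter,
                 ablation = ablation, master_seed = as.integer(master_seed)),
            class = "run_config")
}

.fmt_num <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 12) else x
}

#' Write the tabular outputs of a cohort to CSV
#'
#' Writes `subjects.csv`, `behavior.csv`, `fa.csv` and a long-format
#' `timeseries.csv` (subject, parcel, t, value) into a directory.
#' Floating-point values are written at 12 significant digits.
#'
#' @param cohort A [gen_cohort()] object.
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    df[] <- lapply(df, .fmt_num)
    write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  wr(cohort$subjects, "subjects.csv")
  wr(cohort$behavior, "behavior.csv")
  wr(cohort$fa, "fa.csv")
  ts_long <- do.call(rbind, lapply(names(cohort$timeseries), function(s) {
    m <- cohort$timeseries[[s]]
    data.frame(subject_id = s, parcel = rep(rownames(m), ncol(m)),
               t = rep(seq_len(ncol(m)), each = nrow(m)),
               value = signif(as.numeric(m), 12), stringsAsFactors = FALSE)
  }))
  write.csv(ts_long, file.path(dir, "timeseries.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files.
#' @return List with `subjects`, `behavior`, `fa`, and `timeseries` (named
#'   list of parcel x time matrices).
#' @export
read_cohort_tables <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                             check.names = FALSE)
  ts_long <- rd("timeseries.csv")
  ts <- lapply(split(ts_long, ts_long$subject_id), function(d) {
    parcels <- unique(d$parcel)
    m <- matrix(d$value, nrow = length(parcels),
                dimnames = list(parcels, NULL))
    m
  })
  list(subjects = rd("subjects.csv"), behavior = rd("behavior.csv"),
       fa = rd("fa.csv"), timeseries = ts[unique(ts_long$subject_id)])
}

#' Validate pipeline input tables
#'
#' Checks schema, value ranges (FA in \[0, 1\], condition scores integers in
#' \[0, 20\]), and subject-ID consistency across the behavioral, FA and
#' subject tables. Returns a machine-readable issue list; zero rows means
#' the inputs are clean.
#'
#' @param tables Named list with `subjects`, `behavior`, `fa` data frames
#'   (e.g. from [read_cohort_tables()] or a [gen_cohort()] object).
#' @return Data frame with columns `table`, `row`, `column`, `issue`.
#' @export
validate_inputs <- function(tables) {
  issues <- list()
  add <- function(table, row, column, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      table = table, row = row, column = column, issue = issue,
      stringsAsFactors = FALSE)
  }
  need <- list(
    subjects = c("subject_id", "group"),
    behavior = c("subject_id", "at_verb", "at_circ", "nt_verb", "nt_circ"),
    fa = c("subject_id", tract_names()))
  for (tb in names(need)) {
    if (is.null(tables[[tb]])) { add(tb, NA, NA, "table missing"); next }
    mc <- setdiff(need[[tb]], names(tables[[tb]]))
    for (cl in mc) add(tb, NA, cl, "column missing")
  }
  if (length(issues)) return(do.call(rbind, issues))
  if (!all(tables$subjects$group %in% c("FLE", "CTL", "PCE"))) {
    bad <- which(!tables$subjects$group %in% c("FLE", "CTL", "PCE"))
    for (r in bad) add("subjects", r, "group", "unknown group label")
  }
  for (cl in c("at_verb", "at_circ", "nt_verb", "nt_circ")) {
    v <- tables$behavior[[cl]]
    bad <- which(!is.finite(v) | v < 0 | v > 20 | v != round(v))
    for (r in bad) add("behavior", r, cl, "score outside integer [0, 20]")
  }
  for (cl in tract_names()) {
    v <- tables$fa[[cl]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    for (r in bad) add("fa", r, cl, "FA outside [0, 1]")
  }
  ids <- tables$subjects$subject_id
  for (tb in c("behavior", "fa")) {
    for (s in setdiff(ids, tables[[tb]]$subject_id))
      add(tb, NA, "subject_id", paste0("subject ", s, " missing"))
    for (s in setdiff(tables[[tb]]$subject_id, ids))
      add(tb, NA, "subject_id", paste0("subject ", s, " not in subjects"))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(table = character(), row = integer(), column = character(),
                  issue = character(), stringsAsFactors = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates cohort generation, behavioral Group x Information ANOVAs
#' (action and neutral texts), per-tract FA comparisons (BH-FDR and
#' max-statistic permutation FWE), seed-map connectivity comparisons and
#' network summaries, the brain-behavior correlation screen, and the three
#' pairwise classifications (optionally with the ablation suite). All
#' tabular outputs and a provenance manifest (config, seeds, versions) are
#' written under `config$out_dir`; each stage writes before the next runs,
#' so partial outputs survive a failure.
#'
#' @param config A [run_config()].
#' @return Object of class `"flemark_run"` with elements `cohort`,
#'   `anova_at`, `anova_nt`, `fa_compare`, `fa_fwe`, `map_compare`,
#'   `networks`, `screen`, `classification`, (optionally `ablation`), and
#'   `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    df[] <- lapply(df, .fmt_num)
    write.csv(df, file.path(config$out_dir, f), row.names = FALSE)
  }
  cohort <- .stage("syndata", gen_cohort(config$cohort))
  write_cohort(cohort, config$out_dir)
  groups <- cohort$subjects$group
  cov <- cohort$subjects[c("moca", "ifs")]

  anova_at <- .stage("textscore",
    fit_group_by_information(cohort$behavior, groups, cov, "AT"))
  anova_nt <- .stage("textscore",
    fit_group_by_information(cohort$behavior, groups, cov, "NT"))
  wr(rbind(cbind(text = "AT", anova_at$effects),
           cbind(text = "NT", anova_nt$effects)), "anova.csv")

  pairs <- list(c("CTL", "FLE"), c("CTL", "PCE"), c("PCE", "FLE"))
  fa_compare <- .stage("neurofeat.fa", do.call(rbind, lapply(pairs,
    function(pr) cbind(contrast = paste(pr[1], "vs", pr[2]),
                       group_fa_compare(cohort$fa, groups, pr[1], pr[2])))))
  wr(fa_compare, "fa_compare.csv")
  ife <- groups %in% c("FLE", "CTL")
  fa_fwe <- .stage("neurofeat.fwe", permutation_maxstat(
    as.matrix(cohort$fa[ife, tract_names()]), groups[ife],
    n_perm = config$n_perm, seed = config$master_seed + 101L))
  wr(fa_fwe, "fa_fwe.csv")

  maps <- .stage("wsdm", cohort_seed_maps(cohort))
  networks <- .stage("wsdm", network_summary(maps))
  wr(networks, "networks.csv")
  mn <- (maps[["M1-L"]] + maps[["M1-R"]]) / 2
  map_compare <- .stage("neurofeat.maps", lapply(pairs, function(pr)
    group_map_compare(mn, groups, pr[1], pr[2])))
  names(map_compare) <- vapply(pairs, paste, "", collapse = "_vs_")
  wr(do.call(rbind, lapply(names(map_compare), function(nm)
    cbind(contrast = nm, map_compare[[nm]]$table))), "map_compare.csv")

  screen <- .stage("assoc", correlation_screen(
    cohort$behavior, cohort$fa, networks, groups,
    family = config$fdr_family))
  wr(as.data.frame(screen), "screen.csv")

  feats <- .stage("mlbench", assemble_features(
    cohort, include_cognitive = TRUE, networks = networks))
  wr(feats, "features.csv")
  tasks <- c("FLE-vs-CTL", "PCE-vs-CTL", "FLE-vs-PCE")
  classification <- .stage("mlbench", lapply(tasks, function(task) {
    lapply(config$ml_seeds, function(s)
      classify_task(feats, task, seed = config$master_seed + 200L + s,
                    k_folds = config$k_folds,
                    n_bayes_iter = config$n_bayes_iter))
  }))
  names(classification) <- tasks
  cls_tab <- do.call(rbind, lapply(tasks, function(task) {
    do.call(rbind, lapply(classification[[task]], function(r)
      data.frame(task = task, accuracy = r$accuracy, auc = r$auc,
                 sensitivity = r$sensitivity, specificity = r$specificity)))
  }))
  wr(cls_tab, "classification.csv")

  ablation <- NULL
  if (isTRUE(config$ablation)) {
    ablation <- .stage("mlbench.ablation", ablation_suite(
      feats, seeds = config$master_seed + 200L + config$ml_seeds,
      k_folds = config$k_folds, n_bayes_iter = config$n_bayes_iter))
    wr(ablation$runs, "ablation.csv")
  }

  manifest <- list(
    master_seed = config$master_seed,
    cohort = unclass(config$cohort),
    n_perm = config$n_perm, fdr_family = config$fdr_family,
    ml_seeds = config$ml_seeds, k_folds = config$k_folds,
    n_bayes_iter = config$n_bayes_iter,
    package_version = as.character(utils::packageVersion("flemark")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(cohort = cohort, anova_at = anova_at, anova_nt = anova_nt,
                 fa_compare = fa_compare, fa_fwe = fa_fwe,
                 map_compare = map_compare, networks = networks,
                 screen = screen, classification = classification,
                 ablation = ablation, manifest = manifest,
                 out_dir = config$out_dir),
            class = "flemark_run")
}

#' @export
print.flemark_run <- function(x, ...) {
  cat("flemark pipeline run (outputs in ", x$out_dir, ")\n", sep = "")
  ia <- x$anova_at$effects
  iar <- ia[ia$effect == "group:info" & ia$adjusted, ]
  cat(sprintf("  AT Group x Information (adjusted): F(%d,%d) = %.2f, p = %.4f\n",
              iar$df1, iar$df2, iar$F, iar$p))
  atr <- x$fa_compare[x$fa_compare$contrast == "CTL vs FLE" &
                        x$fa_compare$tract == "ATR", ]
  cat(sprintf("  ATR FA (CTL vs FLE): t = %.2f, FDR p = %.4f, d = %.2f\n",
              atr$t, atr$p_fdr, atr$d))
  pk <- x$map_compare[["CTL_vs_FLE"]]$peak
  cat(sprintf("  M1 map peak (CTL vs FLE): %s, t = %.2f, FDR p = %.4f\n",
              pk$target, pk$t, pk$p_fdr))
  for (task in names(x$classification)) {
    accs <- vapply(x$classification[[task]], `[[`, 0, "accuracy")
    aucs <- vapply(x$classification[[task]], `[[`, 0, "auc")
    cat(sprintf("  %s: mean accuracy %.3f, mean AUC %.3f (%d seed(s))\n",
                task, mean(accs), mean(aucs), length(accs)))
  }
  invisible(x)
}
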
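# Report assembly: demographics comparison table, full-pipeline driver
# with stage toggles, tidy table export and a JSON run manifest.

#' Demographic/behavioral group-comparison table
#'
#' One row per characteristic with per-group mean +/- SD and range, a
#' pooled two-sample t (TD minus ASD) with df and p for continuous
#' variables, and Fisher's exact p for the sex composition. ADOS scores
#' are summarized for the ASD group only, without a group test.
#'
#' @param demographics Demographics data frame.
#' @param variables Continuous columns to compare (defaults to age plus
#'   every `abc`/`gds_*` column present).
#' @return Data frame: `characteristic`, `td_summary`, `asd_summary`,
#'   `statistic`, `df`, `p`.
#' @export
demographics_table <- function(demographics,
                               variables = NULL) {
  dem <- demographics
  if (is.null(variables))
    variables <- intersect(c("age", "abc", "gds_language",
                             "gds_personal_social", "gds_gross_motor",
                             "gds_fine_motor", "gds_adaptive",
                             "gds_total"), names(dem))
  fmt <- function(x) sprintf("%.2f ± %.2f [%.2f, %.2f]",
                             mean(x), stats::sd(x), min(x), max(x))
  td <- dem[dem$group == "TD", ]; asd <- dem[dem$group == "ASD", ]
  rows <- lapply(variables, function(v) {
    tt <- two_sample_t_pooled(td[[v]], asd[[v]])
    data.frame(characteristic = v, td_summary = fmt(td[[v]]),
               asd_summary = fmt(asd[[v]]), statistic = tt$t,
               df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  sex_tab <- table(dem$group, dem$sex)
  rows[[length(rows) + 1]] <- data.frame(
    characteristic = "sex (M/F)",
    td_summary = paste(sex_tab["TD", c("M", "F")], collapse = "/"),
    asd_summary = paste(sex_tab["ASD", c("M", "F")], collapse = "/"),
    statistic = NA_real_, df = NA_real_,
    p = fisher_exact_2x2(sex_tab), stringsAsFactors = FALSE)
  for (v in intersect(c("ados_sa", "ados_rrb", "ados_total"),
                      names(dem))) {
    x <- asd[[v]][!is.na(asd[[v]])]
    if (length(x) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = v, td_summary = "-", asd_summary = fmt(x),
      statistic = NA_real_, df = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param stages Character vector of enabled stages, a subset of
#'   `c("demographics", "laterality", "tractwise", "pointwise",
#'   "associations", "severity")`.
#' @param perm A [perm_config()].
#' @param alpha Significance level.
#' @param min_cluster Minimum consecutive-node cluster length.
#' @param score Behavior score for the association stages.
#' @return List with class `run_config`.
#' @export
run_config <- function(stages = c("demographics", "laterality",
                                  "tractwise", "pointwise",
                                  "associations", "severity"),
                       perm = perm_config(), alpha = 0.05,
                       min_cluster = 4, score = "gds_language") {
  stopifnot(alpha > 0, alpha < 1, min_cluster >= 1)
  structure(list(stages = stages, perm = perm, alpha = alpha,
                 min_cluster = min_cluster, score = score),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a profile dataset
#' and matching demographics: demographics table, lateralization
#' analyses (one-sample, group comparison, behavior association),
#' tract-wise and point-wise group comparisons (the point-wise clusters
#' feed the cluster-level association stages), behavior and severity
#' associations. Optionally writes each result as a delimited table
#' plus a JSON manifest recording configuration, seed and row counts.
#'
#' @param ds A `tract_profiles` dataset.
#' @param demographics Demographics sharing subject ids with `ds`.
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return Named list of result tables (and the manifest), invisibly
#'   when writing, visibly otherwise.
#' @export
run_pipeline <- function(ds, demographics, cfg = run_config(),
                         out_dir = NULL) {
  ids_ds <- attr(ds, "subjects")
  orphans_ds <- setdiff(ids_ds, demographics$id)
  orphans_dem <- setdiff(demographics$id, ids_ds)
  if (length(orphans_ds) > 0 || length(orphans_dem) > 0)
    stop("subject ids do not reconcile; profiles-only: [",
         paste(orphans_ds, collapse = ", "), "], demographics-only: [",
         paste(orphans_dem, collapse = ", "), "]")
  res <- list()
  st <- cfg$stages
  if ("demographics" %in% st)
    res$demographics <- demographics_table(demographics)
  if ("laterality" %in% st) {
    li <- li_table(ds)
    res$li_subject <- li
    res$li_one_sample <- li_one_sample(li, demographics, cfg$perm,
                                       cfg$alpha)
    res$li_group <- li_group_compare(li, demographics, cfg$perm)
    if (cfg$score %in% names(demographics))
      res$li_behavior <- li_behavior(li, demographics, cfg$score,
                                     cfg$perm)
  }
  if ("tractwise" %in% st)
    res$tractwise <- tractwise_compare(ds, demographics, cfg$perm)
  clusters <- NULL
  if ("pointwise" %in% st) {
    pw <- pointwise_compare(ds, demographics, cfg$perm,
                            alpha = cfg$alpha,
                            min_cluster = cfg$min_cluster)
    res$pointwise_nodes <- pw$nodes
    res$pointwise_clusters <- pw$clusters
    res$node_summary <- node_group_summary(ds, demographics)
    clusters <- pw$clusters
  }
  if ("associations" %in% st && cfg$score %in% names(demographics)) {
    res$assoc_tract <- behavior_assoc(ds, demographics, cfg$score,
                                      level = "tract", cfg = cfg$perm)
    if (!is.null(clusters) && nrow(clusters) > 0)
      res$assoc_cluster <- behavior_assoc(ds, demographics, cfg$score,
                                          level = "cluster",
                                          clusters = clusters,
                                          cfg = cfg$perm)
  }
  if ("severity" %in% st && "ados_total" %in% names(demographics))
    res$severity <- severity_assoc(ds, demographics, clusters,
                                   cfg$perm)
  manifest <- list(
    stages = st, seed = cfg$perm$seed, n_perm = cfg$perm$n_perm,
    scheme = cfg$perm$scheme, alpha = cfg$alpha,
    min_cluster = cfg$min_cluster, score = cfg$score,
    n_subjects = length(ids_ds),
    n_tracts = length(attr(ds, "tracts")),
    n_nodes = length(attr(ds, "nodes")),
    row_counts = lapply(res, nrow))
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(res), "manifest"))
      utils::write.csv(res[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
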
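# Brain-behavior association models: tract-wise and cluster-wise
# associations of diffusion metrics with language scores (both groups
# plus a group x score interaction) and with ADOS symptom severity
# (ASD only), with Freedman-Lane permutation correction and
# partial-correlation effect sizes.

# Fit score-association models for one family of responses.
# Y: subjects x members matrix (rownames = subject ids); dem must carry
# `score`, `age`, `sex` (+ `group` for the interaction scope).
assoc_family <- function(Y, dem, scope, cfg, labels) {
  if (scope == "interaction") {
    X <- design_matrix(~ group * score + age + sex, dem)
    term <- grep(":", colnames(X), fixed = TRUE, value = TRUE)[1]
  } else {
    X <- design_matrix(~ score + age + sex, dem)
    term <- "score"
  }
  pf <- perm_t_family(X, Y, term, cfg)
  p_cor <- maxstat_correct(pf$observed, pf$nulls)
  covar <- X[, setdiff(colnames(X), c("(Intercept)", term)),
             drop = FALSE]
  out <- lapply(seq_len(ncol(Y)), function(j) {
    fit <- ols_fit(X, Y[, j])
    row <- fit$coef[fit$coef$term == term, ]
    cbind(labels[j, , drop = FALSE], data.frame(
      group_scope = scope, beta = row$beta, se = row$se, t = row$t,
      df = row$df, p_param = row$p_param,
      p_perm = perm_pvalue(pf$observed[j], pf$nulls[, j]),
      p_corrected = p_cor[j],
      partial_r2 = partial_r2(X[, term], Y[, j], covar),
      stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}

scope_subjects <- function(demographics, score, scope, ids) {
  dem <- demographics[demographics$id %in% ids, , drop = FALSE]
  dem <- dem[!is.na(dem[[score]]), , drop = FALSE]
  if (scope %in% c("TD", "ASD"))
    dem <- dem[dem$group == scope, , drop = FALSE]
  dem$score <- dem[[score]]
  dem
}

#' Metric-behavior association
#'
#' Associates a behavior score with diffusion metrics at the tract level
#' (mean over the node grid) or at the cluster level (mean over a node
#' interval, typically the intervals surviving the point-wise group
#' comparison). Within-group scopes fit metric ~ score + age + sex and
#' test the score slope; the interaction scope fits
#' metric ~ group * score + age + sex and tests the product term.
#' Freedman-Lane permutation p values are corrected by max statistic
#' over the family: the tracts within each (metric, scope) at tract
#' level, or the supplied clusters within each (metric, scope) at
#' cluster level. Cluster-level results are selection-dependent when the
#' intervals were chosen by a group contrast on the same sample.
#'
#' @param ds A `tract_profiles` dataset.
#' @param demographics Demographics with the score column.
#' @param score Behavior column name (e.g. `"gds_language"`).
#' @param scopes Subset of `c("TD", "ASD", "interaction")`.
#' @param level `"tract"` or `"cluster"`.
#' @param clusters Data frame with `tractID`, `metric`, `node_start`,
#'   `node_end` (required at cluster level; typically
#'   `pointwise_compare(...)$clusters`).
#' @param cfg A [perm_config()].
#' @param metrics Metrics to test.
#' @return Data frame with one row per scope x family member: `level`,
#'   `tractID`, `metric`, `node_start`/`node_end` (cluster level),
#'   `group_scope`, `beta`, `se`, `t`, `df`, `p_param`, `p_perm`,
#'   `p_corrected`, `partial_r2`.
#' @export
behavior_assoc <- function(ds, demographics, score = "gds_language",
                           scopes = c("TD", "ASD", "interaction"),
                           level = c("tract", "cluster"),
                           clusters = NULL, cfg = perm_config(),
                           metrics = attr(ds, "metrics")) {
  level <- match.arg(level)
  if (!score %in% names(demographics))
    stop("score column not in demographics: ", score)
  if (level == "cluster") {
    if (is.null(clusters) || nrow(clusters) == 0) {
      warning("no clusters supplied; nothing to test at cluster level")
      return(invisible(NULL))
    }
    clusters <- clusters[clusters$metric %in% metrics, , drop = FALSE]
  }
  subj_ids <- attr(ds, "subjects")
  out <- list()
  for (scope in scopes) {
    dem <- scope_subjects(demographics, score, scope, subj_ids)
    if (nrow(dem) < 5) {
      warning("scope ", scope, ": fewer than 5 usable subjects; skipped")
      next
    }
    if (level == "tract") {
      tm <- tract_means(ds, metrics)
      for (met in metrics) {
        tracts <- unique(tm$tractID)
        Y <- sapply(tracts, function(tr) {
          v <- tm[tm$tractID == tr & tm$metric == met, ]
          v$value[match(dem$id, v$subjectID)]
        })
        Y <- matrix(Y, nrow = nrow(dem),
                    dimnames = list(dem$id, tracts))
        labels <- data.frame(level = "tract", tractID = tracts,
                             metric = met, node_start = NA_real_,
                             node_end = NA_real_,
                             score_name = score,
                             stringsAsFactors = FALSE)
        out[[length(out) + 1]] <- assoc_family(Y, dem, scope, cfg,
                                               labels)
      }
    } else {
      for (met in unique(clusters$metric)) {
        cl <- clusters[clusters$metric == met, , drop = FALSE]
        Y <- sapply(seq_len(nrow(cl)), function(i) {
          sm <- segment_means(ds, cl$tractID[i], met,
                              cl$node_start[i], cl$node_end[i])
          sm[dem$id]
        })
        Y <- matrix(Y, nrow = nrow(dem),
                    dimnames = list(dem$id, NULL))
        labels <- data.frame(level = "cluster", tractID = cl$tractID,
                             metric = met,
                             node_start = cl$node_start,
                             node_end = cl$node_end,
                             score_name = score,
                             stringsAsFactors = FALSE)
        out[[length(out) + 1]] <- assoc_family(Y, dem, scope, cfg,
                                               labels)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Metric-severity association (ASD group)
#'
#' Associates ADOS total scores with diffusion metrics within the ASD
#' group, metric ~ ADOS total + age + sex, at tract level and (when
#' clusters are supplied) at cluster level, with the same permutation
#' machinery as [behavior_assoc()].
#'
#' @inheritParams behavior_assoc
#' @return Data frame as in [behavior_assoc()], scope `"ASD"`, score
#'   `"ados_total"`.
#' @export
severity_assoc <- function(ds, demographics, clusters = NULL,
                           cfg = perm_config(),
                           metrics = attr(ds, "metrics")) {
  if (!"ados_total" %in% names(demographics))
    stop("demographics lack ados_total")
  dem <- demographics[demographics$group == "ASD" &
                      !is.na(demographics$ados_total), , drop = FALSE]
  if (nrow(dem) < 5)
    stop("fewer than 5 ASD subjects with ADOS totals")
  if (stats::sd(dem$ados_total) == 0)
    stop("degenerate design: ADOS total constant across subjects")
  res <- behavior_assoc(ds, demographics, score = "ados_total",
                        scopes = "ASD", level = "tract", cfg = cfg,
                        metrics = metrics)
  if (!is.null(clusters) && nrow(clusters) > 0) {
    res_cl <- behavior_assoc(ds, demographics, score = "ados_total",
                             scopes = "ASD", level = "cluster",
                             clusters = clusters, cfg = cfg,
                             metrics = metrics)
    res <- rbind(res, res_cl)
  }
  rownames(res) <- NULL
  res
}
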
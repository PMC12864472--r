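# Lateralization-index pipeline: per-subject LI per tract pair and
# metric, one-sample tests per group with sign-flip permutation
# correction, between-group LI comparison, and LI-behavior association
# with a group interaction.

#' Lateralization index
#'
#' LI = (R - L) / (R + L): positive values mean the right-hemisphere
#' value exceeds the left. For positive inputs the LI lies in (-1, 1);
#' swapping the hemispheres flips its sign.
#'
#' @param left,right Hemispheric values (tract means), with
#'   `left + right > 0`.
#' @return Numeric LI, same length as the inputs.
#' @export
compute_li <- function(left, right) {
  if (any(left + right <= 0, na.rm = TRUE))
    stop("undefined LI: left + right must be positive")
  (right - left) / (right + left)
}

#' Per-subject lateralization-index table
#'
#' Computes the LI on tract-wise means: for each subject, tract pair and
#' metric, the metric is first averaged over the node grid within each
#' hemisphere, then LI = (R - L)/(R + L) of the two means. Subjects
#' missing one hemisphere of a pair are excluded from that pair with a
#' warning.
#'
#' @param ds A `tract_profiles` dataset whose tracts follow the
#'   `L_<pair>` / `R_<pair>` naming convention.
#' @param metrics Metrics to include (default: all in the dataset).
#' @param pairs Tract pairs (default [tract_pairs()]).
#' @return Data frame with columns `subjectID`, `tract_pair`, `metric`,
#'   `li`.
#' @export
li_table <- function(ds, metrics = attr(ds, "metrics"),
                     pairs = tract_pairs()) {
  tm <- tract_means(ds, metrics)
  out <- list()
  for (pr in pairs) {
    lt <- paste0("L_", pr); rt <- paste0("R_", pr)
    for (m in metrics) {
      lv <- tm[tm$tractID == lt & tm$metric == m, ]
      rv <- tm[tm$tractID == rt & tm$metric == m, ]
      common <- intersect(lv$subjectID, rv$subjectID)
      dropped <- setdiff(union(lv$subjectID, rv$subjectID), common)
      if (length(dropped) > 0)
        warning("pair ", pr, " (", m, "): excluding subject(s) with one ",
                "hemisphere missing: ", paste(dropped, collapse = ", "))
      if (length(common) == 0) next
      li <- compute_li(lv$value[match(common, lv$subjectID)],
                       rv$value[match(common, rv$subjectID)])
      out[[length(out) + 1]] <- data.frame(
        subjectID = common, tract_pair = pr, metric = m, li = li,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# subjects x pairs LI matrix for one metric, rows ordered as `ids`
li_matrix <- function(li_tab, metric, ids,
                      pairs = unique(li_tab$tract_pair)) {
  sub <- li_tab[li_tab$metric == metric, ]
  m <- sapply(pairs, function(pr) {
    v <- sub[sub$tract_pair == pr, ]
    v$li[match(ids, v$subjectID)]
  })
  m <- matrix(m, nrow = length(ids), dimnames = list(ids, pairs))
  m
}

li_direction <- function(metric, t, significant) {
  if (!significant) return("none")
  # positive LI = larger value on the right; for diffusivities a larger
  # value means greater diffusivity, so lateralized *integrity* reverses
  if (metric == "FA") {
    if (t > 0) "rightward" else "leftward"
  } else {
    if (t < 0) "rightward" else "leftward"
  }
}

#' One-sample LI tests per group
#'
#' For each group, tract pair and metric, tests whether the mean LI
#' differs from zero (t = mean/(SD/sqrt(n)), df = n - 1). The
#' permutation null is built by random sign flips of the subject LIs
#' (exchangeable under a null symmetric about zero), shared across the
#' correction family; corrected p comes from max-statistic correction
#' over the tract pairs within each (group, metric) family.
#'
#' @param li_tab Output of [li_table()].
#' @param demographics Demographics data frame (`id`, `group`).
#' @param cfg A [perm_config()].
#' @param alpha Significance level for the direction label.
#' @return Data frame: `group`, `tract_pair`, `metric`, `mean_li`,
#'   `sd_li`, `n`, `t`, `df`, `p_raw`, `p_corrected`, `direction`.
#' @export
li_one_sample <- function(li_tab, demographics, cfg = perm_config(),
                          alpha = 0.05) {
  out <- list()
  metrics <- unique(li_tab$metric)
  pairs <- unique(li_tab$tract_pair)
  for (g in levels(demographics$group)) {
    ids <- demographics$id[demographics$group == g]
    ids <- intersect(ids, unique(li_tab$subjectID))
    if (length(ids) < 2) stop("group ", g, " has fewer than 2 subjects")
    for (met in metrics) {
      Y <- li_matrix(li_tab, met, ids, pairs)
      if (any(apply(Y, 2, stats::sd) == 0))
        stop("degenerate sample: zero LI variance in group ", g,
             ", metric ", met)
      sf <- signflip_t_family(Y, cfg)
      p_raw <- vapply(seq_along(sf$observed), function(j)
        perm_pvalue(sf$observed[j], sf$nulls[, j]), 0)
      p_cor <- maxstat_correct(sf$observed, sf$nulls)
      for (j in seq_along(pairs)) {
        out[[length(out) + 1]] <- data.frame(
          group = g, tract_pair = pairs[j], metric = met,
          mean_li = mean(Y[, j]), sd_li = stats::sd(Y[, j]),
          n = nrow(Y), t = sf$observed[j], df = nrow(Y) - 1,
          p_raw = p_raw[j], p_corrected = p_cor[j],
          direction = li_direction(met, sf$observed[j],
                                   p_cor[j] < alpha),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Merge LI matrix rows with demographics, complete cases only.
li_design_data <- function(li_tab, demographics) {
  ids <- intersect(demographics$id, unique(li_tab$subjectID))
  demographics[match(ids, demographics$id), , drop = FALSE]
}

#' Between-group LI comparison
#'
#' Fits LI ~ group + age + sex per tract pair and metric and tests the
#' group term, with Freedman-Lane permutation p corrected over the tract
#' pairs within each metric (max-statistic).
#'
#' @inheritParams li_one_sample
#' @return Data frame: `tract_pair`, `metric`, `beta`, `se`, `t`, `df`,
#'   `p_param`, `p_perm`, `p_corrected`.
#' @export
li_group_compare <- function(li_tab, demographics, cfg = perm_config()) {
  dem <- li_design_data(li_tab, demographics)
  if (length(unique(dem$group)) < 2)
    stop("both groups must be present")
  X <- design_matrix(~ group + age + sex, dem)
  run_family_models(li_tab, dem, X, term = "groupASD", cfg,
                    scope = NULL)
}

# Shared driver: for each metric, build the subjects x pairs LI matrix,
# fit the model per pair with the family-shared permutation stream, and
# assemble a tidy table.
run_family_models <- function(li_tab, dem, X, term, cfg, scope,
                              score = NULL) {
  out <- list()
  metrics <- unique(li_tab$metric)
  pairs <- unique(li_tab$tract_pair)
  for (met in metrics) {
    Y <- li_matrix(li_tab, met, dem$id, pairs)
    pf <- perm_t_family(X, Y, term, cfg)
    p_cor <- maxstat_correct(pf$observed, pf$nulls)
    for (j in seq_along(pairs)) {
      fit <- ols_fit(X, Y[, j])
      row <- fit$coef[fit$coef$term == term, ]
      pr2 <- if (!is.null(score)) {
        covar <- X[, setdiff(colnames(X), c("(Intercept)", term)),
                   drop = FALSE]
        partial_r2(X[, term], Y[, j], covar)
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        scope = if (is.null(scope)) NA_character_ else scope,
        tract_pair = pairs[j], metric = met,
        beta = row$beta, se = row$se, t = row$t, df = row$df,
        p_param = row$p_param,
        p_perm = perm_pvalue(pf$observed[j], pf$nulls[, j]),
        p_corrected = p_cor[j], partial_r2 = pr2,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LI-behavior association with group interaction
#'
#' Within each group fits LI ~ score + age + sex per tract pair and
#' metric and tests the score slope; across groups fits
#' LI ~ group * score + age + sex and tests the group x score
#' interaction. Permutation p (Freedman-Lane) is corrected over the
#' tract pairs within each (scope, metric) family, and the
#' partial correlation R^2 of LI with the score (controlling for age and
#' sex) is attached.
#'
#' @inheritParams li_one_sample
#' @param score Name of the behavior column in `demographics`
#'   (e.g. `"gds_language"`).
#' @return Data frame with one row per scope (TD, ASD, interaction) x
#'   tract pair x metric.
#' @export
li_behavior <- function(li_tab, demographics, score = "gds_language",
                        cfg = perm_config()) {
  if (!score %in% names(demographics))
    stop("score column not in demographics: ", score)
  out <- list()
  for (g in levels(demographics$group)) {
    dem <- li_design_data(li_tab, demographics)
    dem <- dem[dem$group == g & !is.na(dem[[g_score_col(dem, score)]]), ]
    if (nrow(dem) == 0) {
      warning("score ", score, " missing for group ", g, "; skipped")
      next
    }
    dem$score <- dem[[score]]
    X <- design_matrix(~ score + age + sex, dem)
    out[[length(out) + 1]] <-
      run_family_models(li_tab, dem, X, "score", cfg, scope = g,
                        score = score)
  }
  dem <- li_design_data(li_tab, demographics)
  dem <- dem[!is.na(dem[[score]]), ]
  dem$score <- dem[[score]]
  X <- design_matrix(~ group * score + age + sex, dem)
  out[[length(out) + 1]] <-
    run_family_models(li_tab, dem, X, "groupASD:score", cfg,
                      scope = "interaction", score = score)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

g_score_col <- function(dem, score) {
  if (!score %in% names(dem)) stop("score column missing: ", score)
  score
}
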
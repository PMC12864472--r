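# Tract-wise and point-wise group comparisons of diffusion metrics with
# covariate adjustment, permutation family-wise correction, and the
# consecutive-node cluster-extent criterion.

#' Maximal runs of significant consecutive nodes
#'
#' Returns the maximal runs of `TRUE` of length at least `min_len`, in
#' node order. The default `min_len = 4` encodes the criterion that a
#' point-wise effect must span more than three consecutive nodes.
#'
#' @param mask Logical vector over the node grid.
#' @param min_len Minimum run length to report (default 4).
#' @param labels Optional node labels (defaults to 0-based positions,
#'   the pyAFQ convention); cluster bounds are reported in these labels,
#'   inclusive at both ends.
#' @return Data frame with columns `node_start`, `node_end`, `length`
#'   (zero rows when no run qualifies).
#' @export
find_clusters <- function(mask, min_len = 4, labels = NULL) {
  stopifnot(is.logical(mask), min_len >= 1)
  if (is.null(labels)) labels <- seq_along(mask) - 1L
  stopifnot(length(labels) == length(mask))
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(node_start = labels[starts[keep]],
                    node_end = labels[ends[keep]],
                    length = r$lengths[keep])
  rownames(out) <- NULL
  out
}

# Design + response assembly shared by the two comparison levels.
group_design <- function(demographics) {
  if (length(unique(demographics$group)) < 2)
    stop("both groups must be present")
  design_matrix(~ group + age + sex, demographics)
}

#' Tract-wise group comparison
#'
#' For each tract and metric, the metric is averaged over the node grid
#' per subject and modeled as mean ~ group + age + sex; the group term is
#' tested with Freedman-Lane permutation and corrected over the tracts
#' within each metric by the max statistic.
#'
#' @param ds A `tract_profiles` dataset.
#' @param demographics Demographics data frame sharing subject ids with
#'   `ds`.
#' @param cfg A [perm_config()].
#' @param metrics Metrics to test (default: all in the dataset).
#' @return Data frame: `tractID`, `metric`, `beta` (group coefficient,
#'   ASD minus TD in metric units), `se`, `t`, `df`, `p_param`,
#'   `p_perm`, `p_corrected`.
#' @export
tractwise_compare <- function(ds, demographics, cfg = perm_config(),
                              metrics = attr(ds, "metrics")) {
  tm <- tract_means(ds, metrics)
  ids <- intersect(demographics$id, unique(tm$subjectID))
  dem <- demographics[match(ids, demographics$id), , drop = FALSE]
  if (any(table(dem$group) < 2))
    stop("need at least 2 subjects per group")
  X <- group_design(dem)
  tracts <- unique(tm$tractID)
  out <- list()
  for (met in metrics) {
    Y <- sapply(tracts, function(tr) {
      v <- tm[tm$tractID == tr & tm$metric == met, ]
      v$value[match(ids, v$subjectID)]
    })
    Y <- matrix(Y, nrow = length(ids), dimnames = list(ids, tracts))
    pf <- perm_t_family(X, Y, "groupASD", cfg)
    p_cor <- maxstat_correct(pf$observed, pf$nulls)
    for (j in seq_along(tracts)) {
      fit <- ols_fit(X, Y[, j])
      row <- fit$coef[fit$coef$term == "groupASD", ]
      out[[length(out) + 1]] <- data.frame(
        tractID = tracts[j], metric = met, beta = row$beta,
        se = row$se, t = row$t, df = row$df, p_param = row$p_param,
        p_perm = perm_pvalue(pf$observed[j], pf$nulls[, j]),
        p_corrected = p_cor[j], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Point-wise group comparison with cluster detection
#'
#' For each tract and metric, fits metric ~ group + age + sex at every
#' node, corrects the node p values over the 100-node family by
#' max-statistic permutation (Freedman-Lane, one shared permutation
#' stream per tract x metric family), and reports maximal runs of at
#' least `min_cluster` consecutive corrected-significant nodes. No
#' additional correction is applied beyond the node-level one.
#'
#' @inheritParams tractwise_compare
#' @param alpha Node-level significance threshold on corrected p.
#' @param min_cluster Minimum consecutive-node run (default 4,
#'   i.e. more than three nodes).
#' @param tracts Tracts to test (default: all in the dataset).
#' @return List with `nodes` (data frame: `tractID`, `metric`, `node`,
#'   `beta`, `t`, `p_raw`, `p_corrected`, `in_cluster`) and `clusters`
#'   (data frame: `tractID`, `metric`, `node_start`, `node_end`,
#'   `length`).
#' @export
pointwise_compare <- function(ds, demographics, cfg = perm_config(),
                              metrics = attr(ds, "metrics"),
                              tracts = attr(ds, "tracts"),
                              alpha = 0.05, min_cluster = 4) {
  nodes <- attr(ds, "nodes")
  node_rows <- list(); clus_rows <- list()
  for (tr in tracts) {
    for (met in metrics) {
      Y <- node_matrix(ds, tr, met)
      ids <- rownames(Y)[stats::complete.cases(Y)]
      Y <- Y[ids, , drop = FALSE]
      dem <- demographics[match(intersect(demographics$id, ids),
                                demographics$id), , drop = FALSE]
      Y <- Y[dem$id, , drop = FALSE]
      if (any(table(dem$group) < 2))
        stop("need at least 2 subjects per group")
      X <- group_design(dem)
      pf <- perm_t_family(X, Y, "groupASD", cfg)
      p_raw <- vapply(seq_along(pf$observed), function(j)
        perm_pvalue(pf$observed[j], pf$nulls[, j]), 0)
      p_cor <- maxstat_correct(pf$observed, pf$nulls)
      # betas for reporting
      fit_all <- stats::lm.fit(X, Y)
      beta_g <- fit_all$coefficients["groupASD", ]
      cl <- find_clusters(p_cor < alpha, min_len = min_cluster,
                          labels = nodes)
      in_cl <- rep(FALSE, length(nodes))
      if (nrow(cl) > 0) {
        for (i in seq_len(nrow(cl)))
          in_cl[nodes >= cl$node_start[i] & nodes <= cl$node_end[i]] <-
            TRUE
        clus_rows[[length(clus_rows) + 1]] <-
          cbind(data.frame(tractID = tr, metric = met,
                           stringsAsFactors = FALSE), cl)
      }
      node_rows[[length(node_rows) + 1]] <- data.frame(
        tractID = tr, metric = met, node = nodes,
        beta = as.numeric(beta_g), t = pf$observed, p_raw = p_raw,
        p_corrected = p_cor, in_cluster = in_cl,
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clus_rows) > 0) {
    do.call(rbind, clus_rows)
  } else {
    data.frame(tractID = character(), metric = character(),
               node_start = numeric(), node_end = numeric(),
               length = integer(), stringsAsFactors = FALSE)
  }
  rownames(clusters) <- NULL
  nodes_df <- do.call(rbind, node_rows)
  rownames(nodes_df) <- NULL
  list(nodes = nodes_df, clusters = clusters)
}

#' Group mean and SD per node (plot-ready export)
#'
#' @inheritParams pointwise_compare
#' @return Data frame: `tractID`, `metric`, `node`, `group`, `mean`,
#'   `sd`, the data behind along-tract curve plots.
#' @export
node_group_summary <- function(ds, demographics,
                               metrics = attr(ds, "metrics"),
                               tracts = attr(ds, "tracts")) {
  out <- list()
  for (tr in tracts) {
    for (met in metrics) {
      Y <- node_matrix(ds, tr, met)
      for (g in levels(demographics$group)) {
        ids <- intersect(demographics$id[demographics$group == g],
                         rownames(Y))
        sub <- Y[ids, , drop = FALSE]
        out[[length(out) + 1]] <- data.frame(
          tractID = tr, metric = met,
          node = as.numeric(colnames(Y)), group = g,
          mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
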
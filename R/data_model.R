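#' Diffusion metric names
#'
#' The four tensor-derived scalar metrics carried by a tract-profile
#' dataset, with their display semantics: for FA a larger value means
#' greater anisotropy; for MD, RD and AD a larger value means greater
#' diffusivity.
#'
#' @return Character vector `c("FA", "MD", "RD", "AD")`.
#' @export
metric_names <- function() c("FA", "MD", "RD", "AD")

#' Does a larger metric value mean greater diffusivity?
#'
#' FA is an anisotropy measure; MD, RD and AD are diffusivities. The
#' distinction drives the direction labels of lateralization results:
#' a significantly positive lateralization index means rightward
#' lateralization for FA but leftward for the diffusivity metrics.
#'
#' @param metric One of `metric_names()`.
#' @return Logical scalar.
#' @export
is_diffusivity <- function(metric) {
  metric <- match.arg(metric, metric_names())
  metric != "FA"
}

#' Default tract set: left/right arcuate, inferior fronto-occipital,
#' inferior longitudinal and superior longitudinal fasciculi.
#'
#' @return Character vector of 8 tract identifiers, `L_`/`R_` prefixed.
#' @export
default_tracts <- function() {
  as.vector(outer(c("L", "R"), c("AF", "IFOF", "ILF", "SLF"),
                  function(h, t) paste(h, t, sep = "_")))
}

#' Bilateral tract pairs
#'
#' @return Character vector `c("AF", "IFOF", "ILF", "SLF")`.
#' @export
tract_pairs <- function() c("AF", "IFOF", "ILF", "SLF")

#' Column-name schema for AFQ profile files
#'
#' Maps the canonical internal names onto the column names found in the
#' file. Defaults follow the pyAFQ long-format profile export.
#'
#' @param subject,tract,node Column names for the identifiers.
#' @param metrics Named character vector mapping metric names
#'   (`FA`, `MD`, `RD`, `AD`) to file columns; metrics absent from the
#'   file may be dropped from this map.
#' @return A list with class `afq_schema`.
#' @export
afq_schema <- function(subject = "subjectID", tract = "tractID",
                       node = "nodeID",
                       metrics = c(FA = "dti_fa", MD = "dti_md",
                                   RD = "dti_rd", AD = "dti_ad")) {
  stopifnot(length(metrics) >= 1, !is.null(names(metrics)))
  bad <- setdiff(names(metrics), metric_names())
  if (length(bad) > 0)
    stop("unknown metric(s) in schema: ", paste(bad, collapse = ", "))
  structure(list(subject = subject, tract = tract, node = node,
                 metrics = metrics), class = "afq_schema")
}

#' Construct a tract-profile dataset
#'
#' The canonical container for along-tract diffusion metrics: one row per
#' subject x tract x node, one column per metric. Construction validates
#' the profile invariants: every (subject, tract) present carries the full
#' node grid, FA lies in [0, 1], diffusivities are strictly positive, and
#' RD <= AD wherever both are present.
#'
#' @param data Data frame with columns `subjectID`, `tractID`, `nodeID`
#'   and one column per metric (a subset of `metric_names()`).
#' @param metrics Metric columns to keep; defaults to whichever of the
#'   four canonical metrics are present.
#' @return An object of class `tract_profiles`: the data frame plus
#'   attributes `subjects`, `tracts`, `nodes`, `metrics` (all in first
#'   appearance order).
#' @export
tract_profiles <- function(data, metrics = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("subjectID", "tractID", "nodeID")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("profile data lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(metrics)) metrics <- intersect(metric_names(), names(data))
  if (length(metrics) == 0)
    stop("profile data contains no metric columns")
  data <- as.data.frame(data)[, c(need, metrics)]
  data$subjectID <- as.character(data$subjectID)
  data$tractID <- as.character(data$tractID)
  ds <- structure(data,
                  subjects = unique(data$subjectID),
                  tracts = unique(data$tractID),
                  nodes = sort(unique(data$nodeID)),
                  metrics = metrics,
                  class = c("tract_profiles", "data.frame"))
  validate_profiles(ds)
  ds
}

#' Validate a tract-profile dataset
#'
#' Checks the container invariants and fails with a specific, located
#' error message: a ragged node grid names the offending
#' (subject, tract); an out-of-range FA or non-positive diffusivity names
#' the cell; RD > AD names the cell.
#'
#' @param ds A `tract_profiles` object.
#' @return `ds`, invisibly, if valid.
#' @export
validate_profiles <- function(ds) {
  nodes <- attr(ds, "nodes")
  key <- paste(ds$subjectID, ds$tractID, sep = "\r")
  counts <- table(key)
  bad <- names(counts)[counts != length(nodes)]
  if (length(bad) > 0) {
    pairs <- vapply(strsplit(bad, "\r", fixed = TRUE),
                    function(x) sprintf("(%s, %s)", x[1], x[2]), "")
    stop("ragged node grid: profile(s) without the full ",
         length(nodes), "-node grid: ", paste(pairs, collapse = "; "))
  }
  loc <- function(i) sprintf("(subject %s, tract %s, node %s)",
                             ds$subjectID[i], ds$tractID[i], ds$nodeID[i])
  mets <- attr(ds, "metrics")
  if ("FA" %in% mets) {
    i <- which(!is.na(ds$FA) & (ds$FA < 0 | ds$FA > 1))
    if (length(i) > 0)
      stop("FA outside [0, 1] at ", loc(i[1]),
           sprintf(": %.4g", ds$FA[i[1]]))
  }
  for (m in intersect(c("MD", "RD", "AD"), mets)) {
    v <- ds[[m]]
    i <- which(!is.na(v) & v <= 0)
    if (length(i) > 0)
      stop(m, " not strictly positive at ", loc(i[1]),
           sprintf(": %.4g", v[i[1]]))
  }
  if (all(c("RD", "AD") %in% mets)) {
    ok <- is.na(ds$RD) | is.na(ds$AD) | ds$RD <= ds$AD * (1 + 1e-12)
    i <- which(!ok)
    if (length(i) > 0)
      stop("RD exceeds AD at ", loc(i[1]))
  }
  invisible(ds)
}

#' Read an AFQ-format tract-profile file
#'
#' Reads a delimited long-format profile table (one row per subject x
#' tract x node), remaps columns through the schema, and validates the
#' result. Node ordering is preserved exactly as in the file.
#'
#' @param path Path to a delimited text file with a header.
#' @param schema An [afq_schema()] describing the file's column names.
#' @param sep Field separator (default comma).
#' @return A [tract_profiles()] dataset.
#' @export
read_profiles <- function(path, schema = afq_schema(), sep = ",") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  want <- c(schema$subject, schema$tract, schema$node,
            unname(schema$metrics))
  miss <- setdiff(want, names(raw))
  if (length(miss) > 0)
    stop("profile file lacks required column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(subjectID = raw[[schema$subject]],
                    tractID = raw[[schema$tract]],
                    nodeID = raw[[schema$node]],
                    stringsAsFactors = FALSE)
  for (m in names(schema$metrics)) out[[m]] <- raw[[schema$metrics[[m]]]]
  tract_profiles(out)
}

#' Write a tract-profile dataset
#'
#' Inverse of [read_profiles()]: writes the dataset in the schema's
#' column names, preserving row order, so that a read/write round trip
#' reproduces every cell.
#'
#' @param ds A `tract_profiles` dataset.
#' @param path Output path.
#' @param schema Column-name schema to write under.
#' @param sep Field separator.
#' @export
write_profiles <- function(ds, path, schema = afq_schema(), sep = ",") {
  mets <- intersect(names(schema$metrics), attr(ds, "metrics"))
  out <- data.frame(ds$subjectID, ds$tractID, ds$nodeID,
                    stringsAsFactors = FALSE)
  names(out) <- c(schema$subject, schema$tract, schema$node)
  for (m in mets) out[[schema$metrics[[m]]]] <- ds[[m]]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a demographics/behavior table
#'
#' One row per subject with diagnostic group (TD/ASD), age, sex, the ABC
#' total, GDS developmental-quotient domains, and (for the ASD group)
#' ADOS scores. Group and sex are parsed case-insensitively. ADOS scores
#' present for a TD subject are a validation error; where SA, RRB and
#' total are all present, total must equal SA + RRB.
#'
#' @param path Delimited text file with a header; columns `id`, `group`,
#'   `age`, `sex`, and optionally `abc`, `gds_*`, `ados_*`.
#' @param sep Field separator.
#' @return Data frame of subject records, `group` and `sex` as factors
#'   with levels `TD`/`ASD` and `M`/`F`.
#' @export
read_demographics <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("demographics file is empty")
    return(raw)
  }
  validate_demographics(raw)
}

#' Validate a demographics table
#'
#' @param df Data frame with at least `id`, `group`, `age`, `sex`.
#' @return The validated data frame with normalized factor columns.
#' @export
validate_demographics <- function(df) {
  need <- c("id", "group", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("demographics lack required column(s): ",
         paste(miss, collapse = ", "))
  grp <- toupper(trimws(as.character(df$group)))
  bad <- setdiff(unique(grp), c("TD", "ASD"))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  sx <- toupper(substr(trimws(as.character(df$sex)), 1, 1))
  badsx <- setdiff(unique(sx), c("M", "F"))
  if (length(badsx) > 0)
    stop("unknown sex label(s): ", paste(badsx, collapse = ", "))
  df$id <- as.character(df$id)
  df$group <- factor(grp, levels = c("TD", "ASD"))
  df$sex <- factor(sx, levels = c("M", "F"))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("age must be positive and finite for every subject")
  ados_cols <- intersect(c("ados_sa", "ados_rrb", "ados_total"), names(df))
  if (length(ados_cols) > 0) {
    has_ados <- rowSums(!is.na(df[, ados_cols, drop = FALSE])) > 0
    offend <- which(has_ados & df$group == "TD")
    if (length(offend) > 0)
      stop("ADOS scores present for TD subject(s): ",
           paste(df$id[offend], collapse = ", "))
  }
  if (all(c("ados_sa", "ados_rrb", "ados_total") %in% names(df))) {
    full <- stats::complete.cases(df[, c("ados_sa", "ados_rrb",
                                         "ados_total")])
    off <- which(full &
                 abs(df$ados_total - (df$ados_sa + df$ados_rrb)) > 1e-8)
    if (length(off) > 0)
      stop("ADOS total != SA + RRB for subject(s): ",
           paste(df$id[off], collapse = ", "))
  }
  df
}

#' Mean of a metric over all nodes of one profile
#'
#' The tract-wise summary used throughout: the arithmetic mean of the
#' metric across the full node grid of one (subject, tract) profile.
#'
#' @param ds A `tract_profiles` dataset.
#' @param subject,tract Identifiers of the profile.
#' @param metric One of the dataset's metrics.
#' @return Numeric scalar.
#' @export
tract_mean <- function(ds, subject, tract, metric) {
  metric <- match.arg(metric, attr(ds, "metrics"))
  sel <- ds$subjectID == subject & ds$tractID == tract
  if (!any(sel))
    stop("no profile for (subject ", subject, ", tract ", tract, ")")
  mean(ds[[metric]][sel])
}

#' Mean of a metric over an inclusive node interval
#'
#' The cluster-wise summary: the mean over the nodes from `node_start` to
#' `node_end` inclusive, in input node labels. Over the full grid it
#' equals [tract_mean()].
#'
#' @inheritParams tract_mean
#' @param node_start,node_end Inclusive interval bounds, both on the
#'   node grid.
#' @return Numeric scalar.
#' @export
segment_mean <- function(ds, subject, tract, metric, node_start, node_end) {
  metric <- match.arg(metric, attr(ds, "metrics"))
  nodes <- attr(ds, "nodes")
  if (node_start > node_end)
    stop("node_start must not exceed node_end")
  if (!(node_start %in% nodes) || !(node_end %in% nodes))
    stop("node interval [", node_start, ", ", node_end,
         "] is off the node grid")
  sel <- ds$subjectID == subject & ds$tractID == tract &
    ds$nodeID >= node_start & ds$nodeID <= node_end
  if (!any(sel))
    stop("no profile for (subject ", subject, ", tract ", tract, ")")
  mean(ds[[metric]][sel])
}

#' Tract-wise means for all subjects and tracts
#'
#' @param ds A `tract_profiles` dataset.
#' @param metrics Metrics to summarize (default: all in the dataset).
#' @return Long data frame with columns `subjectID`, `tractID`, `metric`,
#'   `value` (the mean over the node grid), ordered by subject then tract.
#' @export
tract_means <- function(ds, metrics = attr(ds, "metrics")) {
  metrics <- match.arg(metrics, attr(ds, "metrics"), several.ok = TRUE)
  key <- paste(ds$subjectID, ds$tractID, sep = "\r")
  key <- factor(key, levels = unique(key))
  out <- do.call(rbind, lapply(metrics, function(m) {
    mu <- tapply(ds[[m]], key, mean)
    ids <- strsplit(names(mu), "\r", fixed = TRUE)
    data.frame(subjectID = vapply(ids, `[`, "", 1),
               tractID = vapply(ids, `[`, "", 2),
               metric = m, value = as.numeric(mu),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Segment means for all subjects on one tract
#'
#' @inheritParams tract_means
#' @param tract Tract identifier.
#' @param node_start,node_end Inclusive node interval.
#' @param metric Metric name.
#' @return Named numeric vector of per-subject segment means.
#' @export
segment_means <- function(ds, tract, metric, node_start, node_end) {
  metric <- match.arg(metric, attr(ds, "metrics"))
  nodes <- attr(ds, "nodes")
  if (!(node_start %in% nodes) || !(node_end %in% nodes) ||
      node_start > node_end)
    stop("node interval [", node_start, ", ", node_end,
         "] is off the node grid")
  sel <- ds$tractID == tract & ds$nodeID >= node_start &
    ds$nodeID <= node_end
  sub <- ds[sel, ]
  mu <- tapply(sub[[metric]], sub$subjectID, mean)
  out <- as.numeric(mu)
  names(out) <- names(mu)
  out
}

#' Per-node value matrix for one tract and metric
#'
#' @param ds A `tract_profiles` dataset.
#' @param tract Tract identifier.
#' @param metric Metric name.
#' @return Numeric matrix, subjects x nodes; rownames are subject ids,
#'   colnames node labels.
#' @export
node_matrix <- function(ds, tract, metric) {
  metric <- match.arg(metric, attr(ds, "metrics"))
  sel <- ds$tractID == tract
  if (!any(sel)) stop("tract not in dataset: ", tract)
  sub <- ds[sel, ]
  nodes <- attr(ds, "nodes")
  subs <- unique(sub$subjectID)
  m <- matrix(NA_real_, length(subs), length(nodes),
              dimnames = list(subs, as.character(nodes)))
  m[cbind(match(sub$subjectID, subs), match(sub$nodeID, nodes))] <-
    sub[[metric]]
  m
}

#' @export
print.tract_profiles <- function(x, ...) {
  cat(sprintf(
    "tract_profiles: %d subjects x %d tracts x %d nodes; metrics: %s\n",
    length(attr(x, "subjects")), length(attr(x, "tracts")),
    length(attr(x, "nodes")), paste(attr(x, "metrics"), collapse = ", ")))
  invisible(x)
}
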
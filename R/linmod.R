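# Statistical kernel: OLS with coefficient t-tests, classical one/two
# sample tests, Fisher's exact test, partial correlation, and the
# permutation engine (label and Freedman-Lane residual permutation with
# max-statistic family-wise correction).

#' Build a design matrix from a model frame
#'
#' Thin wrapper over [stats::model.matrix()] that enforces the
#' conventions used throughout: an intercept is always present, group is
#' coded TD = 0 / ASD = 1 and sex M = 0 / F = 1 (so a positive group
#' coefficient means ASD > TD).
#'
#' @param formula RHS-only formula, e.g. `~ group + age + sex`.
#' @param data Data frame holding the terms.
#' @return Numeric matrix with named columns; the first is `(Intercept)`.
#' @export
design_matrix <- function(formula, data) {
  X <- stats::model.matrix(formula, data)
  if (!"(Intercept)" %in% colnames(X))
    stop("design must contain an intercept")
  # a covariate constant in the analyzed subset (e.g. a single-sex
  # subgroup) carries no information and would only break the fit
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(v) stats::sd(v) > 0))
  X[, keep, drop = FALSE]
}

#' Ordinary least squares with coefficient t-tests
#'
#' Fits y = X beta + e by least squares and reports, per term, the
#' coefficient, its standard error from the unbiased residual-variance
#' estimator, the t statistic, residual degrees of freedom and the
#' two-sided parametric p value.
#'
#' @param X Numeric design matrix with named columns (intercept included).
#' @param y Response vector, `length(y) == nrow(X)`.
#' @return List with `coef` (data frame: term, beta, se, t, df, p_param),
#'   `sigma2` (residual variance), `residuals`, `fitted`, `df`.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), nrow(X) > ncol(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular design: collinear term(s): ",
         paste(drop, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  beta <- fit$coefficients
  tval <- beta / se
  coef <- data.frame(term = colnames(X), beta = unname(beta),
                     se = unname(se), t = unname(tval), df = df,
                     p_param = 2 * stats::pt(-abs(unname(tval)), df),
                     stringsAsFactors = FALSE)
  list(coef = coef, sigma2 = sigma2, residuals = fit$residuals,
       fitted = fit$fitted.values, df = df)
}

#' One-sample t-test
#'
#' t = mean / (SD / sqrt(n)) with df = n - 1 and a two-sided p value;
#' the test applied per group to the lateralization indices.
#'
#' @param values Numeric vector, n >= 2, nonzero sample SD.
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 observations")
  if (stats::sd(values) == 0)
    stop("degenerate sample: zero standard deviation")
  ht <- stats::t.test(values, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values), sd = stats::sd(values),
       n = length(values))
}

#' One-sample t from summary statistics
#'
#' Recomputes t = mean/(SD/sqrt(n)) from printed summary values, as used
#' to check published lateralization tables.
#'
#' @param mean,sd,n Sample mean, standard deviation and size.
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_t_summary <- function(mean, sd, n) {
  stopifnot(n >= 2, sd > 0)
  t <- mean / (sd / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimator and
#' df = n_a + n_b - 2; the sign convention is mean(a) - mean(b).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t_pooled <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) + stats::var(b) == 0)
    stop("degenerate samples: zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pooled two-sample t from summary statistics
#'
#' @param mean_a,sd_a,n_a Summary statistics of the first sample.
#' @param mean_b,sd_b,n_b Summary statistics of the second sample.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) stop("degenerate samples: zero pooled variance")
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by summing hypergeometric probabilities not larger
#' than that of the observed table (the standard two-sided convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The exact two-sided p value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  stats::fisher.test(tab)$p.value
}

#' Squared partial correlation
#'
#' Squared Pearson correlation of the residuals of `x` and `y` after
#' regressing each on the covariates (with intercept); the effect size
#' reported alongside brain-behavior associations. With no covariates it
#' reduces to the squared ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame of covariate
#'   columns (no intercept needed; one is added).
#' @return Squared partial correlation in [0, 1].
#' @export
partial_r2 <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      NROW(covariates) == 0) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    Z <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    if (qr(Z)$rank < ncol(Z)) stop("singular covariate design")
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  }
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1e-300))
    stop("degenerate residuals: no variance left after adjustment")
  stats::cor(rx, ry)^2
}

#' Permutation configuration
#'
#' @param n_perm Number of permutations (default 5000, the convention in
#'   along-tract permutation studies).
#' @param seed Integer seed; every permutation p value is reproducible
#'   from it.
#' @param scheme `"freedman_lane"` (residual permutation under the
#'   reduced model; the default whenever covariates are present) or
#'   `"label_permutation"` (permute the tested column directly).
#' @return List with class `perm_config`.
#' @export
perm_config <- function(n_perm = 5000, seed = 1,
                        scheme = c("freedman_lane", "label_permutation")) {
  stopifnot(n_perm >= 1)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scheme = match.arg(scheme)), class = "perm_config")
}

# Run code with a private RNG stream, restoring the caller's state.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Permutation p value (add-one estimator)
#'
#' p = (1 + #\{|null| >= |observed|\}) / (B + 1), two-sided on absolute
#' values; guaranteed to lie in (0, 1].
#'
#' @param observed Observed statistic.
#' @param null_stats Vector of statistics under the permutation null.
#' @return Permutation p value.
#' @export
perm_pvalue <- function(observed, null_stats) {
  if (length(null_stats) == 0) stop("empty null distribution")
  (1 + sum(abs(null_stats) >= abs(observed))) /
    (length(null_stats) + 1)
}

# Core engine: null t statistics for one term of a linear model, shared
# across a family of responses (columns of Y) so that max-statistic
# correction is coherent. The same permutation (or sign-flip) vector is
# applied to every column within a draw.
#
# Returns list(observed = t per column, nulls = n_perm x ncol matrix).
perm_t_family <- function(X, Y, term, cfg) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(X))
  if (!term %in% colnames(X)) stop("term not in design: ", term)
  n <- nrow(X); k <- ncol(X); m <- ncol(Y)
  if (qr(X)$rank < k) stop("singular design")
  gi <- match(term, colnames(X))
  XtX_inv <- chol2inv(chol(crossprod(X)))
  H <- XtX_inv %*% t(X)                       # k x n
  cg <- XtX_inv[gi, gi]
  t_of <- function(Ym) {
    B <- H %*% Ym                              # k x m
    R <- Ym - X %*% B
    s2 <- colSums(R^2) / (n - k)
    B[gi, ] / sqrt(s2 * cg)
  }
  observed <- as.numeric(t_of(Y))
  Z <- X[, -gi, drop = FALSE]                  # reduced model
  if (ncol(Z) > 0) {
    fitz <- stats::lm.fit(Z, Y)
    Fz <- as.matrix(fitz$fitted.values)
    Ez <- as.matrix(fitz$residuals)
  } else {
    Fz <- matrix(0, n, m)
    Ez <- Y
  }
  nulls <- matrix(NA_real_, cfg$n_perm, m)
  with_rng(cfg$seed, {
    for (b in seq_len(cfg$n_perm)) {
      pi_b <- sample.int(n)
      if (cfg$scheme == "freedman_lane") {
        nulls[b, ] <- t_of(Fz + Ez[pi_b, , drop = FALSE])
      } else {
        Xp <- X
        Xp[, gi] <- X[pi_b, gi]
        XtX_inv_p <- tryCatch(chol2inv(chol(crossprod(Xp))),
                              error = function(e) NULL)
        if (is.null(XtX_inv_p)) { nulls[b, ] <- 0; next }
        Hp <- XtX_inv_p %*% t(Xp)
        Bp <- Hp %*% Y
        Rp <- Y - Xp %*% Bp
        s2p <- colSums(Rp^2) / (n - k)
        nulls[b, ] <- Bp[gi, ] / sqrt(s2p * XtX_inv_p[gi, gi])
      }
    }
  })
  colnames(nulls) <- colnames(Y)
  list(observed = observed, nulls = nulls)
}

#' Null t distribution for one term by permutation
#'
#' Generates the permutation null distribution of the t statistic for a
#' single term of a linear model. Under `"freedman_lane"` the residuals
#' of the reduced model (the design without the term) are permuted, added
#' back to the reduced-model fit, and the full model refit; under
#' `"label_permutation"` the term's column is permuted directly. Output
#' is fully reproducible from `cfg$seed`.
#'
#' @param X Design matrix with named columns.
#' @param y Response vector.
#' @param term Name of the tested column of `X`.
#' @param cfg A [perm_config()].
#' @return Numeric vector of length `cfg$n_perm` of null t statistics.
#' @export
permute_term <- function(X, y, term, cfg) {
  as.numeric(perm_t_family(X, as.matrix(y), term, cfg)$nulls[, 1])
}

#' Max-statistic family-wise error correction
#'
#' Corrected p for test i is the add-one proportion of permutations whose
#' maximum absolute null statistic over the whole family reaches
#' |observed_i|. Corrected p never falls below the per-test permutation
#' p, and with a family of one it reduces to [perm_pvalue()].
#'
#' @param observed Vector of observed statistics (one per family member).
#' @param nulls Matrix of null statistics, n_perm x family size, from a
#'   shared permutation stream.
#' @return Vector of corrected p values.
#' @export
maxstat_correct <- function(observed, nulls) {
  nulls <- as.matrix(nulls)
  if (ncol(nulls) != length(observed))
    stop("family size mismatch: ", length(observed), " observed vs ",
         ncol(nulls), " null columns")
  maxnull <- apply(abs(nulls), 1, max)
  vapply(observed, function(o) {
    (1 + sum(maxnull >= abs(o))) / (nrow(nulls) + 1)
  }, 0)
}

# Sign-flip engine for one-sample (symmetric-about-zero) nulls, shared
# flips across the columns of Y. Used by the lateralization one-sample
# tests. Returns list(observed, nulls) of t statistics.
signflip_t_family <- function(Y, cfg) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  tstat <- function(Ym) {
    mu <- colMeans(Ym)
    sd <- sqrt(colSums(sweep(Ym, 2, mu)^2) / (n - 1))
    mu / (sd / sqrt(n))
  }
  observed <- tstat(Y)
  nulls <- matrix(NA_real_, cfg$n_perm, ncol(Y))
  with_rng(cfg$seed, {
    for (b in seq_len(cfg$n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      nulls[b, ] <- tstat(Y * s)
    }
  })
  colnames(nulls) <- colnames(Y)
  list(observed = as.numeric(observed), nulls = nulls)
}
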
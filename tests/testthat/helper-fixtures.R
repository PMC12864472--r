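# Fixture builders and independent oracles used across the suite.

# Small well-formed profile table: n_sub subjects x tracts x n_nodes
# nodes, metric values filled from a deterministic function or supplied
# generator.
make_profiles_df <- function(n_sub = 2, tracts = c("L_AF", "R_AF"),
                             n_nodes = 100,
                             fill = function(s, tr, node) {
                               0.4 + 0.001 * node / n_nodes
                             }) {
  subs <- sprintf("s%02d", seq_len(n_sub))
  g <- expand.grid(nodeID = seq_len(n_nodes) - 1L, tractID = tracts,
                   subjectID = subs, stringsAsFactors = FALSE)
  g <- g[, c("subjectID", "tractID", "nodeID")]
  fa <- mapply(fill, g$subjectID, g$tractID, g$nodeID)
  g$FA <- pmin(pmax(fa, 0), 1)
  g$AD <- 1.3e-3 + 1e-5 * (g$nodeID %% 7)
  g$RD <- 0.5 * g$AD
  g$MD <- (g$AD + 2 * g$RD) / 3
  g
}

make_demog <- function(n_td = 10, n_asd = 12, seed = 99) {
  withr::with_seed(seed, {
    n <- n_td + n_asd
    data.frame(
      id = sprintf("s%02d", seq_len(n)),
      group = factor(rep(c("TD", "ASD"), c(n_td, n_asd)),
                     levels = c("TD", "ASD")),
      age = runif(n, 1.5, 6),
      sex = factor(sample(c("M", "F"), n, replace = TRUE,
                          prob = c(0.8, 0.2)), levels = c("M", "F")),
      gds_language = c(rnorm(n_td, 93.5, 4), rnorm(n_asd, 46.8, 11.9)),
      ados_total = c(rep(NA_real_, n_td),
                     round(runif(n_asd, 8, 24))),
      stringsAsFactors = FALSE)
  })
}

# --- independent oracles -------------------------------------------------

# OLS via SVD pseudoinverse: beta, se, t computed from first principles,
# independent of lm/lm.fit.
ols_oracle <- function(X, y) {
  sv <- svd(X)
  pinv <- sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)
  beta <- as.numeric(pinv %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- sv$v %*% diag(1 / sv$d^2, length(sv$d)) %*% t(sv$v)
  se <- sqrt(s2 * diag(XtXinv))
  list(beta = beta, se = se, t = beta / se, df = df)
}

# Two-sided Fisher exact p by direct hypergeometric enumeration over
# all tables with the observed margins.
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  a_range <- max(0, k - n2):min(m, k)
  probs <- dhyper(a_range, m, n2, k)
  p_obs <- dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# First-order partial correlation by the closed-form recursion.
partial_cor_oracle <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- (1:n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
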
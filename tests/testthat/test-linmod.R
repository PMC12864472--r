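test_that("ols_fit matches the pseudoinverse oracle and exact cases", {
  # exact fit: y = 2 x
  x <- 1:10
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- ols_fit(X, 2 * x)
  expect_equal(fit$coef$beta[fit$coef$term == "x"], 2)
  expect_lt(fit$sigma2, 1e-20)
  # intercept-only model reproduces the one-sample t
  set.seed(3)
  y <- rnorm(15, 0.3)
  fit0 <- ols_fit(matrix(1, 15, 1, dimnames = list(NULL, "(Intercept)")),
                  y)
  ot <- one_sample_t(y)
  expect_equal(fit0$coef$beta[1], mean(y))
  expect_equal(fit0$coef$t[1], ot$t, tolerance = 1e-12)
  # random designs vs SVD pseudoinverse oracle
  set.seed(4)
  for (i in 1:20) {
    X <- cbind(1, matrix(rnorm(30 * 3), 30, 3))
    colnames(X) <- c("(Intercept)", "a", "b", "c")
    y <- rnorm(30)
    fit <- ols_fit(X, y)
    or <- ols_oracle(X, y)
    expect_equal(fit$coef$beta, or$beta, tolerance = 1e-10)
    expect_equal(fit$coef$se, or$se, tolerance = 1e-10)
    expect_equal(fit$coef$t, or$t, tolerance = 1e-10)
    expect_equal(fit$coef$df[1], or$df)
  }
  # t = beta/se identity and df bookkeeping under subject removal
  fit_full <- ols_fit(X, y)
  fit_drop <- ols_fit(X[-1, ], y[-1])
  expect_equal(fit_full$coef$t, fit_full$coef$beta / fit_full$coef$se)
  expect_equal(fit_full$coef$df[1] - fit_drop$coef$df[1], 1)
  # collinear design errors with the term named
  Xs <- cbind(X, dup = X[, "a"])
  expect_error(ols_fit(Xs, y), "singular")
})

test_that("classical tests reproduce their definitions", {
  # one-sample: zero-mean symmetric sample
  expect_equal(one_sample_t(c(-1, 1))$t, 0)
  expect_equal(one_sample_t(c(-1, 1))$p, 1)
  expect_error(one_sample_t(rep(0.5, 6)), "degenerate")
  # summary form matches vector form on a realized sample
  set.seed(5)
  v <- rnorm(22, 0.01, 0.02)
  expect_equal(one_sample_t(v)$t,
               one_sample_t_summary(mean(v), sd(v), 22)$t)
  # two-sample pooled: identical samples give t = 0, df = n1 + n2 - 2
  a <- c(1, 2, 3, 4); b <- c(4, 3, 2, 1)
  tt <- two_sample_t_pooled(a, b)
  expect_equal(tt$t, 0)
  expect_equal(tt$df, 6)
  # vector and summary forms agree
  set.seed(6)
  a <- rnorm(12); b <- rnorm(17, 0.5)
  expect_equal(two_sample_t_pooled(a, b)$t,
               two_sample_t_summary(mean(a), sd(a), 12,
                                    mean(b), sd(b), 17)$t,
               tolerance = 1e-12)
  expect_error(two_sample_t_pooled(rep(1, 3), rep(1, 4)), "degenerate")
})

test_that("fisher_exact_2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_2x2(t2), fisher_oracle(t2),
               tolerance = 1e-12)
  t3 <- matrix(c(17, 24, 5, 4), 2)
  expect_equal(fisher_exact_2x2(t3), fisher_oracle(t3),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("partial_r2 reduces to Pearson and matches the recursion", {
  set.seed(7)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40); z <- rnorm(40)
  expect_equal(partial_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
  expect_equal(partial_r2(x, y, cbind(z = z)),
               partial_cor_oracle(x, y, z)^2, tolerance = 1e-12)
  # response that is an exact function of the covariates degenerates
  y_exact <- 2 + 3 * z
  expect_error(partial_r2(x, y_exact, cbind(z = z)), "degenerate")
})

test_that("perm_pvalue implements the two-sided add-one rule", {
  expect_equal(perm_pvalue(10, c(1, -2, 3, -1)), 1 / 5)
  expect_equal(perm_pvalue(0, c(1, -2, 3, -1)), 1)
  expect_equal(perm_pvalue(2.5, c(3, -3, 1, 2)), 3 / 5)
  expect_error(perm_pvalue(1, numeric(0)), "empty")
})

test_that("permute_term is seed-reproducible and leaves the RNG alone", {
  set.seed(8)
  X <- cbind(`(Intercept)` = 1, g = rep(0:1, each = 10),
             age = runif(20, 2, 6))
  y <- rnorm(20)
  cfg <- perm_config(n_perm = 50, seed = 42)
  n1 <- permute_term(X, y, "g", cfg)
  before <- .Random.seed
  n2 <- permute_term(X, y, "g", cfg)
  expect_identical(n1, n2)
  expect_identical(before, .Random.seed)
  expect_length(n1, 50)
  expect_error(permute_term(X, y, "nope", cfg), "term")
})

test_that("label and residual schemes share an exhaustive null at n = 5
           when there are no covariates", {
  # with an intercept-only reduced model the two schemes generate the
  # same set of achievable t statistics over all 5! permutations
  set.seed(9)
  x <- c(0, 1, 0, 1, 1); y <- rnorm(5)
  X <- cbind(`(Intercept)` = 1, x = x)
  P <- all_perms(5)
  t_label <- apply(P, 1, function(p) {
    Xp <- X; Xp[, "x"] <- x[p]
    ols_fit(Xp, y)$coef$t[2]
  })
  t_fl <- apply(P, 1, function(p) {
    e <- y - mean(y)
    ols_fit(X, mean(y) + e[p])$coef$t[2]
  })
  expect_equal(sort(t_label), sort(t_fl), tolerance = 1e-10)
})

test_that("maxstat correction dominates per-test p and is symmetric", {
  set.seed(10)
  obs <- c(2.5, -1, 0.3)
  nulls <- matrix(rnorm(300), 100, 3)
  pc <- maxstat_correct(obs, nulls)
  praw <- vapply(1:3, function(j) perm_pvalue(obs[j], nulls[, j]), 0)
  expect_true(all(pc >= praw))
  # family of one reduces to perm_pvalue
  expect_equal(maxstat_correct(obs[1], nulls[, 1, drop = FALSE]),
               perm_pvalue(obs[1], nulls[, 1]))
  # duplicated member receives identical corrected p
  pc2 <- maxstat_correct(c(2, 2), cbind(nulls[, 1], nulls[, 1]))
  expect_equal(pc2[1], pc2[2])
  # corrected p monotone nondecreasing in family size
  pc_small <- maxstat_correct(obs[1], nulls[, 1, drop = FALSE])
  pc_large <- maxstat_correct(obs, nulls)[1]
  expect_gte(pc_large, pc_small)
  expect_error(maxstat_correct(c(1, 2), nulls), "mismatch")
})
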
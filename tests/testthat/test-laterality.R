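# Shared fixture: bilateral dataset where every right-hemisphere value
# is `ratio` times its left counterpart, optionally perturbed by
# multiplicative per-cell noise so the LI varies across subjects.
li_fixture <- function(ratio = 1.1, n_sub = 8, seed = 21,
                       noise_sd = 0) {
  withr::with_seed(seed, {
    left <- make_profiles_df(n_sub, c("L_AF", "L_SLF"), n_nodes = 30,
                             fill = function(s, tr, node)
                               runif(1, 0.35, 0.45))
    for (m in c("AD", "RD", "MD"))
      left[[m]] <- left[[m]] * runif(nrow(left), 0.95, 1.05)
    right <- left
    right$tractID <- sub("^L_", "R_", right$tractID)
    for (m in c("FA", "MD", "RD", "AD")) {
      f <- ratio * exp(rnorm(nrow(right), 0, noise_sd))
      right[[m]] <- right[[m]] * f
    }
    tract_profiles(rbind(left, right))
  })
}

test_that("compute_li implements (R - L)/(R + L) with antisymmetry", {
  expect_equal(compute_li(0.5, 0.5), 0)
  expect_equal(compute_li(0.4, 0.6), 0.2)
  set.seed(22)
  l <- runif(20, 0.1, 1); r <- runif(20, 0.1, 1)
  expect_equal(compute_li(l, r), -compute_li(r, l))
  expect_true(all(abs(compute_li(l, r)) < 1))
  expect_error(compute_li(-0.5, 0.2), "undefined")
})

test_that("li_table composes tract means with the LI formula", {
  ds <- li_fixture(ratio = 1.1)
  li <- li_table(ds, pairs = c("AF", "SLF"))
  # right = 1.1 x left exactly => LI = 0.1/2.1 everywhere
  expect_equal(li$li, rep(0.1 / 2.1, nrow(li)), tolerance = 1e-12)
  # cell-by-cell composition oracle on a random dataset
  ds2 <- li_fixture(ratio = 1, seed = 23, noise_sd = 0.05)
  li2 <- li_table(ds2, pairs = "AF")
  row <- li2[li2$subjectID == "s03" & li2$metric == "MD", ]
  expect_equal(row$li,
               compute_li(tract_mean(ds2, "s03", "L_AF", "MD"),
                          tract_mean(ds2, "s03", "R_AF", "MD")))
  # scale invariance: multiplying one subject's data by a constant
  # (a gentler factor for FA, which must stay within [0, 1])
  ds3 <- ds2
  sel <- ds3$subjectID == "s01"
  for (m in c("MD", "RD", "AD")) ds3[[m]][sel] <- ds3[[m]][sel] * 3.7
  ds3$FA[sel] <- ds3$FA[sel] * 1.5
  li3 <- li_table(tract_profiles(as.data.frame(ds3)), pairs = "AF")
  expect_equal(li3$li[li3$subjectID == "s01"],
               li2$li[li2$subjectID == "s01"], tolerance = 1e-12)
  # a missing hemisphere drops the subject with a warning
  ds4 <- as.data.frame(ds2)
  ds4 <- ds4[!(ds4$subjectID == "s02" & ds4$tractID == "R_AF"), ]
  expect_warning(li4 <- li_table(tract_profiles(ds4), pairs = "AF"),
                 "s02")
  expect_false("s02" %in% li4$subjectID)
})

test_that("li_table negates under hemisphere relabeling", {
  ds <- li_fixture(ratio = 1, seed = 24, noise_sd = 0.05)
  swapped <- as.data.frame(ds)
  swapped$tractID <- ifelse(grepl("^L_", swapped$tractID),
                            sub("^L_", "R_", swapped$tractID),
                            sub("^R_", "L_", swapped$tractID))
  li_a <- li_table(ds, pairs = c("AF", "SLF"))
  li_b <- li_table(tract_profiles(swapped), pairs = c("AF", "SLF"))
  key <- function(d) d[order(d$subjectID, d$tract_pair, d$metric), ]
  expect_equal(key(li_a)$li, -key(li_b)$li, tolerance = 1e-12)
})

test_that("li_one_sample recovers the definitional t and labels
           direction by metric semantics", {
  ds <- li_fixture(ratio = 1.08, n_sub = 10, noise_sd = 0.02)
  dem <- make_demog(5, 5)
  cfg <- perm_config(n_perm = 200, seed = 3)
  res <- li_one_sample(li_table(ds, pairs = c("AF", "SLF")), dem, cfg)
  # t is mean/(SD/sqrt(n)) of the realized LIs per cell
  li <- li_table(ds, pairs = c("AF", "SLF"))
  td_ids <- dem$id[dem$group == "TD"]
  v <- li$li[li$subjectID %in% td_ids & li$tract_pair == "AF" &
             li$metric == "FA"]
  row <- res[res$group == "TD" & res$tract_pair == "AF" &
             res$metric == "FA", ]
  expect_equal(row$t, mean(v) / (sd(v) / sqrt(length(v))),
               tolerance = 1e-12)
  expect_equal(row$df, length(v) - 1)
  # strong rightward shift: FA rows label rightward, diffusivity rows
  # (positive LI here too) label leftward per the metric semantics
  sig <- res[res$p_corrected < 0.05, ]
  expect_true(all(sig$direction[sig$metric == "FA"] == "rightward"))
  expect_true(all(sig$direction[sig$metric != "FA"] == "leftward"))
  expect_true(all(res$p_corrected >= res$p_raw - 1e-12))
  # degenerate all-zero LI errors
  ds0 <- li_fixture(ratio = 1)
  li0 <- li_table(ds0, pairs = "AF")
  li0$li <- 0
  expect_error(li_one_sample(li0, dem, cfg), "degenerate")
})

test_that("direction assignment reproduces the published significance
           pattern when table summaries are fed through the test", {
  # TD SLF FA: mean .0086 SD .0172 n 22 -> rightward (positive t, sig)
  tt <- one_sample_t_summary(0.0086, 0.0172, 22)
  expect_gt(tt$t, 0)
  expect_lt(tt$p, 0.05)
  # ASD AF AD: mean -.0059 SD .0105 n 28 -> negative t, significant,
  # which for a diffusivity metric reads as rightward lateralization
  tt2 <- one_sample_t_summary(-0.0059, 0.0105, 28)
  expect_lt(tt2$t, 0)
  expect_lt(tt2$p, 0.05)
})

test_that("li_group_compare recovers an injected group offset", {
  withr::with_seed(31, {
    n_td <- 12; n_asd <- 14
    dem <- make_demog(n_td, n_asd, seed = 31)
    delta <- 0.05
    li <- expand.grid(subjectID = dem$id, tract_pair = "AF",
                      metric = "FA", stringsAsFactors = FALSE)
    li$li <- rnorm(nrow(li), 0, 0.02) +
      delta * (dem$group[match(li$subjectID, dem$id)] == "ASD")
    cfg <- perm_config(n_perm = 300, seed = 5)
    res <- li_group_compare(li, dem, cfg)
    expect_lt(abs(res$beta - delta), 0.025)
    expect_lt(res$p_perm, 0.05)
  })
})

test_that("li_behavior recovers an injected slope and interaction", {
  withr::with_seed(32, {
    dem <- make_demog(12, 14, seed = 32)
    slope <- 0.0008
    li <- expand.grid(subjectID = dem$id, tract_pair = "AF",
                      metric = "FA", stringsAsFactors = FALSE)
    lang <- dem$gds_language[match(li$subjectID, dem$id)]
    grp <- dem$group[match(li$subjectID, dem$id)]
    li$li <- rnorm(nrow(li), 0, 0.01) +
      slope * (grp == "ASD") * (lang - mean(lang))
    cfg <- perm_config(n_perm = 300, seed = 6)
    res <- li_behavior(li, dem, "gds_language", cfg)
    asd <- res[res$scope == "ASD", ]
    expect_lt(abs(asd$beta - slope), 7e-4)
    expect_true(all(c("TD", "ASD", "interaction") %in% res$scope))
    inter <- res[res$scope == "interaction", ]
    expect_lt(abs(inter$beta - slope), 7e-4)
    expect_true(all(res$partial_r2 >= 0 & res$partial_r2 <= 1))
  })
})
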
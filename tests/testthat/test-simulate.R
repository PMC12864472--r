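test_that("identical seeds give bit-identical cohorts", {
  spec <- simulation_spec(n_td = 6, n_asd = 8, n_nodes = 30,
                          tracts = c("L_AF", "R_AF"), effects = NULL,
                          seed = 77)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(as.data.frame(a$profiles), as.data.frame(b$profiles))
  expect_identical(a$demographics, b$demographics)
  c <- simulate_cohort(simulation_spec(n_td = 6, n_asd = 8, n_nodes = 30,
                                       tracts = c("L_AF", "R_AF"),
                                       effects = NULL, seed = 78))
  expect_false(identical(a$profiles$FA, c$profiles$FA))
})

test_that("generated metrics satisfy the tensor-derived constraints", {
  sim <- simulate_cohort(simulation_spec(seed = 5))
  ds <- sim$profiles
  expect_true(all(ds$FA > 0 & ds$FA < 1))
  expect_true(all(ds$MD > 0 & ds$RD > 0 & ds$AD > 0))
  expect_true(all(ds$RD <= ds$AD))
  # dataset passes its own validation and the demographic invariants
  expect_silent(validate_profiles(ds))
  expect_equal(as.vector(table(sim$demographics$group)), c(22, 28))
  expect_equal(as.vector(table(sim$demographics$sex,
                               sim$demographics$group)["M", ]),
               c(17, 24))
  asd <- sim$demographics[sim$demographics$group == "ASD", ]
  expect_equal(asd$ados_total, asd$ados_sa + asd$ados_rrb)
  expect_true(all(is.na(
    sim$demographics$ados_total[sim$demographics$group == "TD"])))
  expect_true(all(sim$demographics$age >= 1.5 &
                  sim$demographics$age <= 6.07))
})

test_that("node noise has the specified autocorrelation length", {
  # empirical correlogram of the latent node noise vs the
  # squared-exponential kernel exp(-d^2 / (2 l^2))
  spec <- simulation_spec(n_td = 2, n_asd = 2, corr_length = 10)
  withr::with_seed(61, {
    L <- tractstats:::node_noise_chol(100, spec$corr_length)
    E <- t(L) %*% matrix(rnorm(100 * 2000), 100, 2000)
    for (lag in c(5, 10, 20)) {
      emp <- mean(vapply(seq_len(100 - lag), function(i)
        cor(E[i, ], E[i + lag, ]), 0))
      expect_lt(abs(emp - exp(-lag^2 / 200)), 0.05)
    }
  })
})

test_that("null cohorts have no group effect or mean asymmetry", {
  # across replicates, empirical group difference and mean LI stay
  # within Monte-Carlo error of zero
  reps <- 40
  diffs <- numeric(reps); lis <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_null(simulation_spec(
      n_td = 10, n_asd = 10, n_nodes = 30, tracts = c("L_SLF", "R_SLF"),
      effects = NULL, behavior_links = NULL, seed = 700 + r))
    tm <- tract_means(sim$profiles, "FA")
    v <- tm$value[tm$tractID == "L_SLF"]
    g <- sim$demographics$group[match(tm$subjectID[tm$tractID == "L_SLF"],
                                      sim$demographics$id)]
    diffs[r] <- mean(v[g == "ASD"]) - mean(v[g == "TD"])
    li <- li_table(sim$profiles, metrics = "FA", pairs = "SLF")
    lis[r] <- mean(li$li)
  }
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(reps))
  expect_lt(abs(mean(lis)), 2 * sd(lis) / sqrt(reps))
})

test_that("injected LI targets are recovered by the one-sample pipeline", {
  # SLF FA target 0.0086 in the TD group: average recovered mean LI
  # across replicates within 2 MC-SE of the target
  reps <- 30
  got <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- simulation_spec(n_td = 22, n_asd = 2, n_nodes = 40,
                            tracts = c("L_SLF", "R_SLF"),
                            effects = NULL, behavior_links = NULL,
                            seed = 900 + r)
    sim <- simulate_cohort(spec)
    li <- li_table(sim$profiles, metrics = "FA", pairs = "SLF")
    td <- sim$demographics$id[sim$demographics$group == "TD"]
    got[r] <- mean(li$li[li$subjectID %in% td])
  }
  expect_lt(abs(mean(got) - 0.0086), 2 * sd(got) / sqrt(reps))
})

test_that("injected interval effects equal the fitted group beta at the
           interval center", {
  # large-n check of generative linearity: the fitted group coefficient
  # at the center node approximates the absolute amplitude
  spec <- simulation_spec(
    n_td = 150, n_asd = 150, n_nodes = 30, tracts = c("L_AF", "R_AF"),
    asymmetry = within(default_asymmetry(), li_mean <- 0),
    effects = data.frame(tractID = "L_AF", metric = "FA",
                         node_start = 10, node_end = 20,
                         amplitude = 1, standardized = TRUE),
    behavior_links = NULL, seed = 99)
  sim <- simulate_cohort(spec)
  amp_abs <- sim$truth$effects$amplitude_abs
  Y <- node_matrix(sim$profiles, "L_AF", "FA")
  dem <- sim$demographics
  X <- design_matrix(~ group + age + sex, dem)
  beta15 <- ols_fit(X, Y[dem$id, "15"])$coef
  b <- beta15$beta[beta15$term == "groupASD"]
  se <- beta15$se[beta15$term == "groupASD"]
  expect_lt(abs(b - amp_abs), 3 * se)
  # and the delta-method SD used for standardization is close to the
  # empirical covariate-adjusted between-subject node SD (within 20%)
  td <- dem[dem$group == "TD", ]
  resid_td <- ols_fit(design_matrix(~ age + sex, td),
                      Y[td$id, "15"])$residuals
  td_sd <- sd(resid_td)
  expect_lt(abs(td_sd - amp_abs) / amp_abs, 0.2)
})

test_that("null_spec zeroes effects, links and mean asymmetry only", {
  spec <- simulation_spec()
  ns <- null_spec(spec)
  expect_equal(nrow(ns$effects), 0)
  expect_true(all(ns$behavior_links$slope == 0))
  expect_true(all(ns$asymmetry$li_mean == 0))
  expect_equal(ns$asymmetry$li_sd, spec$asymmetry$li_sd)
  expect_equal(ns$noise_sd_logad, spec$noise_sd_logad)
})

test_that("spec validation rejects off-grid intervals", {
  expect_error(simulation_spec(
    n_nodes = 50,
    effects = data.frame(tractID = "L_AF", metric = "FA",
                         node_start = 45, node_end = 55,
                         amplitude = 1)), "off the node grid")
})
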
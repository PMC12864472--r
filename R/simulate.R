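# Synthetic tract-profile generator. Emulates the cohort structure the
# analyses assume: two groups (TD/ASD) of young children, 8 bilateral
# language tracts x 100 nodes x 4 coupled diffusion metrics with smooth
# node-autocorrelated profiles, hemispheric asymmetry, localized group
# effects on node intervals, age/sex covariate effects, and behavior
# scores coupled to tract metrics. Every injected parameter is returned
# in a truth record so recovery can be tested.

#' Default per-group score distributions
#'
#' Mean, SD and truncation range for each behavioral instrument per
#' group; scores are drawn from truncated normals so developmental
#' quotients stay within observed support.
#'
#' @return Nested list: group -> instrument -> c(mean, sd, lo, hi).
#' @export
default_score_models <- function() {
  list(
    TD = list(
      age = c(mean = 2.97, sd = 1.31, lo = 1.5, hi = 5.81),
      abc = c(mean = 23.59, sd = 7.7, lo = 8, hi = 40),
      gds_language = c(mean = 93.51, sd = 4.03, lo = 83.3, hi = 101),
      gds_personal_social = c(mean = 94.07, sd = 4.01, lo = 83.3, hi = 103),
      gds_gross_motor = c(mean = 98.38, sd = 5.5, lo = 83, hi = 107),
      gds_fine_motor = c(mean = 96.43, sd = 4.82, lo = 86, hi = 105),
      gds_adaptive = c(mean = 95.44, sd = 4.09, lo = 88, hi = 105),
      gds_total = c(mean = 95.08, sd = 3.85, lo = 86.1, hi = 100.8)),
    ASD = list(
      age = c(mean = 3.24, sd = 1.26, lo = 1.67, hi = 6.07),
      abc = c(mean = 70.25, sd = 14.13, lo = 53, hi = 107),
      gds_language = c(mean = 46.8, sd = 11.9, lo = 23.6, hi = 70.7),
      gds_personal_social = c(mean = 55.59, sd = 9.15, lo = 32.4, hi = 70.2),
      gds_gross_motor = c(mean = 76.17, sd = 7.07, lo = 64.1, hi = 89.3),
      gds_fine_motor = c(mean = 68.72, sd = 9.61, lo = 45.9, hi = 84.2),
      gds_adaptive = c(mean = 60.54, sd = 11.39, lo = 38.6, hi = 73.7),
      gds_total = c(mean = 61.58, sd = 7.99, lo = 43.5, hi = 73.6),
      ados_sa = c(mean = 12.75, sd = 3.69, lo = 7, hi = 22),
      ados_rrb = c(mean = 1.18, sd = 0.77, lo = 0, hi = 3)))
}

#' Default hemispheric asymmetry targets
#'
#' Mean and between-subject SD of the lateralization index per group,
#' tract pair and metric (diffusivities leftward on average, FA
#' rightward in the SLF).
#'
#' @return Data frame: `group`, `tract_pair`, `metric`, `li_mean`,
#'   `li_sd`.
#' @export
default_asymmetry <- function() {
  tab <- expand.grid(group = c("TD", "ASD"),
                     tract_pair = tract_pairs(),
                     metric = metric_names(),
                     stringsAsFactors = FALSE)
  vals <- rbind(
    # metric, pair, TD mean, TD sd, ASD mean, ASD sd
    c("FA", "AF",  -0.0029, 0.0224, -0.0054, 0.0225),
    c("FA", "IFOF", 0.0040, 0.0132, -0.0021, 0.0135),
    c("FA", "ILF",  0.0063, 0.0165,  0.0047, 0.0117),
    c("FA", "SLF",  0.0086, 0.0172,  0.0140, 0.0231),
    c("MD", "AF",  -0.0047, 0.0074, -0.0051, 0.0062),
    c("MD", "IFOF", -0.0052, 0.0098, -0.0072, 0.0199),
    c("MD", "ILF",  -0.0095, 0.0168, -0.0087, 0.0170),
    c("MD", "SLF",  -0.0092, 0.0113, -0.0071, 0.0091),
    c("RD", "AF",  -0.0034, 0.0114, -0.0041, 0.0134),
    c("RD", "IFOF", -0.0067, 0.0129, -0.0060, 0.0237),
    c("RD", "ILF",  -0.0120, 0.0231, -0.0111, 0.0199),
    c("RD", "SLF",  -0.0145, 0.0130, -0.0139, 0.0135),
    c("AD", "AF",  -0.0057, 0.0141, -0.0059, 0.0105),
    c("AD", "IFOF", -0.0040, 0.0102, -0.0082, 0.0181),
    c("AD", "ILF",  -0.0069, 0.0127, -0.0064, 0.0165),
    c("AD", "SLF",  -0.0038, 0.0138, -0.0003, 0.0143))
  df <- data.frame(metric = vals[, 1], tract_pair = vals[, 2],
                   td_mean = as.numeric(vals[, 3]),
                   td_sd = as.numeric(vals[, 4]),
                   asd_mean = as.numeric(vals[, 5]),
                   asd_sd = as.numeric(vals[, 6]),
                   stringsAsFactors = FALSE)
  out <- rbind(
    data.frame(group = "TD", tract_pair = df$tract_pair,
               metric = df$metric, li_mean = df$td_mean,
               li_sd = df$td_sd, stringsAsFactors = FALSE),
    data.frame(group = "ASD", tract_pair = df$tract_pair,
               metric = df$metric, li_mean = df$asd_mean,
               li_sd = df$asd_sd, stringsAsFactors = FALSE))
  out
}

#' Default localized group effects
#'
#' ASD-minus-TD effects on node intervals, in standardized units of the
#' between-subject node SD: FA elevations and AD shifts on localized
#' segments of the arcuate, superior longitudinal, inferior
#' fronto-occipital and inferior longitudinal fasciculi.
#'
#' @param amplitude Standardized amplitude applied to every interval.
#' @return Data frame: `tractID`, `metric`, `node_start`, `node_end`,
#'   `amplitude`, `standardized`.
#' @export
default_effects <- function(amplitude = 1) {
  eff <- rbind(
    data.frame(tractID = c("L_AF", "L_SLF", "L_IFOF", "R_SLF", "R_SLF",
                           "R_IFOF"),
               metric = "FA",
               node_start = c(38, 82, 53, 3, 66, 51),
               node_end = c(42, 90, 56, 9, 72, 56),
               amplitude = amplitude, stringsAsFactors = FALSE),
    data.frame(tractID = c("L_SLF", "R_AF", "R_ILF", "R_SLF", "R_SLF"),
               metric = "AD",
               node_start = c(22, 17, 89, 2, 66),
               node_end = c(30, 20, 95, 7, 69),
               amplitude = c(-amplitude, -amplitude, amplitude,
                             amplitude, amplitude),
               stringsAsFactors = FALSE))
  eff$standardized <- TRUE
  eff
}

#' Default behavior couplings
#'
#' Within-group slopes of a tract metric on a behavior score, in metric
#' units per score point (language-score couplings to FA/RD and
#' severity couplings to FA/RD in the ASD group).
#'
#' @return Data frame: `group`, `score`, `tractID`, `metric`, `slope`.
#' @export
default_behavior_links <- function() {
  data.frame(
    group = c("ASD", "ASD", "ASD", "ASD", "ASD", "ASD"),
    score = c("gds_language", "gds_language", "gds_language",
              "gds_language", "ados_total", "ados_total"),
    tractID = c("L_AF", "L_ILF", "R_ILF", "L_AF", "L_AF", "L_ILF"),
    metric = c("FA", "FA", "FA", "RD", "FA", "RD"),
    slope = c(-0.001, -0.0008, -0.0009, 1.46e-06, 0.003, -4.7e-06),
    stringsAsFactors = FALSE)
}

#' Simulation specification for synthetic tract profiles
#'
#' Bundles every parameter of the generative model. Defaults emulate a
#' two-group early-childhood cohort: 22 TD and 28 ASD children, ages
#' roughly 1.5-6 years, 8 bilateral language tracts x 100 nodes x 4
#' coupled diffusion metrics, hemispheric asymmetries matching the
#' published per-group LI tables, localized standardized group effects
#' on the published node intervals, and behavior scores coupled to tract
#' metrics at the published slopes.
#'
#' The diffusion metrics are generated from a latent axial diffusivity
#' (log scale) and a latent radial/axial ratio (logit scale), so that
#' MD = (AD + 2 RD)/3, FA = (1 - r)/sqrt(1 + 2 r^2) and RD <= AD hold by
#' construction before metric-targeted perturbations are added.
#'
#' @param n_td,n_asd Group sizes.
#' @param n_nodes Node-grid size.
#' @param tracts Tract identifiers (`L_`/`R_` prefixed pairs).
#' @param p_male Named vector of male proportions per group.
#' @param subject_sd_logad,subject_sd_logitr Between-subject SDs of the
#'   latent random effects.
#' @param noise_sd_logad,noise_sd_logitr Node-level noise SDs on the
#'   latent scales.
#' @param corr_length Correlation length (in nodes) of the stationary
#'   squared-exponential node-noise kernel.
#' @param age_slope_logad,age_slope_logitr Covariate effect of age
#'   (per year) on the latent scales.
#' @param sex_effect_logitr Additive effect of female sex on the latent
#'   ratio scale.
#' @param asymmetry Data frame (`group`, `tract_pair`, `metric`,
#'   `li_mean`, `li_sd`) of LI targets; see [default_asymmetry()].
#' @param effects Data frame (`tractID`, `metric`, `node_start`,
#'   `node_end`, `amplitude`, `standardized`) of ASD-minus-TD effects.
#' @param behavior_links Data frame (`group`, `score`, `tractID`,
#'   `metric`, `slope`) of metric-score couplings.
#' @param score_models Per-group score distributions; see
#'   [default_score_models()].
#' @param taper_width Nodes over which an injected interval effect decays
#'   smoothly to zero outside its interval.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return List with class `sim_spec`.
#' @export
simulation_spec <- function(n_td = 22, n_asd = 28, n_nodes = 100,
                            tracts = default_tracts(),
                            p_male = c(TD = 17 / 22, ASD = 24 / 28),
                            subject_sd_logad = 0.035,
                            subject_sd_logitr = 0.09,
                            noise_sd_logad = 0.025,
                            noise_sd_logitr = 0.06,
                            corr_length = 10,
                            age_slope_logad = -0.02,
                            age_slope_logitr = -0.06,
                            sex_effect_logitr = 0.02,
                            asymmetry = default_asymmetry(),
                            effects = default_effects(),
                            behavior_links = default_behavior_links(),
                            score_models = default_score_models(),
                            taper_width = 2,
                            seed = 1) {
  nodes <- seq_len(n_nodes) - 1L
  # simulating a subset of tracts restricts the injected conditions to it
  if (!is.null(effects) && nrow(effects) > 0)
    effects <- effects[effects$tractID %in% tracts, , drop = FALSE]
  if (!is.null(behavior_links) && nrow(behavior_links) > 0)
    behavior_links <-
      behavior_links[behavior_links$tractID %in% tracts, , drop = FALSE]
  if (!is.null(effects) && nrow(effects) > 0) {
    off <- !(effects$node_start %in% nodes) |
      !(effects$node_end %in% nodes) |
      effects$node_start > effects$node_end
    if (any(off))
      stop("effect interval off the node grid: row(s) ",
           paste(which(off), collapse = ", "))
    stopifnot(all(is.finite(effects$amplitude)))
  }
  stopifnot(n_td >= 2, n_asd >= 2, n_nodes >= 2,
            subject_sd_logad > 0, subject_sd_logitr > 0,
            noise_sd_logad > 0, noise_sd_logitr > 0, corr_length > 0)
  structure(list(
    n_td = n_td, n_asd = n_asd, n_nodes = n_nodes, tracts = tracts,
    p_male = p_male, subject_sd_logad = subject_sd_logad,
    subject_sd_logitr = subject_sd_logitr,
    noise_sd_logad = noise_sd_logad,
    noise_sd_logitr = noise_sd_logitr, corr_length = corr_length,
    age_slope_logad = age_slope_logad,
    age_slope_logitr = age_slope_logitr,
    sex_effect_logitr = sex_effect_logitr,
    asymmetry = asymmetry, effects = effects,
    behavior_links = behavior_links, score_models = score_models,
    taper_width = taper_width, seed = as.integer(seed)),
    class = "sim_spec")
}

#' Null variant of a simulation spec
#'
#' Zeroes every group effect, behavior coupling and mean asymmetry while
#' keeping all nuisance structure (noise, random effects, covariate
#' effects, LI between-subject spread), for calibration suites.
#'
#' @param spec A [simulation_spec()].
#' @return A `sim_spec` with effects removed, link slopes zeroed and
#'   `li_mean` set to 0 everywhere.
#' @export
null_spec <- function(spec = simulation_spec()) {
  spec$effects <- spec$effects[0, , drop = FALSE]
  if (!is.null(spec$behavior_links) && nrow(spec$behavior_links) > 0)
    spec$behavior_links$slope <- 0
  spec$asymmetry$li_mean <- 0
  spec
}

# truncated normal by rejection (ranges are a few SDs wide, so cheap)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Smooth baseline profiles on [0, 1]: gentle tract-specific undulation
# around typical early-childhood white-matter values (AD ~ 1.3e-3,
# RD/AD ratio ~ 0.42).
baseline_latents <- function(spec) {
  u <- (seq_len(spec$n_nodes) - 1) / (spec$n_nodes - 1)
  pairs <- tract_pairs()
  shapes <- list(
    AF = list(ad = 0.06 * sin(2 * pi * u), r = 0.10 * cos(pi * u)),
    IFOF = list(ad = 0.05 * cos(2 * pi * u), r = 0.08 * sin(pi * u)),
    ILF = list(ad = 0.04 * sin(pi * u), r = 0.09 * sin(2 * pi * u)),
    SLF = list(ad = 0.05 * cos(pi * u), r = 0.07 * cos(2 * pi * u)))
  out <- list()
  for (tr in spec$tracts) {
    pr <- sub("^[LR]_", "", tr)
    sh <- shapes[[pr]]
    if (is.null(sh)) sh <- list(ad = 0 * u, r = 0 * u)
    out[[tr]] <- list(logad = log(1.3e-3) + sh$ad,
                      logitr = stats::qlogis(0.42) + sh$r)
  }
  out
}

# Cholesky factor of the squared-exponential node-correlation kernel.
node_noise_chol <- function(n_nodes, corr_length) {
  d <- abs(outer(seq_len(n_nodes), seq_len(n_nodes), "-"))
  K <- exp(-d^2 / (2 * corr_length^2))
  chol(K + diag(1e-8, n_nodes))
}

# Smooth interval weight: 1 inside [start, end], half-cosine decay over
# `taper` nodes beyond each edge (effects in real profiles bleed
# smoothly past any nominal boundary).
interval_weight <- function(nodes, start, end, taper) {
  w <- numeric(length(nodes))
  w[nodes >= start & nodes <= end] <- 1
  if (taper > 0) {
    lo <- nodes >= start - taper & nodes < start
    w[lo] <- 0.5 * (1 + cos(pi * (start - nodes[lo]) / (taper + 1)))
    hi <- nodes > end & nodes <= end + taper
    w[hi] <- 0.5 * (1 + cos(pi * (nodes[hi] - end) / (taper + 1)))
  }
  w
}

# metrics from the latent pair (vectorized)
latents_to_metrics <- function(ad, r) {
  list(AD = ad, RD = r * ad, MD = (1 + 2 * r) / 3 * ad,
       FA = (1 - r) / sqrt(1 + 2 * r^2))
}

# Delta-method between-subject SD of a metric node value, at the
# baseline latents, used to convert standardized effect amplitudes into
# metric units.
node_metric_sd <- function(spec, tract, metric, node_idx) {
  bl <- baseline_latents(spec)[[tract]]
  mu_ad <- exp(bl$logad[node_idx])
  r <- stats::plogis(bl$logitr[node_idx])
  s_ad <- sqrt(spec$subject_sd_logad^2 + spec$noise_sd_logad^2)
  s_r <- sqrt(spec$subject_sd_logitr^2 + spec$noise_sd_logitr^2)
  sd_ad <- mu_ad * s_ad          # lognormal, small-sigma
  sd_r <- r * (1 - r) * s_r      # logistic-normal, small-sigma
  out <- switch(metric,
    AD = sd_ad,
    RD = sqrt((r * sd_ad)^2 + (mu_ad * sd_r)^2),
    MD = sqrt(((1 + 2 * r) / 3 * sd_ad)^2 + (2 * mu_ad / 3 * sd_r)^2),
    FA = {
      g <- (1 + 2 * r^2)^(-0.5) *
        (1 + 2 * r * (1 - r) / (1 + 2 * r^2))
      g * sd_r
    })
  mean(out)
}

# Smooth unit-interval squash: identity on [lo, hi], exponential
# approach to 0 and 1 outside, C1 everywhere.
squash_unit <- function(x, lo = 0.02, hi = 0.98) {
  below <- x < lo; above <- x > hi
  x[below] <- lo * exp((x[below] - lo) / lo)
  x[above] <- 1 - (1 - hi) * exp(-(x[above] - hi) / (1 - hi))
  x
}

#' Generate a synthetic cohort
#'
#' Draws demographics/behavior and tract profiles from a
#' [simulation_spec()]: smooth per-tract baselines plus subject random
#' effects and node-autocorrelated noise on the latent (log AD,
#' logit RD/AD) scales, covariate effects of age and sex, per-subject
#' hemispheric asymmetry targeting the spec's LI means, localized group
#' effects with smoothly tapered edges, and behavior couplings. The same
#' seed yields a bit-identical cohort.
#'
#' @param spec A [simulation_spec()].
#' @return List: `profiles` (a [tract_profiles()] dataset),
#'   `demographics` (data frame), `truth` (list of every injected
#'   parameter, including the effect amplitudes in metric units and the
#'   delta-method node SDs used to standardize them).
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_rng(spec$seed, {
    n <- spec$n_td + spec$n_asd
    ids <- sprintf("sub%03d", seq_len(n))
    group <- factor(rep(c("TD", "ASD"), c(spec$n_td, spec$n_asd)),
                    levels = c("TD", "ASD"))
    dem <- data.frame(id = ids, group = group, stringsAsFactors = FALSE)
    dem$sex <- "F"
    for (g in c("TD", "ASD")) {
      idx <- which(dem$group == g)
      n_m <- round(length(idx) * spec$p_male[[g]])
      dem$sex[idx[seq_len(n_m)]] <- "M"
    }
    dem$sex <- factor(dem$sex, levels = c("M", "F"))
    sm <- spec$score_models
    dem$age <- NA_real_
    for (g in c("TD", "ASD")) {
      idx <- which(dem$group == g)
      p <- sm[[g]][["age"]]
      dem$age[idx] <- rtruncnorm(length(idx), p["mean"], p["sd"],
                                 p["lo"], p["hi"])
    }
    score_cols <- unique(unlist(lapply(sm, function(x)
      setdiff(names(x), "age"))))
    for (sc in score_cols) dem[[sc]] <- NA_real_
    for (g in c("TD", "ASD")) {
      idx <- which(dem$group == g)
      for (sc in setdiff(names(sm[[g]]), "age")) {
        p <- sm[[g]][[sc]]
        dem[[sc]][idx] <- rtruncnorm(length(idx), p["mean"], p["sd"],
                                     p["lo"], p["hi"])
      }
    }
    if (all(c("ados_sa", "ados_rrb") %in% names(dem)))
      dem$ados_total <- dem$ados_sa + dem$ados_rrb
    dem <- validate_demographics(dem)

    nodes <- seq_len(spec$n_nodes) - 1L
    bl <- baseline_latents(spec)
    L <- node_noise_chol(spec$n_nodes, spec$corr_length)
    age_c <- dem$age - mean(dem$age)
    sexF <- as.numeric(dem$sex == "F")

    # per-subject asymmetry draws per (pair, metric)
    asym <- spec$asymmetry
    A <- array(0, dim = c(n, length(tract_pairs()), 4),
               dimnames = list(ids, tract_pairs(), metric_names()))
    for (i in seq_len(nrow(asym))) {
      idx <- which(dem$group == asym$group[i])
      A[idx, asym$tract_pair[i], asym$metric[i]] <-
        stats::rnorm(length(idx), asym$li_mean[i], asym$li_sd[i])
    }

    mets <- metric_names()
    vals <- vector("list", length(spec$tracts))
    names(vals) <- spec$tracts
    # subject random effects are shared between the hemispheres of a
    # pair (same child, same bundle), so laterality noise comes from
    # node noise and the asymmetry draws, not the subject effect
    pairs_present <- unique(sub("^[LR]_", "", spec$tracts))
    u_ad_pair <- lapply(pairs_present, function(p)
      stats::rnorm(n, 0, spec$subject_sd_logad))
    names(u_ad_pair) <- pairs_present
    u_r_pair <- lapply(pairs_present, function(p)
      stats::rnorm(n, 0, spec$subject_sd_logitr))
    names(u_r_pair) <- pairs_present
    for (tr in spec$tracts) {
      hemi <- substr(tr, 1, 1)
      pr <- sub("^[LR]_", "", tr)
      u_ad <- u_ad_pair[[pr]]
      u_r <- u_r_pair[[pr]]
      e_ad <- t(L) %*% matrix(stats::rnorm(spec$n_nodes * n), ncol = n) *
        spec$noise_sd_logad
      e_r <- t(L) %*% matrix(stats::rnorm(spec$n_nodes * n), ncol = n) *
        spec$noise_sd_logitr
      logad <- outer(bl[[tr]]$logad, rep(1, n)) + e_ad
      logad <- sweep(logad, 2, u_ad + spec$age_slope_logad * age_c, "+")
      logitr <- outer(bl[[tr]]$logitr, rep(1, n)) + e_r
      logitr <- sweep(logitr, 2,
                      u_r + spec$age_slope_logitr * age_c +
                        spec$sex_effect_logitr * sexF, "+")
      m <- latents_to_metrics(exp(logad), stats::plogis(logitr))
      # hemispheric asymmetry: right scaled by (1 + A), left by (1 - A)
      if (pr %in% tract_pairs()) {
        sgn <- if (hemi == "R") 1 else -1
        for (met in mets)
          m[[met]] <- sweep(m[[met]], 2, 1 + sgn * A[, pr, met], "*")
      }
      vals[[tr]] <- m
    }

    # localized group effects (added to ASD subjects)
    truth_eff <- NULL
    eff <- spec$effects
    if (!is.null(eff) && nrow(eff) > 0) {
      asd_idx <- which(dem$group == "ASD")
      truth_eff <- eff
      truth_eff$amplitude_abs <- NA_real_
      for (i in seq_len(nrow(eff))) {
        tr <- eff$tractID[i]; met <- eff$metric[i]
        std <- if (!is.null(eff$standardized)) eff$standardized[i] else TRUE
        amp <- eff$amplitude[i]
        if (std) {
          idx <- which(nodes >= eff$node_start[i] &
                       nodes <= eff$node_end[i])
          amp <- amp * node_metric_sd(spec, tr, met, idx)
        }
        truth_eff$amplitude_abs[i] <- amp
        w <- interval_weight(nodes, eff$node_start[i], eff$node_end[i],
                             spec$taper_width)
        vals[[tr]][[met]][, asd_idx] <-
          vals[[tr]][[met]][, asd_idx] + amp * w
      }
    }

    # behavior couplings: metric shifted by slope * centered score
    links <- spec$behavior_links
    if (!is.null(links) && nrow(links) > 0) {
      for (i in seq_len(nrow(links))) {
        g <- links$group[i]
        idx <- which(dem$group == g & !is.na(dem[[links$score[i]]]))
        if (length(idx) == 0) next
        sc <- dem[[links$score[i]]][idx]
        shift <- links$slope[i] * (sc - mean(sc))
        vals[[links$tractID[i]]][[links$metric[i]]][, idx] <-
          sweep(vals[[links$tractID[i]]][[links$metric[i]]][, idx,
                                                            drop = FALSE],
                2, shift, "+")
      }
    }

    # final projection: FA smoothly squashed into (0, 1); RD capped
    # just below AD if a metric-targeted perturbation crossed it
    n_squash <- 0L; n_rdcap <- 0L
    for (tr in spec$tracts) {
      fa <- vals[[tr]]$FA
      out_of_range <- fa < 0.02 | fa > 0.98
      n_squash <- n_squash + sum(out_of_range)
      vals[[tr]]$FA <- squash_unit(fa)
      over <- vals[[tr]]$RD > vals[[tr]]$AD
      n_rdcap <- n_rdcap + sum(over)
      vals[[tr]]$RD[over] <- vals[[tr]]$AD[over] * 0.999
    }

    rows <- do.call(rbind, lapply(spec$tracts, function(tr) {
      data.frame(subjectID = rep(ids, each = spec$n_nodes),
                 tractID = tr, nodeID = rep(nodes, n),
                 FA = as.numeric(vals[[tr]]$FA),
                 MD = as.numeric(vals[[tr]]$MD),
                 RD = as.numeric(vals[[tr]]$RD),
                 AD = as.numeric(vals[[tr]]$AD),
                 stringsAsFactors = FALSE)
    }))
    ds <- tract_profiles(rows)
    truth <- list(spec = spec, effects = truth_eff,
                  behavior_links = links, asymmetry = spec$asymmetry,
                  age_slopes = c(logad = spec$age_slope_logad,
                                 logitr = spec$age_slope_logitr),
                  n_fa_squashed = n_squash, n_rd_capped = n_rdcap)
    list(profiles = ds, demographics = dem, truth = truth)
  })
}

#' Generate a null cohort
#'
#' Convenience wrapper: [simulate_cohort()] on [null_spec()], sharing
#' all nuisance structure but with every effect, coupling and mean
#' asymmetry zeroed.
#'
#' @param spec A [simulation_spec()] (its seed is kept).
#' @return As [simulate_cohort()].
#' @export
simulate_null <- function(spec = simulation_spec()) {
  simulate_cohort(null_spec(spec))
}
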
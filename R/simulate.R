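# Moments of a normal truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  d <- (dnorm(a) - dnorm(b)) / z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - d^2)
  c(mean = unname(m), sd = unname(sqrt(v)))
}

# Underlying (mu, sigma) such that the [lo, hi]-truncated normal has the
# requested mean and sd (moment matching; corrects the small truncation
# bias instead of ignoring it).
truncnorm_match <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF sample of the truncated normal from standard-normal draws
# (the copula margin transform).
truncnorm_from_z <- function(z, mu, sigma, lo, hi) {
  a <- pnorm((lo - mu) / sigma)
  b <- pnorm((hi - mu) / sigma)
  qnorm(a + pnorm(z) * (b - a)) * sigma + mu
}

default_outcome_models <- function() {
  list(
    gwg_kg = list(
      target_mean = 12.0, resid_sd = 6.26, neonatal = FALSE,
      coef = c(pei_upf = 1.33, age = 2.6, "pei_upf:age" = -0.05,
               obese = -5.1, "pei_upf:obese" = 0.06,
               energy_kcal_per_day = 0.003, fat_g_per_day = -0.06,
               race_aa = -7.9, clinic_high = -2.0, moderate_pa_pct = -0.2,
               gest_age = 0)
    ),
    thigh_skinfold_mm = list(
      target_mean = 6.6, resid_sd = 1.16, neonatal = TRUE,
      coef = c(pei_upf = 0.22, age = 0.4, "pei_upf:age" = -0.008,
               obese = -2.6, "pei_upf:obese" = 0.06,
               energy_kcal_per_day = -0.0009, fat_g_per_day = 0.03,
               race_aa = -0.3, clinic_high = 0.3, moderate_pa_pct = -0.05,
               gest_age = 0.3)
    ),
    subscap_skinfold_mm = list(
      target_mean = 4.4, resid_sd = 0.82, neonatal = TRUE,
      coef = c(pei_upf = 0.14, age = 0.3, "pei_upf:age" = -0.006,
               obese = -0.8, "pei_upf:obese" = 0.02,
               energy_kcal_per_day = 0.0002, fat_g_per_day = -0.0008,
               race_aa = -0.2, clinic_high = -0.08, moderate_pa_pct = -0.004,
               gest_age = 0.2)
    ),
    neonate_bodyfat_pct = list(
      target_mean = 11.5, resid_sd = 3.40, neonatal = TRUE,
      coef = c(pei_upf = 0.62, age = 1.3, "pei_upf:age" = -0.02,
               obese = -3.0, "pei_upf:obese" = 0.09,
               energy_kcal_per_day = 0.0009, fat_g_per_day = -0.01,
               race_aa = 0.3, clinic_high = 1.4, moderate_pa_pct = 0.04,
               gest_age = -0.1)
    )
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions the modelling stage assumes: a
#' two-group (16 lean / 29 obese) pregnancy cohort of 45 women whose
#' ultra-processed energy share (PEI-UPF) averages 54.4 with SD 13.2,
#' strongly negatively correlated (r = -0.74, via a Gaussian copula) with
#' an HEI-2010 diet-quality score of mean 62.2, SD 13.0; maternal age 27.2
#' +- 5.1 years; and linear outcome models whose focal PEI-UPF effects
#' default to 1.33 kg gestational weight gain, 0.22 mm thigh skinfold,
#' 0.14 mm subscapular skinfold and 0.62 percentage points of neonatal
#' body fat per percentage point of PEI-UPF, each with a negative
#' PEI-UPF-by-age interaction and a (non-significant) PEI-UPF-by-obesity
#' interaction. Residual SDs were calibrated once so the focal standard
#' errors at n = 45 match the half-widths of the confidence intervals the
#' models are expected to produce; see the methods vignette.
#'
#' @param n_subjects Cohort size (default 45).
#' @param lean_fraction Fraction assigned to the lean group, allocated
#'   exactly (default 16/45).
#' @param pei_upf_mean,pei_upf_sd Target moments of PEI-UPF, truncated to
#'   \[0, 100\] with moment-matching (defaults 54.4, 13.2).
#' @param hei_mean,hei_sd Target HEI-2010 moments (defaults 62.2, 13.0).
#' @param hei_corr Copula correlation between PEI-UPF and HEI-2010
#'   (default -0.74; must satisfy |r| < 1).
#' @param age_mean,age_sd Maternal age (defaults 27.2, 5.1).
#' @param race_aa_prob,clinic_high_prob Bernoulli probabilities of the
#'   African-American/other race coding (0.533) and the high-income clinic
#'   (0.578).
#' @param pa_mean,pa_sd Percent of time in moderate physical activity
#'   (13.8, 4.1).
#' @param energy_kcal_mean,energy_kcal_sd Daily energy intake covariate in
#'   kcal (2510, 550).
#' @param fat_per_kcal,fat_sd Daily fat grams are generated as
#'   `fat_per_kcal * energy + noise` (defaults 0.0389 g/kcal — about 35% of
#'   energy from fat — and SD 12 g).
#' @param gest_age_mean,gest_age_sd Gestational age at neonatal
#'   measurement in weeks (39.6, 1.2).
#' @param outcome_models Per-outcome list: `target_mean`, `resid_sd`,
#'   `neonatal` flag and named coefficient vector (see
#'   `upfdiet:::default_outcome_models`). The intercept is solved so the
#'   expected outcome equals `target_mean` at the covariate means.
#' @param missing_rate MCAR masking rate applied to generated responses
#'   (default 0.05).
#' @param seed Integer seed (default 1).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 45,
                          lean_fraction = 16 / 45,
                          pei_upf_mean = 54.4, pei_upf_sd = 13.2,
                          hei_mean = 62.2, hei_sd = 13.0,
                          hei_corr = -0.74,
                          age_mean = 27.2, age_sd = 5.1,
                          race_aa_prob = 0.533, clinic_high_prob = 0.578,
                          pa_mean = 13.8, pa_sd = 4.1,
                          energy_kcal_mean = 2510, energy_kcal_sd = 550,
                          fat_per_kcal = 0.0389, fat_sd = 12,
                          gest_age_mean = 39.6, gest_age_sd = 1.2,
                          outcome_models = default_outcome_models(),
                          missing_rate = 0.05,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (abs(cfg$hei_corr) >= 1) abort("|hei_corr| must be < 1.")
  if (cfg$lean_fraction < 0 || cfg$lean_fraction > 1 ||
      cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    abort("fractions and rates must lie in [0, 1].")
  }
  for (s in c("pei_upf_sd", "hei_sd", "age_sd", "pa_sd", "energy_kcal_sd",
              "gest_age_sd")) {
    if (cfg[[s]] <= 0) abort(sprintf("`%s` must be > 0.", s))
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' Draws covariates from the configured distributions (PEI-UPF and
#' HEI-2010 through a Gaussian copula with moment-matched truncated-normal
#' margins; exact lean/obese allocation), then builds each outcome as its
#' configured linear predictor plus normal noise. Deterministic for a
#' fixed `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: dietary indices, covariates
#'   (factors `race`, `clinic`, `weight_status` with reference levels
#'   Caucasian / low_income / lean) and the four outcomes.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  # dietary indices via Gaussian copula
  z1 <- rnorm(n)
  z2 <- config$hei_corr * z1 + sqrt(1 - config$hei_corr^2) * rnorm(n)
  ppar <- truncnorm_match(config$pei_upf_mean, config$pei_upf_sd, 0, 100)
  hpar <- truncnorm_match(config$hei_mean, config$hei_sd, 0, 100)
  pei <- truncnorm_from_z(z1, ppar["mu"], ppar["sigma"], 0, 100)
  hei <- truncnorm_from_z(z2, hpar["mu"], hpar["sigma"], 0, 100)

  n_lean <- round(n * config$lean_fraction)
  ws <- sample(rep(c("lean", "obese"), c(n_lean, n - n_lean)))
  age <- rnorm(n, config$age_mean, config$age_sd)
  race_aa <- rbinom(n, 1, config$race_aa_prob)
  clinic_high <- rbinom(n, 1, config$clinic_high_prob)
  pa <- pmax(rnorm(n, config$pa_mean, config$pa_sd), 0)
  energy <- pmax(rnorm(n, config$energy_kcal_mean, config$energy_kcal_sd), 800)
  fat <- pmax(config$fat_per_kcal * energy + rnorm(n, 0, config$fat_sd), 10)
  gest <- rnorm(n, config$gest_age_mean, config$gest_age_sd)

  cohort <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    pei_upf = pei,
    hei2010 = hei,
    age = age,
    race = factor(ifelse(race_aa == 1, "AfricanAmerican_other", "Caucasian"),
                  levels = c("Caucasian", "AfricanAmerican_other")),
    clinic = factor(ifelse(clinic_high == 1, "high_income", "low_income"),
                    levels = c("low_income", "high_income")),
    weight_status = factor(ws, levels = c("lean", "obese")),
    energy_kcal_per_day = energy,
    fat_g_per_day = fat,
    moderate_pa_pct = pa,
    gestational_age_at_measure = gest
  )

  # expected covariate values used to solve each model's intercept
  e_obese <- 1 - config$lean_fraction
  expectations <- c(
    pei_upf = config$pei_upf_mean,
    age = config$age_mean,
    "pei_upf:age" = config$pei_upf_mean * config$age_mean,
    obese = e_obese,
    "pei_upf:obese" = config$pei_upf_mean * e_obese,
    energy_kcal_per_day = config$energy_kcal_mean,
    fat_g_per_day = config$fat_per_kcal * config$energy_kcal_mean,
    race_aa = config$race_aa_prob,
    clinic_high = config$clinic_high_prob,
    moderate_pa_pct = config$pa_mean,
    gest_age = config$gest_age_mean
  )
  obese_ind <- as.numeric(cohort$weight_status == "obese")
  design <- cbind(
    pei_upf = cohort$pei_upf,
    age = cohort$age,
    "pei_upf:age" = cohort$pei_upf * cohort$age,
    obese = obese_ind,
    "pei_upf:obese" = cohort$pei_upf * obese_ind,
    energy_kcal_per_day = cohort$energy_kcal_per_day,
    fat_g_per_day = cohort$fat_g_per_day,
    race_aa = as.numeric(cohort$race == "AfricanAmerican_other"),
    clinic_high = as.numeric(cohort$clinic == "high_income"),
    moderate_pa_pct = cohort$moderate_pa_pct,
    gest_age = cohort$gestational_age_at_measure
  )
  for (oc in names(config$outcome_models)) {
    om <- config$outcome_models[[oc]]
    beta <- om$coef[colnames(design)]
    beta[is.na(beta)] <- 0
    intercept <- om$target_mean - sum(beta * expectations[colnames(design)])
    lp <- intercept + drop(design %*% beta)
    noise <- if (om$resid_sd > 0) rnorm(n, 0, om$resid_sd) else 0
    cohort[[oc]] <- lp + noise
  }
  cohort
}

#' Generate FFQ responses that realise assigned PEI-UPF targets
#'
#' For each subject, portion and condiment options are drawn at random and
#' the frequency options are then adjusted greedily — one option step at a
#' time, always taking the step that brings the implied ultra-processed
#' energy share closest to the subject's assigned `pei_upf` — until the
#' share is within `tol` of the target or no step improves it. The
#' complete table is finally masked completely at random at
#' `config$missing_rate` over the applicable answer cells.
#'
#' The implied share is computed with exactly the same arithmetic as
#' [score_intake()] (condiments riding on their main item's frequency,
#' energy recomputed from macronutrients), so scoring the unmasked table
#' reproduces `achieved` exactly.
#'
#' @param config A [cohort_config()].
#' @param instrument An `ffq_instrument`.
#' @param foods A `food_table` containing items in at least two NOVA
#'   groups.
#' @param cohort Optionally a cohort generated by [generate_cohort()]
#'   whose `pei_upf` column supplies the targets; generated from `config`
#'   when omitted.
#' @param tol Per-subject stopping tolerance on the energy-share
#'   percentage (default 0.25).
#' @return A list: `responses` (masked), `responses_complete` (unmasked),
#'   `targets` (tibble `subject_id`, `target`, `achieved`), and `cohort`.
#' @export
generate_responses <- function(config, instrument, foods, cohort = NULL,
                               tol = 0.25) {
  stopifnot(inherits(config, "cohort_config"))
  validate_food_table(foods)
  if (length(unique(foods$nova_group)) < 2) {
    abort("food list must span at least two NOVA groups.")
  }
  if (is.null(cohort)) cohort <- generate_cohort(config)
  set.seed(config$seed + 104729L) # distinct stream from generate_cohort

  dpm <- instrument$days_per_month
  mains <- foods %>% filter(.data$kind != "condiment")
  conds <- foods %>% filter(.data$kind == "condiment")

  n_opts <- function(kind) {
    if (kind == "beverage") nrow(instrument$beverage_frequency)
    else nrow(instrument$food_frequency)
  }
  tpm_list <- lapply(mains$kind, function(k) {
    if (k == "beverage") instrument$beverage_frequency$times_per_month
    else instrument$food_frequency$times_per_month
  })
  serv_mat <- function(tbl, opt) {
    cbind(tbl$serv_small_g, tbl$serv_med_g, tbl$serv_large_g)[
      cbind(seq_len(nrow(tbl)), opt)]
  }

  all_rows <- vector("list", nrow(cohort))
  targets <- numeric(nrow(cohort))
  achieved <- numeric(nrow(cohort))

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  for (si in seq_len(nrow(cohort))) {
    target <- cohort$pei_upf[si]
    # latent subject tendencies, mirroring real FFQ structure: a portion-size
    # (appetite) propensity shared across items and a condiment-use habit
    appetite <- rnorm(1)
    cond_habit <- rnorm(1)
    amount_main <- as.integer(clamp(round(2 + 0.8 * appetite +
                                            0.6 * rnorm(nrow(mains))), 1, 3))
    amount_cond <- as.integer(clamp(round(2 + 0.8 * appetite +
                                            0.6 * rnorm(nrow(conds))), 1, 3))
    n_frac <- nrow(instrument$condiment_fraction)
    frac_opt <- as.integer(clamp(round((n_frac + 1) / 2 + 1.2 * cond_habit +
                                         1.0 * rnorm(nrow(conds))), 1, n_frac))
    frac <- instrument$condiment_fraction$fraction[frac_opt]
    serv_m <- serv_mat(mains, amount_main)
    serv_c <- serv_mat(conds, amount_cond)

    # per main item and frequency option: total and group-4 energy/day,
    # condiment contributions folded into their main item
    e_per_tpm <- serv_m * mains$energy_MJ_per_100g / 100 / dpm
    e4_per_tpm <- e_per_tpm * (mains$nova_group == 4)
    if (nrow(conds) > 0) {
      ci <- match(conds$attached_to, mains$item_id)
      add <- frac * serv_c * conds$energy_MJ_per_100g / 100 / dpm
      for (k in seq_along(ci)) {
        e_per_tpm[ci[k]] <- e_per_tpm[ci[k]] + add[k]
        if (conds$nova_group[k] == 4) {
          e4_per_tpm[ci[k]] <- e4_per_tpm[ci[k]] + add[k]
        }
      }
    }
    opt_counts <- vapply(mains$kind, n_opts, integer(1))
    # starting frequencies reflect the subject's diet pattern: the further the
    # assigned ultra-processed share is above (below) the cohort centre, the
    # higher (lower) the group-4 item frequencies start, and conversely for
    # unprocessed items; the greedy pass below then fine-tunes the share
    pattern <- (target - config$pei_upf_mean) / max(config$pei_upf_sd, 1e-9)
    direction <- if_else(mains$nova_group == 4, 1, -1)
    k_cur <- as.integer(clamp(round(3 + 1.2 * pattern * direction +
                                      0.9 * rnorm(nrow(mains))),
                              1L, pmin(opt_counts, 7L)))
    tpm_cur <- mapply(function(tl, k) tl[k], tpm_list, k_cur)
    etot <- sum(e_per_tpm * tpm_cur)
    e4 <- sum(e4_per_tpm * tpm_cur)
    share <- function(et, e4v) if (et > 0) 100 * e4v / et else NA_real_

    for (step in seq_len(500L)) {
      s_now <- share(etot, e4)
      if (is.finite(s_now) && abs(s_now - target) <= tol) break
      best <- NULL
      for (dir in c(-1L, 1L)) {
        k_new <- k_cur + dir
        ok <- which(k_new >= 1L & k_new <= opt_counts)
        for (j in ok) {
          tpm_new <- tpm_list[[j]][k_new[j]]
          et <- etot + e_per_tpm[j] * (tpm_new - tpm_cur[j])
          e4n <- e4 + e4_per_tpm[j] * (tpm_new - tpm_cur[j])
          if (et <= 0) next
          gap <- abs(share(et, e4n) - target)
          if (is.null(best) || gap < best$gap) {
            best <- list(gap = gap, j = j, k = k_new[j], et = et, e4 = e4n)
          }
        }
      }
      if (is.null(best) || best$gap >= abs(s_now - target) - 1e-9) break
      j <- best$j
      k_cur[j] <- best$k
      tpm_cur[j] <- tpm_list[[j]][best$k]
      etot <- best$et
      e4 <- best$e4
    }
    targets[si] <- target
    achieved[si] <- share(etot, e4)
    if (abs(achieved[si] - target) > 2) {
      warn(sprintf(
        "subject %s: target share %.1f unreachable; best achieved %.1f.",
        cohort$subject_id[si], target, achieved[si]))
    }

    all_rows[[si]] <- bind_rows(
      tibble(subject_id = cohort$subject_id[si], item_id = mains$item_id,
             freq_opt = as.integer(k_cur), amount_opt = as.integer(amount_main),
             cond_frac_opt = NA_integer_),
      tibble(subject_id = cohort$subject_id[si], item_id = conds$item_id,
             freq_opt = NA_integer_, amount_opt = as.integer(amount_cond),
             cond_frac_opt = as.integer(frac_opt))
    )
  }

  complete <- bind_rows(all_rows)
  masked <- complete
  if (config$missing_rate > 0) {
    kind <- foods$kind[match(masked$item_id, foods$item_id)]
    maskable <- list(
      freq_opt = kind != "condiment",
      amount_opt = rep(TRUE, nrow(masked)),
      cond_frac_opt = kind == "condiment"
    )
    for (field in names(maskable)) {
      hit <- maskable[[field]] & runif(nrow(masked)) < config$missing_rate
      masked[[field]][hit] <- NA_integer_
    }
  }

  list(
    responses = masked,
    responses_complete = complete,
    targets = tibble(subject_id = cohort$subject_id, target = targets,
                     achieved = achieved),
    cohort = cohort
  )
}
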
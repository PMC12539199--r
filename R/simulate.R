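#' Simulation configuration for a synthetic triangulation study
#'
#' Defines the ground-truth mediation structure X -> M -> Y used by the
#' synthetic-study generator: an adiposity-like continuous exposure X
#' instrumented by independent SNPs, a panel of metabolite-like mediators M
#' (each with its own instruments, plus an effect `gamma` of X), and a binary
#' disease outcome D whose log-odds combine a direct exposure effect
#' `tau_direct`, per-mediator effects `delta`, and optional directional
#' pleiotropy on a fraction of the exposure instruments. All continuous traits
#' are standardized within each simulated panel, so `gamma` is in SD/SD units
#' and `delta`/`tau_direct` in log-odds per SD. The implied total effect is
#' `tau_direct + sum(gamma * delta)`.
#'
#' Panels (exposure, mediator, outcome, observational) are drawn from disjoint
#' random substreams of the master seed, emulating non-overlapping GWAS
#' samples.
#'
#' @param seed master seed; every substream (panel, catalogue, bootstrap) is
#'   derived deterministically from it.
#' @param n_samples_per_panel individuals per simulated panel (>= 500).
#' @param n_instruments_x number of exposure instruments.
#' @param n_instruments_per_m instruments per mediator.
#' @param n_mediators number of mediators (may be 0).
#' @param maf_range range of minor-allele frequencies, within (0.01, 0.5).
#' @param instrument_effect_scale typical per-allele effect in SD units; the
#'   default 0.07 gives per-SNP F-statistics near 40 at n = 20,000, the
#'   strength regime of well-powered adiposity/metabolite GWAS instruments.
#' @param gamma numeric vector (length `n_mediators`): effect of X on each
#'   mediator, SD/SD.
#' @param delta numeric vector (length `n_mediators`): effect of each mediator
#'   on the outcome log-odds, per SD.
#' @param tau_direct direct exposure effect on the outcome log-odds, per SD.
#' @param invalid_fraction fraction of exposure instruments given a direct
#'   (horizontally pleiotropic) outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd normal distribution of the per-allele
#'   pleiotropic log-odds effects of invalid instruments.
#' @param baseline_prevalence target outcome prevalence; the intercept is
#'   solved so the mean simulated risk matches it.
#' @param confounding_strength effect of a shared latent confounder on X, M
#'   (and the outcome log-odds), creating observational-but-not-genetic
#'   confounding.
#' @param include_subtypes also generate two outcome-subtype GWAS panels with
#'   scaled effects (see `subtype_tau_scale`).
#' @param subtype_tau_scale length-2 multiplier applied to `tau_direct` and
#'   `delta` for the endometrioid / non-endometrioid subtype panels.
#' @param include_observational generate the individual-level cohort arm.
#' @param lowpower_n optional size of an additional, lower-powered exposure
#'   panel (used in multivariable MR to protect mediator instrument strength);
#'   `NULL` to skip.
#' @param ld_block_r2 optional r-squared for a synthetic LD-block mode that
#'   duplicates each exposure instrument with a correlated twin variant (and
#'   emits an LD table), giving clumping a real test surface; `NULL` for
#'   mutually independent instruments.
#' @param palindromic_fraction fraction of variants assigned strand-ambiguous
#'   (A/T or G/C) allele pairs, to exercise harmonization policies.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples_per_panel = 20000L,
                       n_instruments_x = 50L,
                       n_instruments_per_m = 10L,
                       n_mediators = 2L,
                       maf_range = c(0.05, 0.45),
                       instrument_effect_scale = 0.07,
                       gamma = c(0.3, 0.2),
                       delta = c(0.5, 0.1),
                       tau_direct = 0.1,
                       invalid_fraction = 0,
                       pleiotropy_mean = 0.04,
                       pleiotropy_sd = 0.02,
                       baseline_prevalence = 0.05,
                       confounding_strength = 0.3,
                       include_subtypes = FALSE,
                       subtype_tau_scale = c(endometrioid = 0.95,
                                             non_endometrioid = 1.25),
                       include_observational = FALSE,
                       lowpower_n = NULL,
                       ld_block_r2 = NULL,
                       palindromic_fraction = 0) {
  cfg <- list(seed = as.integer(seed),
              n_samples_per_panel = as.integer(n_samples_per_panel),
              n_instruments_x = as.integer(n_instruments_x),
              n_instruments_per_m = as.integer(n_instruments_per_m),
              n_mediators = as.integer(n_mediators),
              maf_range = as.numeric(maf_range),
              instrument_effect_scale = instrument_effect_scale,
              gamma = as.numeric(gamma), delta = as.numeric(delta),
              tau_direct = tau_direct,
              invalid_fraction = invalid_fraction,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              baseline_prevalence = baseline_prevalence,
              confounding_strength = confounding_strength,
              include_subtypes = isTRUE(include_subtypes),
              subtype_tau_scale = subtype_tau_scale,
              include_observational = isTRUE(include_observational),
              lowpower_n = if (is.null(lowpower_n)) NULL else as.integer(lowpower_n),
              ld_block_r2 = ld_block_r2,
              palindromic_fraction = palindromic_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_field(field, "must be a single finite number")
    v
  }
  for (f in c("tau_direct", "instrument_effect_scale", "pleiotropy_mean",
              "pleiotropy_sd", "confounding_strength")) num1(f)
  for (f in c("invalid_fraction", "palindromic_fraction")) {
    v <- num1(f)
    if (v < 0 || v > 1) stop_field(f, "must lie in [0, 1]")
  }
  if (num1("baseline_prevalence") <= 0 || cfg$baseline_prevalence >= 1)
    stop_field("baseline_prevalence", "must lie in (0, 1)")
  if (cfg$n_samples_per_panel < 500L)
    stop_field("n_samples_per_panel", "must be at least 500")
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] >= mr[2] ||
      mr[1] <= 0.01 || mr[2] >= 0.5)
    stop_field("maf_range", "must be an increasing pair within (0.01, 0.5)")
  if (length(cfg$gamma) != cfg$n_mediators)
    stop_field("gamma", "length must equal n_mediators")
  if (length(cfg$delta) != cfg$n_mediators)
    stop_field("delta", "length must equal n_mediators")
  if (any(!is.finite(cfg$gamma)) || any(!is.finite(cfg$delta)))
    stop_field("gamma/delta", "must be finite")
  if (!is.null(cfg$ld_block_r2) &&
      (cfg$ld_block_r2 <= 0 || cfg$ld_block_r2 >= 1))
    stop_field("ld_block_r2", "must lie in (0, 1) or be NULL")
  invisible(cfg)
}

# Non-palindromic allele pairs (palindromic = A/T or C/G).
.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"),
                       c("G", "A"), c("C", "A"), c("T", "G"), c("T", "C"))
.palindromic_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# Variant-level layout: ids, alleles, MAFs, per-allele effects, pleiotropy
# assignment. Drawn once from the master seed so every panel sees the same
# variants; genotype draws then use per-panel substreams.
study_layout <- function(config) {
  with_seed(derive_seed(config$seed, "layout"), {
    jx <- config$n_instruments_x
    jm <- config$n_instruments_per_m * config$n_mediators
    j <- jx + jm
    role <- c(rep("exposure", jx),
              if (config$n_mediators > 0)
                rep(sprintf("met_%02d", seq_len(config$n_mediators)),
                    each = config$n_instruments_per_m))
    ids <- sprintf("rs%05d", seq_len(j))
    maf <- stats::runif(j, config$maf_range[1], config$maf_range[2])
    pal <- stats::runif(j) < config$palindromic_fraction
    pick <- function(palindromic) {
      pool <- if (palindromic) .palindromic_pairs else .allele_pairs
      pool[sample.int(nrow(pool), 1L), ]
    }
    alleles <- t(vapply(pal, pick, character(2)))
    # per-allele effects of each variant on its own trait, positive by
    # construction (effect allele = trait-increasing allele)
    a <- config$instrument_effect_scale * stats::runif(j, 0.5, 1.5)
    n_invalid <- round(config$invalid_fraction * jx)
    invalid_idx <- if (n_invalid > 0) sort(sample.int(jx, n_invalid)) else integer(0)
    pleio <- numeric(j)
    if (n_invalid > 0)
      pleio[invalid_idx] <- stats::rnorm(n_invalid, config$pleiotropy_mean,
                                         config$pleiotropy_sd)
    variants <- data.frame(variant_id = ids,
                           effect_allele = alleles[, 1],
                           other_allele = alleles[, 2],
                           maf = maf, role = role, allele_effect = a,
                           pleiotropy = pleio,
                           stringsAsFactors = FALSE)
    ld <- NULL
    if (!is.null(config$ld_block_r2)) {
      twin <- variants[variants$role == "exposure", ]
      twin$variant_id <- paste0(twin$variant_id, "b")
      twin$allele_effect <- 0
      twin$pleiotropy <- 0
      twin$role <- "exposure_ld_twin"
      ld <- data.frame(id_a = variants$variant_id[variants$role == "exposure"],
                       id_b = twin$variant_id,
                       r2 = config$ld_block_r2, stringsAsFactors = FALSE)
      variants <- rbind(variants, twin)
    }
    list(variants = variants, ld = ld, invalid_idx = invalid_idx)
  })
}

#' Ground truth of a simulation configuration
#'
#' Returns the planted effect sizes the pipeline is built to recover:
#' per-instrument allele effects, `gamma`, `delta`, `tau_direct`, the implied
#' total effect `tau_total = tau_direct + sum(gamma * delta)` and the
#' per-instrument pleiotropy terms.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(config) {
  layout <- study_layout(config)
  v <- layout$variants
  xv <- v[v$role == "exposure", ]
  med_ids <- if (config$n_mediators > 0)
    sprintf("met_%02d", seq_len(config$n_mediators)) else character(0)
  structure(list(
    instrument_effects = stats::setNames(xv$allele_effect, xv$variant_id),
    mediator_instrument_effects = lapply(
      stats::setNames(med_ids, med_ids),
      function(m) {
        mv <- v[v$role == m, ]
        stats::setNames(mv$allele_effect, mv$variant_id)
      }),
    gamma = config$gamma, delta = config$delta,
    tau_direct = config$tau_direct,
    tau_total = config$tau_direct + sum(config$gamma * config$delta),
    pleiotropy = stats::setNames(xv$pleiotropy, xv$variant_id),
    invalid_instruments = xv$variant_id[layout$invalid_idx]
  ), class = "synthetic_truth")
}

# Draw a genotype matrix for one panel; twins (synthetic LD mode) copy their
# primary variant for a fraction sqrt(r2) of individuals so cor(G, twin) ~ r.
draw_genotypes <- function(n, layout) {
  v <- layout$variants
  primary <- v$role != "exposure_ld_twin"
  G <- matrix(stats::rbinom(n * sum(primary), 2L,
                            rep(v$maf[primary], each = n)),
              nrow = n, dimnames = list(NULL, v$variant_id[primary]))
  if (any(!primary)) {
    f <- sqrt(layout$ld$r2)
    Gt <- matrix(0L, n, nrow(layout$ld),
                 dimnames = list(NULL, layout$ld$id_b))
    for (k in seq_len(nrow(layout$ld))) {
      src <- G[, layout$ld$id_a[k]]
      fresh <- stats::rbinom(n, 2L, v$maf[match(layout$ld$id_b[k], v$variant_id)])
      keep <- stats::runif(n) < f[k]
      Gt[, k] <- ifelse(keep, src, fresh)
    }
    G <- cbind(G, Gt)[, v$variant_id, drop = FALSE]
  }
  G
}

#' Simulate one individual-level panel
#'
#' Draws genotypes, builds the exposure, mediators and binary outcome under
#' the configured mediation structure, and (for the observational panel)
#' attaches covariates and cancer-registry-style age fields. The outcome
#' intercept is solved by root finding so the realized mean risk matches
#' `baseline_prevalence`.
#'
#' @param config a [sim_config()].
#' @param panel one of `"exposure"`, `"exposure_lowpower"`, `"mediator"`,
#'   `"outcome"`, `"outcome_endometrioid"`, `"outcome_nonendometrioid"`,
#'   `"observational"`. Each panel uses its own random substream, so panels
#'   emulate disjoint samples.
#' @return a list of class `sim_cohort` with elements `G` (genotype matrix,
#'   0/1/2), `traits` (data frame of measured traits), `variants`, `panel`,
#'   `n`.
#' @export
simulate_cohort <- function(config, panel = c("exposure", "exposure_lowpower",
                                              "mediator", "outcome",
                                              "outcome_endometrioid",
                                              "outcome_nonendometrioid",
                                              "observational")) {
  panel <- match.arg(panel)
  validate_sim_config(config)
  layout <- study_layout(config)
  v <- layout$variants
  n <- if (panel == "exposure_lowpower") {
    if (is.null(config$lowpower_n))
      stop("lowpower_n must be set to simulate the low-powered exposure panel")
    config$lowpower_n
  } else config$n_samples_per_panel

  tau_scale <- switch(panel,
                      outcome_endometrioid = config$subtype_tau_scale[[1]],
                      outcome_nonendometrioid = config$subtype_tau_scale[[2]],
                      1)

  with_seed(derive_seed(config$seed, paste0("panel_", panel)), {
    G <- draw_genotypes(n, layout)
    conf <- stats::rnorm(n)
    cs <- config$confounding_strength

    xidx <- which(v$role == "exposure")
    a <- v$allele_effect[xidx]
    var_gx <- sum(a^2 * 2 * v$maf[xidx] * (1 - v$maf[xidx]))
    x_noise_sd <- sqrt(max(0.05, 1 - var_gx - cs^2))
    x_lat <- drop(G[, xidx, drop = FALSE] %*% a) + cs * conf +
      stats::rnorm(n, 0, x_noise_sd)
    X <- as.numeric(scale(x_lat))

    M <- NULL
    if (config$n_mediators > 0) {
      M <- matrix(0, n, config$n_mediators,
                  dimnames = list(NULL, sprintf("met_%02d",
                                                seq_len(config$n_mediators))))
      for (m in seq_len(config$n_mediators)) {
        midx <- which(v$role == sprintf("met_%02d", m))
        b <- v$allele_effect[midx]
        var_gm <- sum(b^2 * 2 * v$maf[midx] * (1 - v$maf[midx]))
        m_noise_sd <- sqrt(max(0.05, 1 - config$gamma[m]^2 - var_gm -
                                 (0.5 * cs)^2))
        m_lat <- config$gamma[m] * X + drop(G[, midx, drop = FALSE] %*% b) +
          0.5 * cs * conf + stats::rnorm(n, 0, m_noise_sd)
        M[, m] <- as.numeric(scale(m_lat))
      }
    }

    age <- pmin(70, pmax(40, round(stats::rnorm(n, 56.5, 8))))
    lp <- tau_scale * config$tau_direct * X + 0.6 * cs * conf
    if (config$n_mediators > 0)
      lp <- lp + drop(M %*% (tau_scale * config$delta))
    if (any(v$pleiotropy != 0))
      lp <- lp + drop(G[, which(v$pleiotropy != 0), drop = FALSE] %*%
                        v$pleiotropy[v$pleiotropy != 0])
    if (panel == "observational") lp <- lp + 0.04 * (age - 56)

    f <- function(alpha) mean(stats::plogis(alpha + lp)) -
      config$baseline_prevalence
    if (f(-40) > 0 || f(40) < 0)
      stop("prevalence solver failed to bracket the outcome intercept")
    a0 <- stats::qlogis(config$baseline_prevalence)
    alpha <- stats::uniroot(f, c(a0 - 8, a0 + 8), extendInt = "yes",
                            tol = 1e-6)$root
    D <- stats::rbinom(n, 1L, stats::plogis(alpha + lp))

    outcome_name <- switch(panel,
                           outcome = "cancer_overall",
                           outcome_endometrioid = "cancer_endometrioid",
                           outcome_nonendometrioid = "cancer_nonendometrioid",
                           "cancer_overall")
    traits <- data.frame(adiposity = X)
    if (!is.null(M)) traits <- cbind(traits, as.data.frame(M))
    traits[[outcome_name]] <- D

    cohort <- list(G = G, traits = traits, variants = v, panel = panel, n = n)

    if (panel == "observational") {
      obs <- data.frame(adiposity_raw = 27 + 5.2 * X,
                        age = age,
                        centre = sample(sprintf("centre_%02d", 1:10), n,
                                        replace = TRUE),
                        smoking = sample(c("never", "former", "current"), n,
                                         replace = TRUE, prob = c(.55, .3, .15)),
                        alcohol = sample(c("rarely", "weekly", "daily"), n,
                                         replace = TRUE),
                        education = sample(c("basic", "secondary", "degree"),
                                           n, replace = TRUE),
                        activity_met = pmax(0, stats::rnorm(n, 25, 12) - 2 * X),
                        hrt = stats::rbinom(n, 1, 0.3),
                        menopause = as.integer(age >= 50 |
                                                 stats::runif(n) < 0.1),
                        age_menarche = round(stats::rnorm(n, 13, 1.5), 1),
                        age_first_birth = round(stats::rnorm(n, 26, 4), 1),
                        stringsAsFactors = FALSE)
      if (!is.null(M)) {
        raw <- sweep(sweep(M, 2, 0.4, "*"), 2, 1.5, "+")
        colnames(raw) <- paste0(colnames(M), "_raw")
        obs <- cbind(obs, as.data.frame(raw))
      }
      obs$case <- D
      obs$age_at_diagnosis <- NA_real_
      is_case <- D == 1L
      obs$age_at_diagnosis[is_case] <-
        obs$age[is_case] + sample(-5:10, sum(is_case), replace = TRUE)
      cohort$observational <- obs
    }
    structure(cohort, class = "sim_cohort")
  })
}

#' Per-variant GWAS summary statistics from a simulated panel
#'
#' Runs one simple regression of the trait on each variant's allele dosage:
#' ordinary least squares for continuous traits, maximum-likelihood logistic
#' regression (log-odds scale) for binary traits. P-values use the
#' large-sample normal approximation. Monomorphic variants are emitted with
#' `beta = 0`, `se = Inf` so downstream selection excludes them.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param trait column name in `cohort$traits`.
#' @return a data frame of summary statistics with the canonical columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, `trait_id`. The effect allele is the counted (dosage)
#'   allele.
#' @export
compute_sumstats <- function(cohort, trait) {
  if (!trait %in% names(cohort$traits))
    stop(sprintf("trait '%s' not measured in panel '%s'", trait, cohort$panel))
  y <- cohort$traits[[trait]]
  G <- cohort$G
  n <- cohort$n
  binary <- all(y %in% c(0, 1))
  if (binary && (sum(y) == 0 || sum(y) == n))
    stop("binary trait has a single class; cannot fit per-variant logistic models")

  if (binary) {
    fit <- logistic_sumstats(G, y)
  } else {
    gbar <- colMeans(G)
    sxx <- colSums(G^2) - n * gbar^2
    ybar <- mean(y)
    sxy <- drop(crossprod(G, y)) - n * gbar * ybar
    syy <- sum(y^2) - n * ybar^2
    beta <- ifelse(sxx > 0, sxy / sxx, 0)
    sse <- pmax(0, syy - beta * sxy)
    se <- ifelse(sxx > 0, sqrt(sse / (n - 2) / sxx), Inf)
    fit <- list(beta = beta, se = se)
  }
  pval <- ifelse(is.finite(fit$se) & fit$se > 0,
                 norm_pval(fit$beta / fit$se), 1)
  v <- cohort$variants
  data.frame(variant_id = v$variant_id,
             effect_allele = v$effect_allele,
             other_allele = v$other_allele,
             eaf = colMeans(G) / 2,
             beta = unname(fit$beta), se = unname(fit$se),
             pval = unname(pval), n = n, trait_id = trait,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-variant logistic regression (intercept + dosage), Newton iteration
# vectorized across variants. With 0/1/2 dosages the per-variant likelihood
# depends only on the genotype counts and per-genotype case counts, so the
# exact MLE is computed from those sufficient statistics. Monomorphic
# columns get beta = 0, se = Inf.
logistic_sumstats <- function(G, y, tol = 1e-10, maxit = 50L) {
  n <- length(y)
  n1 <- colSums(G == 1L); n2 <- colSums(G == 2L)
  n0 <- n - n1 - n2
  Gc <- G[y == 1, , drop = FALSE]
  c1 <- colSums(Gc == 1L); c2 <- colSums(Gc == 2L)
  c0 <- nrow(Gc) - c1 - c2
  ng <- cbind(n0, n1, n2)          # J x 3 genotype counts
  cg <- cbind(c0, c1, c2)          # J x 3 case counts
  g <- c(0, 1, 2)
  mono <- rowSums(ng > 0) < 2
  b0 <- rep(stats::qlogis(mean(y)), ncol(G))
  b1 <- numeric(ncol(G))
  i00 <- i01 <- i11 <- rep(NA_real_, ncol(G))
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(outer(b0, rep(1, 3)) + outer(b1, g))
    w <- ng * mu * (1 - mu)
    r <- cg - ng * mu
    u0 <- rowSums(r)
    u1 <- rowSums(r * rep(g, each = nrow(r)))
    i00 <- rowSums(w)
    i01 <- rowSums(w * rep(g, each = nrow(w)))
    i11 <- rowSums(w * rep(g^2, each = nrow(w)))
    det <- i00 * i11 - i01^2
    d0 <- (i11 * u0 - i01 * u1) / det
    d1 <- (i00 * u1 - i01 * u0) / det
    d0[mono | !is.finite(d0)] <- 0
    d1[mono | !is.finite(d1)] <- 0
    b0 <- b0 + d0; b1 <- b1 + d1
    if (max(abs(c(d0, d1))) < tol) break
  }
  mu <- stats::plogis(outer(b0, rep(1, 3)) + outer(b1, g))
  w <- ng * mu * (1 - mu)
  det <- rowSums(w) * rowSums(w * rep(g^2, each = nrow(w))) -
    rowSums(w * rep(g, each = nrow(w)))^2
  se <- sqrt(rowSums(w) / det)
  b1[mono] <- 0
  se[mono | !is.finite(se)] <- Inf
  list(beta = b1, se = se)
}

#' Generate a complete synthetic triangulation study
#'
#' Simulates disjoint panels, reduces them to GWAS summary statistics, and
#' bundles them with the observational cohort (if configured), the LD table
#' (synthetic LD mode) and the ground truth.
#'
#' @param config a [sim_config()].
#' @return an object of class `mr_study` with elements:
#'   `exposure` (exposure summary statistics), `exposure_lowpower` (optional),
#'   `mediators` (one summary-statistics data frame, stacked over mediators,
#'   or `NULL`), `outcomes` (named list: `cancer_overall` plus subtypes when
#'   configured), `observational` (cohort data frame or `NULL`), `ld`
#'   (LD table or `NULL`), `truth` ([synthetic_truth()]), `config`.
#' @export
generate_study <- function(config) {
  validate_sim_config(config)
  exposure <- compute_sumstats(simulate_cohort(config, "exposure"), "adiposity")
  exposure_lowpower <- NULL
  if (!is.null(config$lowpower_n))
    exposure_lowpower <- compute_sumstats(
      simulate_cohort(config, "exposure_lowpower"), "adiposity")

  mediators <- NULL
  if (config$n_mediators > 0) {
    med_cohort <- simulate_cohort(config, "mediator")
    mediators <- do.call(rbind, lapply(
      sprintf("met_%02d", seq_len(config$n_mediators)),
      function(m) compute_sumstats(med_cohort, m)))
  }

  outcomes <- list(cancer_overall = compute_sumstats(
    simulate_cohort(config, "outcome"), "cancer_overall"))
  if (config$include_subtypes) {
    outcomes$cancer_endometrioid <- compute_sumstats(
      simulate_cohort(config, "outcome_endometrioid"), "cancer_endometrioid")
    outcomes$cancer_nonendometrioid <- compute_sumstats(
      simulate_cohort(config, "outcome_nonendometrioid"),
      "cancer_nonendometrioid")
  }

  observational <- NULL
  if (config$include_observational)
    observational <- simulate_cohort(config, "observational")$observational

  layout <- study_layout(config)
  structure(list(exposure = exposure,
                 exposure_lowpower = exposure_lowpower,
                 mediators = mediators,
                 outcomes = outcomes,
                 observational = observational,
                 ld = layout$ld,
                 truth = synthetic_truth(config),
                 config = config),
            class = "mr_study")
}

#' @export
print.mr_study <- function(x, ...) {
  cat("Synthetic triangulation study\n")
  cat(sprintf("  exposure instruments: %d (+%d mediator instruments)\n",
              x$config$n_instruments_x,
              x$config$n_instruments_per_m * x$config$n_mediators))
  cat(sprintf("  mediators: %d; outcomes: %s\n", x$config$n_mediators,
              paste(names(x$outcomes), collapse = ", ")))
  cat(sprintf("  truth: tau_direct = %.3f, tau_total = %.3f\n",
              x$truth$tau_direct, x$truth$tau_total))
  invisible(x)
}

# Trait-domain dictionary for the synthetic phenome catalogue.
phenome_domains <- list(
  anthropometric = c("height", "body fat percentage", "birth weight"),
  "blood cell" = c("red blood cell count", "platelet count",
                   "lymphocyte count", "mean corpuscular volume"),
  lipid = c("LDL cholesterol", "HDL cholesterol", "triglycerides",
            "apolipoprotein B"),
  glycaemic = c("fasting insulin", "HbA1c", "type 2 diabetes"),
  inflammatory = c("C-reactive protein", "white blood cell count"),
  cardiovascular = c("systolic blood pressure", "coronary artery disease"),
  renal = c("creatinine", "urate"))

#' Generate a synthetic phenome catalogue
#'
#' Builds a PhenoScanner-like lookup table of (variant, trait, domain,
#' p-value) rows: background associations appear for each variant-trait pair
#' independently with probability `bg_rate` (log-uniform p-values, so a share
#' fall below typical lookup thresholds), and — optionally — every instrument
#' of the named mediators is planted with a very strong association
#' (p well below 1e-10) to a chosen trait, emulating genuinely shared genetic
#' architecture.
#'
#' @param study an [generate_study()] bundle (supplies the variant roster and
#'   the master seed).
#' @param planted_mediators character vector of mediator ids (e.g. "met_01")
#'   whose instruments receive the planted association; empty for a pure
#'   background (exchangeable-null) catalogue.
#' @param planted_trait trait name receiving planted associations.
#' @param bg_rate per variant-trait background inclusion probability.
#' @param seed substream seed; defaults to one derived from the study seed.
#' @return data frame with columns `variant_id`, `trait`, `domain`, `pval`.
#' @export
generate_catalogue <- function(study, planted_mediators = character(),
                               planted_trait = "fasting insulin",
                               bg_rate = 0.25, seed = NULL) {
  layout <- study_layout(study$config)
  v <- layout$variants
  traits <- data.frame(
    trait = unlist(phenome_domains, use.names = FALSE),
    domain = rep(names(phenome_domains), lengths(phenome_domains)),
    stringsAsFactors = FALSE)
  seed <- seed %||% derive_seed(study$config$seed, "catalogue")
  with_seed(seed, {
    grid <- expand.grid(variant_id = v$variant_id, trait_row = seq_len(nrow(traits)),
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < bg_rate
    bg <- grid[keep, , drop = FALSE]
    cat_df <- data.frame(variant_id = bg$variant_id,
                         trait = traits$trait[bg$trait_row],
                         domain = traits$domain[bg$trait_row],
                         pval = 10^-stats::runif(nrow(bg), 4, 30),
                         stringsAsFactors = FALSE)
    if (length(planted_mediators) > 0) {
      bad <- setdiff(planted_mediators, v$role)
      if (length(bad) > 0)
        stop("unknown mediators in planted_mediators: ",
             paste(bad, collapse = ", "))
      pv <- v$variant_id[v$role %in% planted_mediators]
      dom <- traits$domain[match(planted_trait, traits$trait)]
      if (is.na(dom)) dom <- "other"
      planted <- data.frame(variant_id = pv, trait = planted_trait,
                            domain = dom,
                            pval = 10^-stats::runif(length(pv), 25, 35),
                            stringsAsFactors = FALSE)
      cat_df <- cat_df[!(cat_df$variant_id %in% pv &
                           cat_df$trait == planted_trait), , drop = FALSE]
      cat_df <- rbind(cat_df, planted)
    }
    rownames(cat_df) <- NULL
    cat_df
  })
}

#' Instrument variant ids of a simulated trait (from ground truth)
#'
#' @param study an `mr_study` bundle.
#' @param trait `"adiposity"` or a mediator id such as `"met_01"`.
#' @return character vector of variant ids.
#' @export
study_instruments <- function(study, trait) {
  layout <- study_layout(study$config)
  role <- if (trait == "adiposity") "exposure" else trait
  ids <- layout$variants$variant_id[layout$variants$role == role]
  if (length(ids) == 0) stop("unknown trait: ", trait)
  ids
}
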
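test_that("configuration invariants are enforced with named fields", {
  expect_error(sim_config(n_samples_per_panel = 100), "n_samples_per_panel")
  expect_error(sim_config(maf_range = c(0.005, 0.4)), "maf_range")
  expect_error(sim_config(gamma = c(0.1), delta = c(0.5, 0.1)), "gamma")
  expect_error(sim_config(invalid_fraction = 1.2), "invalid_fraction")
  expect_error(sim_config(baseline_prevalence = 0), "baseline_prevalence")
})

test_that("ground-truth bookkeeping is exact", {
  cfg <- sim_config(seed = 1, n_mediators = 2, gamma = c(0.3, 0.2),
                    delta = c(0.5, 0.1), tau_direct = 0.1,
                    n_samples_per_panel = 600, n_instruments_x = 5,
                    n_instruments_per_m = 3)
  tr <- synthetic_truth(cfg)
  expect_identical(tr$tau_total, 0.1 + 0.3 * 0.5 + 0.2 * 0.1)
  # identity holds exactly for arbitrary vectors
  set.seed(4)
  g <- rnorm(5); d <- rnorm(5); td <- rnorm(1)
  cfg2 <- sim_config(seed = 2, n_mediators = 5, gamma = g, delta = d,
                     tau_direct = td, n_samples_per_panel = 600,
                     n_instruments_x = 4, n_instruments_per_m = 2)
  expect_identical(synthetic_truth(cfg2)$tau_total, td + sum(g * d))
})

test_that("panels are deterministic per seed and disjoint across panels", {
  cfg <- sim_config(seed = 5, n_samples_per_panel = 600,
                    n_instruments_x = 6, n_instruments_per_m = 3)
  a <- simulate_cohort(cfg, "exposure")
  b <- simulate_cohort(cfg, "exposure")
  expect_identical(a$G, b$G)
  expect_identical(a$traits, b$traits)
  c <- simulate_cohort(cfg, "outcome")
  expect_false(identical(a$G, c$G))
  # a different master seed changes draws but not the schema
  cfg2 <- sim_config(seed = 6, n_samples_per_panel = 600,
                     n_instruments_x = 6, n_instruments_per_m = 3)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg2)
  expect_false(isTRUE(all.equal(st1$exposure$beta, st2$exposure$beta)))
  expect_identical(names(st1$exposure), names(st2$exposure))
})

test_that("invalid-instrument bookkeeping is exact", {
  cfg <- sim_config(seed = 9, invalid_fraction = 0.3, n_instruments_x = 10,
                    n_samples_per_panel = 600, n_mediators = 0,
                    gamma = numeric(0), delta = numeric(0))
  tr <- synthetic_truth(cfg)
  expect_equal(length(tr$invalid_instruments), round(0.3 * 10))
  expect_equal(sum(tr$pleiotropy != 0), 3)
})

test_that("per-variant regressions recover planted allele effects at n = 50,000", {
  cfg <- sim_config(seed = 13, n_samples_per_panel = 50000,
                    n_instruments_x = 5, n_mediators = 0,
                    gamma = numeric(0), delta = numeric(0), tau_direct = 0)
  co <- simulate_cohort(cfg, "exposure")
  ss <- compute_sumstats(co, "adiposity")
  a <- synthetic_truth(cfg)$instrument_effects
  for (j in seq_along(a)) {
    row <- ss[ss$variant_id == names(a)[j], ]
    expect_lt(abs(row$beta - a[[j]]), 4 * row$se)
  }
})

test_that("summary statistics are invariant to individual ordering", {
  cfg <- sim_config(seed = 21, n_samples_per_panel = 800,
                    n_instruments_x = 6, n_instruments_per_m = 3)
  co <- simulate_cohort(cfg, "outcome")
  ss1 <- compute_sumstats(co, "cancer_overall")
  perm <- sample(co$n)
  co2 <- co
  co2$G <- co$G[perm, , drop = FALSE]
  co2$traits <- co$traits[perm, , drop = FALSE]
  ss2 <- compute_sumstats(co2, "cancer_overall")
  expect_equal(ss1$beta, ss2$beta, tolerance = 1e-9)
  expect_equal(ss1$se, ss2$se, tolerance = 1e-9)
})

test_that("degenerate traits and variants are handled explicitly", {
  cfg <- sim_config(seed = 22, n_samples_per_panel = 600,
                    n_instruments_x = 4, n_mediators = 0,
                    gamma = numeric(0), delta = numeric(0))
  co <- simulate_cohort(cfg, "outcome")
  co$traits$cancer_overall <- 0L
  expect_error(compute_sumstats(co, "cancer_overall"), "single class")
  co2 <- simulate_cohort(cfg, "exposure")
  co2$G[, 2] <- 1L   # monomorphic
  ss <- compute_sumstats(co2, "adiposity")
  expect_equal(ss$beta[2], 0)
  expect_equal(ss$se[2], Inf)
  expect_equal(ss$pval[2], 1)
  # monomorphic variants are excluded by selection
  sel <- suppressWarnings(select_instruments(ss, 1))
  expect_false(ss$variant_id[2] %in% sel$variants$variant_id)
})

test_that("a global-null cohort shows no exposure-outcome association at n = 20,000", {
  cfg <- sim_config(seed = 31, n_samples_per_panel = 20000,
                    n_instruments_x = 10, n_mediators = 0,
                    gamma = numeric(0), delta = numeric(0), tau_direct = 0,
                    confounding_strength = 0)
  co <- simulate_cohort(cfg, "outcome")
  res <- fit_logistic(co$traits$cancer_overall, co$traits$adiposity)
  expect_lt(abs(res$estimate), 3 * res$se)
  # prevalence close to target
  expect_lt(abs(mean(co$traits$cancer_overall) - 0.05), 0.01)
})

test_that("the mediation structure propagates planted effects into GWAS betas", {
  cfg <- quick_config(seed = 41, n_samples_per_panel = 20000)
  st <- generate_study(cfg)
  tr <- st$truth
  # exposure instruments associate with the mediator through gamma * a
  x_ids <- names(tr$instrument_effects)
  med <- st$mediators[match(x_ids, st$mediators$variant_id), ]
  fit <- lm(med$beta ~ unname(tr$instrument_effects) - 1)
  expect_lt(abs(unname(coef(fit)) - cfg$gamma), 0.1)
  # mediator instruments associate with the outcome through delta * b
  m_ids <- names(tr$mediator_instrument_effects$met_01)
  oc <- st$outcomes$cancer_overall[match(m_ids,
                                         st$outcomes$cancer_overall$variant_id), ]
  fit2 <- lm(oc$beta ~ unname(tr$mediator_instrument_effects$met_01) - 1)
  expect_lt(abs(unname(coef(fit2)) - cfg$delta), 0.25)
})

test_that("study bundles round-trip through plain-text files", {
  cfg <- quick_config(seed = 51, n_samples_per_panel = 1000,
                      include_observational = TRUE, include_subtypes = TRUE)
  st <- generate_study(cfg)
  dir <- tempfile()
  write_study(st, dir)
  back <- load_study(dir)
  expect_equal(back$exposure$beta, st$exposure$beta, tolerance = 1e-12)
  expect_equal(back$mediators$pval, st$mediators$pval, tolerance = 1e-12)
  expect_setequal(names(back$outcomes), names(st$outcomes))
  expect_identical(names(back$outcomes)[1], "cancer_overall")
  expect_equal(nrow(back$observational), nrow(st$observational))
  expect_equal(back$truth$tau_total, st$truth$tau_total)
})

test_that("synthetic LD blocks give clumping a real surface", {
  cfg <- quick_config(seed = 61, n_samples_per_panel = 4000,
                      n_mediators = 0, gamma = numeric(0),
                      delta = numeric(0), ld_block_r2 = 0.6)
  st <- generate_study(cfg)
  expect_equal(nrow(st$ld), cfg$n_instruments_x)
  sel <- select_instruments(st$exposure, 1e-4, ld_info = st$ld,
                            r2_threshold = 0.001)
  # at most one variant per LD pair survives
  for (i in seq_len(nrow(st$ld)))
    expect_lt(sum(c(st$ld$id_a[i], st$ld$id_b[i]) %in%
                    sel$variants$variant_id), 2)
  # twins really are correlated in the genotypes
  co <- simulate_cohort(cfg, "exposure")
  r <- cor(co$G[, st$ld$id_a[1]], co$G[, st$ld$id_b[1]])
  expect_gt(r^2, 0.3)
})

test_that("catalogue planting is complete and background-only catalogues are clean", {
  cfg <- quick_config(seed = 71, n_samples_per_panel = 600, n_mediators = 2,
                      gamma = c(0.3, 0.2), delta = c(0.5, 0.1),
                      n_instruments_per_m = 4)
  st <- generate_study(cfg)
  bg <- generate_catalogue(st, planted_mediators = character())
  expect_setequal(names(bg), c("variant_id", "trait", "domain", "pval"))
  planted <- generate_catalogue(st, planted_mediators = "met_01",
                                planted_trait = "fasting insulin")
  for (v in study_instruments(st, "met_01")) {
    rows <- planted[planted$variant_id == v & planted$trait == "fasting insulin", ]
    expect_true(any(rows$pval < 1e-10))
  }
  # (variant, trait) pairs unique
  expect_false(any(duplicated(planted[, c("variant_id", "trait")])))
  expect_error(generate_catalogue(st, planted_mediators = "met_99"),
               "unknown mediators")
})
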
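test_that("Wald ratio is by/bx with first-order delta SE and rejects bx = 0", {
  e <- wald_ratio(bx = 0.1, bx_se = 0.01, by = 0.05, by_se = 0.02)
  expect_equal(e$theta, 0.5)
  expect_equal(e$se, 0.2)
  expect_equal(e$method, "wald")
  expect_equal(wald_ratio(1, 0.1, 0, 0.1)$theta, 0)
  expect_error(wald_ratio(0, 0.1, 0.05, 0.02), "zero")
})

test_that("IVW-MRE handles exact collinearity and refuses single variants", {
  h <- harmonized_set(bx = c(1, 2), bx_se = c(0.1, 0.1),
                      by = c(0.5, 1.0), by_se = c(0.1, 0.1))
  e <- ivw_mre(h)
  expect_equal(e$theta, 0.5)
  expect_equal(e$q, 0)
  expect_equal(e$se, 0)
  h1 <- harmonized_set(1, 0.1, 0.5, 0.1)
  expect_error(ivw_mre(h1), "at least 2")
})

test_that("IVW-MRE matches a generic weighted-least-squares oracle", {
  for (s in 1:6) {
    h <- random_h(L = sample(3:20, 1), seed = 100 + s)
    d <- h$data
    e <- ivw_mre(h)
    o <- wls_origin_oracle(d$bx, d$by, 1 / d$by_se^2)
    expect_equal(e$theta, o$theta, tolerance = 1e-10)
    expect_equal(e$se, o$se_mre, tolerance = 1e-10)
  }
  # a fixed numeric instance
  h <- harmonized_set(bx = c(0.08, 0.12, 0.10), bx_se = rep(0.01, 3),
                      by = c(0.050, 0.055, 0.070),
                      by_se = c(0.01, 0.012, 0.009))
  o <- wls_origin_oracle(h$data$bx, h$data$by, 1 / h$data$by_se^2)
  e <- ivw_mre(h)
  expect_equal(e$theta, o$theta, tolerance = 1e-10)
  expect_equal(e$se, o$se_mre, tolerance = 1e-10)
})

test_that("MR-Egger recovers an exact linear law and matches the WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.22, 0.3)
  h <- harmonized_set(bx = bx, bx_se = rep(0.01, 6),
                      by = 0.1 + 0.5 * bx, by_se = rep(0.02, 6))
  e <- mr_egger(h)
  expect_equal(e$theta, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  for (s in 1:6) {
    h <- random_h(L = sample(4:15, 1), seed = 200 + s)
    d <- h$data
    e <- mr_egger(h)
    o <- egger_oracle(d$bx, d$by, 1 / d$by_se^2)
    expect_equal(e$theta, o$slope, tolerance = 1e-10)
    expect_equal(e$egger_intercept, o$intercept, tolerance = 1e-10)
    expect_equal(e$se, o$se_slope, tolerance = 1e-10)
    expect_equal(e$egger_intercept_se, o$se_int, tolerance = 1e-10)
  }
})

test_that("MR-Egger is invariant to sign-flipping any variant and needs spread in bx", {
  h <- random_h(L = 8, seed = 33)
  e0 <- mr_egger(h)
  d <- h$data
  d$bx[3] <- -d$bx[3]; d$by[3] <- -d$by[3]
  h2 <- harmonized_set(d$bx, d$bx_se, d$by, d$by_se)
  e1 <- mr_egger(h2)
  expect_equal(e1$theta, e0$theta, tolerance = 1e-12)
  expect_equal(e1$egger_intercept, e0$egger_intercept, tolerance = 1e-12)
  hflat <- harmonized_set(bx = rep(0.1, 4), bx_se = rep(0.01, 4),
                          by = rnorm(4), by_se = rep(0.02, 4))
  expect_error(mr_egger(hflat), "unidentifiable")
  expect_error(mr_egger(harmonized_set(1:2 / 10, c(.01, .01), 1:2 / 10,
                                       c(.01, .01))), "at least 3")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # equal weights, ratios 1,2,3: s = (1/6, 1/2, 5/6), interpolate at 1/2 -> 2
  h <- harmonized_set(bx = rep(1, 3), bx_se = rep(0, 3),
                      by = c(1, 2, 3), by_se = rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$theta, 2)
  # all ratios equal
  h2 <- harmonized_set(bx = c(1, 2, 4), bx_se = rep(0, 3),
                       by = c(0.7, 1.4, 2.8), by_se = c(0.1, 0.2, 0.4))
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$theta, 0.7,
               tolerance = 1e-12)
  # unequal weights against the brute-force interpolation definition
  for (s in 1:5) {
    h3 <- random_h(L = 5, seed = 300 + s)
    d <- h3$data
    r <- d$by / d$bx
    w <- 1 / (d$by_se^2 / d$bx^2 + d$by^2 * d$bx_se^2 / d$bx^4)
    expect_equal(mr_weighted_median(h3, n_boot = 10, seed = 1)$theta,
                 wmed_oracle(r, w), tolerance = 1e-12)
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  h <- harmonized_set(bx = c(1, 2, 4), bx_se = rep(0, 3),
                      by = c(0.7, 1.4, 2.8), by_se = c(0.1, 0.2, 0.4))
  e <- mr_weighted_mode(h, n_boot = 10, seed = 1)
  expect_equal(e$theta, 0.7)
  expect_equal(e$se, 0)
  # majority cluster near 0.5 dominates a single outlying ratio at 3
  h2 <- harmonized_set(bx = rep(1, 5), bx_se = rep(0, 5),
                       by = c(0.50, 0.51, 0.49, 0.50, 3.0),
                       by_se = rep(0.1, 5))
  e2 <- mr_weighted_mode(h2, n_boot = 10, seed = 1)
  expect_lt(abs(e2$theta - 0.5), 0.05)
  # matches a 10x-resolution dense-grid maximization within grid spacing
  for (s in 1:4) {
    h3 <- random_h(L = 6, seed = 400 + s)
    d <- h3$data
    r <- d$by / d$bx
    w <- 1 / (d$by_se^2 / d$bx^2 + d$by^2 * d$bx_se^2 / d$bx^4)
    mad_r <- mad(r)
    bw <- 0.9 * min(sd(r), if (mad_r > 0) mad_r else Inf) * length(r)^(-1 / 5)
    spacing <- (diff(range(r)) + 6 * bw) / 511
    expect_lt(abs(mr_weighted_mode(h3, n_boot = 10, seed = 1)$theta -
                    wmode_oracle(r, w)), spacing)
  }
})

test_that("estimator suite dispatches on instrument count", {
  h1 <- harmonized_set(0.1, 0.01, 0.05, 0.02)
  r1 <- run_univariable(h1)
  expect_named(r1, "wald")
  h2 <- harmonized_set(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                       c(0.02, 0.02))
  r2 <- run_univariable(h2)
  expect_named(r2, "ivw_mre")
  h10 <- random_h(10, seed = 5)
  r10 <- run_univariable(h10, n_boot = 20, seed = 1)
  expect_setequal(names(r10),
                  c("ivw_mre", "egger", "weighted_median", "weighted_mode"))
})

test_that("estimates are equivariant under outcome rescaling", {
  h <- random_h(8, seed = 77)
  d <- h$data
  base <- run_univariable(h, n_boot = 50, seed = 9)
  cc <- 2.5
  hs <- harmonized_set(d$bx, d$bx_se, cc * d$by, cc * d$by_se)
  scaled <- run_univariable(hs, n_boot = 50, seed = 9)
  for (m in names(base)) {
    expect_equal(scaled[[m]]$theta, cc * base[[m]]$theta, tolerance = 1e-6)
    expect_equal(scaled[[m]]$se, cc * base[[m]]$se, tolerance = 1e-6)
  }
})

test_that("binary outcomes carry odds-ratio fields", {
  h <- random_h(6, seed = 12, outcome_type = "binary")
  e <- ivw_mre(h)
  expect_equal(e$or, exp(e$theta))
  expect_equal(e$or_ci_low, exp(e$ci_low))
  expect_true(e$or > 0)
})
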
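# Fixture builders and independent oracles shared across test files.

# Random harmonized set with well-separated exposure betas.
random_h <- function(L, seed, outcome_type = "continuous") {
  set.seed(seed)
  harmonized_set(bx = runif(L, 0.05, 0.3) * sample(c(-1, 1), L, replace = TRUE),
                 bx_se = runif(L, 0.005, 0.02),
                 by = rnorm(L, 0, 0.1),
                 by_se = runif(L, 0.01, 0.08),
                 outcome_type = outcome_type)
}

# Harmonized multivariable set built directly from matrices.
make_hmv <- function(bx, bx_se, by, by_se, outcome_type = "continuous") {
  bx <- as.matrix(bx); bx_se <- as.matrix(bx_se)
  ids <- sprintf("v%03d", seq_len(nrow(bx)))
  exposure_ids <- colnames(bx) %||% sprintf("exp%d", seq_len(ncol(bx)))
  dimnames(bx) <- dimnames(bx_se) <- list(ids, exposure_ids)
  structure(list(bx = bx, bx_se = bx_se, by = by, by_se = by_se,
                 variant_id = ids, exposure_ids = exposure_ids,
                 outcome_id = "outcome", outcome_type = outcome_type,
                 n_snp = nrow(bx), actions = NULL),
            class = "harmonized_mvmr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Generic weighted-least-squares oracles via stats::lm.
wls_origin_oracle <- function(bx, by, w) {
  fit <- lm(by ~ bx - 1, weights = w)
  s <- summary(fit)
  list(theta = unname(coef(fit)[1]),
       se_mre = unname(s$coefficients[1, 2]),
       sigma2 = s$sigma^2)
}

egger_oracle <- function(bx, by, w) {
  s <- ifelse(bx < 0, -1, 1)
  fit <- lm(I(by * s) ~ I(bx * s), weights = w)
  su <- summary(fit)
  scale_fac <- max(1, su$sigma^2)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_int = unname(su$coefficients[1, 2]) * sqrt(scale_fac) / su$sigma,
       se_slope = unname(su$coefficients[2, 2]) * sqrt(scale_fac) / su$sigma)
}

mvmr_oracle <- function(X, by, w) {
  fit <- lm(by ~ X - 1, weights = w)
  su <- summary(fit)
  list(theta = unname(coef(fit)), se = unname(su$coefficients[, 2]))
}

# Independent evaluation of the weighted-median interpolation definition.
wmed_oracle <- function(r, w) {
  o <- order(r); r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Dense-grid weighted-mode oracle at 10x the implementation resolution.
wmode_oracle <- function(r, w, phi = 1) {
  mad_r <- mad(r)
  bw <- phi * 0.9 * min(sd(r), if (mad_r > 0) mad_r else Inf) *
    length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 5120L)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - r) / bw)), numeric(1))
  grid[which.max(dens)]
}

# Small canonical sumstats data frame.
make_sumstats <- function(n = 5, trait = "traitA", seed = 1,
                          ids = sprintf("rs%05d", seq_len(n))) {
  set.seed(seed)
  data.frame(variant_id = ids,
             effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
             other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
             eaf = runif(n, 0.1, 0.9), beta = rnorm(n, 0, 0.05),
             se = runif(n, 0.005, 0.02), pval = runif(n, 1e-12, 0.5),
             n = 10000L, trait_id = trait, stringsAsFactors = FALSE)
}

# Quick small-study configuration used by pipeline tests: strong instruments
# so genome-wide selection thresholds are met at modest panel sizes.
quick_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_samples_per_panel = 6000,
                   n_instruments_x = 30, n_instruments_per_m = 12,
                   n_mediators = 1, instrument_effect_scale = 0.15,
                   gamma = 0.6, delta = 0.8, tau_direct = 0.1)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
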
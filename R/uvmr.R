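#' Construct an MR estimate object
#'
#' Internal constructor shared by all univariable estimators. Confidence
#' intervals are `theta +/- 1.96 * se` and p-values are two-sided from the
#' normal approximation (the two-sample MR convention). When the outcome is
#' binary (log-odds scale), odds-ratio fields `or`, `or_ci_low`,
#' `or_ci_high` are attached.
#' @keywords internal
new_mr_estimate <- function(method, theta, se, n_snp,
                            outcome_type = "continuous",
                            q = NA_real_, q_pval = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_pval = NA_real_) {
  pval <- if (se == 0) {
    if (theta == 0) 1 else .Machine$double.xmin
  } else norm_pval(theta / se)
  est <- list(method = method, theta = theta, se = se,
              ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
              pval = pval, n_snp = n_snp, q = q, q_pval = q_pval,
              egger_intercept = egger_intercept,
              egger_intercept_se = egger_intercept_se,
              egger_intercept_pval = egger_intercept_pval,
              outcome_type = outcome_type)
  if (identical(outcome_type, "binary")) {
    est$or <- exp(theta)
    est$or_ci_low <- exp(est$ci_low)
    est$or_ci_high <- exp(est$ci_high)
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("MR estimate (%s), %d SNP%s\n", x$method, x$n_snp,
              if (x$n_snp == 1) "" else "s"))
  cat(sprintf("  theta = %.*f (SE %.*f), 95%% CI [%.*f, %.*f], p = %.3g\n",
              digits, x$theta, digits, x$se, digits, x$ci_low, digits,
              x$ci_high, x$pval))
  if (identical(x$outcome_type, "binary"))
    cat(sprintf("  OR = %.*f [%.*f, %.*f]\n", digits, x$or, digits,
                x$or_ci_low, digits, x$or_ci_high))
  if (!is.na(x$q))
    cat(sprintf("  Cochran Q = %.*f (p = %.3g)\n", digits, x$q, x$q_pval))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.*f (SE %.*f, p = %.3g)\n", digits,
                x$egger_intercept, digits, x$egger_intercept_se,
                x$egger_intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, theta = x$theta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_snp = x$n_snp, q = x$q, q_pval = x$q_pval,
             egger_intercept = x$egger_intercept,
             egger_intercept_se = x$egger_intercept_se,
             egger_intercept_pval = x$egger_intercept_pval,
             or = x$or %||% NA_real_,
             or_ci_low = x$or_ci_low %||% NA_real_,
             or_ci_high = x$or_ci_high %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$theta, object$method)
}

hdata <- function(h) {
  if (inherits(h, "harmonized_set")) h$data
  else stop("expected a harmonized_set")
}

#' Wald ratio estimator (single instrument)
#'
#' `theta = by / bx` with the first-order delta-method standard error
#' `|by_se / bx|` (uncertainty in the exposure beta is ignored, the standard
#' first-order convention).
#'
#' @param bx,bx_se exposure beta and SE (bx must be nonzero).
#' @param by,by_se outcome beta and SE.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(bx, bx_se, by, by_se, outcome_type = "continuous") {
  if (!is.finite(bx) || bx == 0)
    stop("Wald ratio undefined: exposure beta is zero")
  new_mr_estimate("wald", theta = by / bx, se = abs(by_se / bx), n_snp = 1L,
                  outcome_type = outcome_type)
}

#' Inverse-variance weighted estimator, multiplicative random effects
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1/by_se^2`:
#' `theta = sum(w bx by) / sum(w bx^2)`. Heterogeneity is Cochran's
#' `Q = sum(w (by - theta bx)^2)`; the multiplicative random-effects SE
#' scales the fixed-effect variance by the residual dispersion
#' `Q/(L-1)` with no flooring, so under-dispersed sets can have SEs below
#' the fixed-effect ones.
#'
#' @param h a `harmonized_set` with at least 2 variants.
#' @return an `mr_estimate`.
#' @export
ivw_mre <- function(h) {
  d <- hdata(h)
  L <- nrow(d)
  if (L < 2) stop("IVW requires at least 2 variants; use wald_ratio for 1")
  w <- 1 / d$by_se^2
  sxx <- sum(w * d$bx^2)
  theta <- sum(w * d$bx * d$by) / sxx
  q <- sum(w * (d$by - theta * d$bx)^2)
  se <- sqrt((q / (L - 1)) / sxx)
  new_mr_estimate("ivw_mre", theta, se, L, h$outcome_type, q = q,
                  q_pval = stats::pchisq(q, df = L - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/by_se^2`), after orienting every pair so the
#' exposure beta is non-negative. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy. Standard errors use
#' the residual dispersion floored at 1 (inflation-only random effects,
#' mirroring the estimator's reference implementation).
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @return an `mr_estimate` with `egger_intercept` fields.
#' @export
mr_egger <- function(h) {
  d <- hdata(h)
  L <- nrow(d)
  if (L < 3) stop("MR-Egger requires at least 3 variants")
  s <- ifelse(d$bx < 0, -1, 1)
  bx <- d$bx * s
  by <- d$by * s
  if (stats::var(bx) == 0)
    stop("MR-Egger slope unidentifiable: all exposure betas identical after orientation")
  w <- 1 / d$by_se^2
  # weighted least squares with intercept via the 2x2 normal equations
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  intercept <- (swx2 * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  resid <- by - intercept - slope * bx
  q <- sum(w * resid^2)
  scale <- max(1, q / (L - 2))
  se_slope <- sqrt(scale * sw / det)
  se_int <- sqrt(scale * swx2 / det)
  new_mr_estimate("egger", slope, se_slope, L, h$outcome_type, q = q,
                  q_pval = stats::pchisq(q, df = L - 2, lower.tail = FALSE),
                  egger_intercept = intercept, egger_intercept_se = se_int,
                  egger_intercept_pval = norm_pval(intercept / se_int))
}

# Per-variant Wald ratios and their first-order inverse-variance weights.
ratio_weights <- function(d) {
  if (any(d$bx == 0)) stop("ratio-based estimators require nonzero exposure betas")
  r <- d$by / d$bx
  var_r <- d$by_se^2 / d$bx^2 + d$by^2 * d$bx_se^2 / d$bx^4
  list(r = r, w = 1 / var_r)
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(d, point_fun, n_boot, seed) {
  ests <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(d), d$bx, d$bx_se)
      by <- stats::rnorm(nrow(d), d$by, d$by_se)
      point_fun(data.frame(bx = bx, bx_se = d$bx_se,
                           by = by, by_se = d$by_se))
    }, numeric(1))
  })
  stats::sd(ests)
}

#' Weighted-median estimator
#'
#' The weighted median of the per-variant Wald ratios: ratios are sorted,
#' standardized cumulative weights `s_j = (cumsum(w)_j - w_j/2) / sum(w)` are
#' formed, and the estimate is the linear interpolation of the ratios at
#' `s = 0.5`. Weights are first-order inverse variances of the ratios. The
#' standard error is the standard deviation of the estimate over a seeded
#' parametric bootstrap (betas resampled from their normal sampling
#' distributions). Consistent when at least half the weight comes from valid
#' instruments.
#'
#' @param h a `harmonized_set` with at least 3 variants and nonzero exposure
#'   betas.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  d <- hdata(h)
  if (nrow(d) < 3) stop("weighted median requires at least 3 variants")
  rw <- ratio_weights(d)
  theta <- weighted_median_point(rw$r, rw$w)
  point <- function(dd) {
    rw <- ratio_weights(dd)
    weighted_median_point(rw$r, rw$w)
  }
  se <- boot_se(d, point, n_boot, derive_seed(seed, "weighted_median_boot"))
  new_mr_estimate("weighted_median", theta, se, nrow(d), h$outcome_type)
}

weighted_mode_point <- function(r, w, phi = 1, n_grid = 512L) {
  if (length(unique(r)) == 1) return(r[1])
  mad_r <- stats::mad(r)
  s <- min(stats::sd(r), if (mad_r > 0) mad_r else Inf)
  bw <- phi * 0.9 * s * length(r)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(r[which.max(w)])
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = n_grid)
  dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / bw))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' The mode of a normal-kernel weighted density of the per-variant Wald
#' ratios, located on a fine grid (512 points over the padded ratio range).
#' The bandwidth is `phi * 0.9 * min(sd(r), mad(r)) * L^(-1/5)`. Weights and
#' the bootstrap standard error are as in [mr_weighted_median()]. Consistent
#' when the largest homogeneous cluster of instruments is valid.
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth inflation factor (> 0, default 1).
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(h, phi = 1, n_boot = 1000L, seed = 1L) {
  if (phi <= 0) stop("phi must be positive")
  d <- hdata(h)
  if (nrow(d) < 3) stop("weighted mode requires at least 3 variants")
  rw <- ratio_weights(d)
  if (length(unique(rw$r)) == 1)
    return(new_mr_estimate("weighted_mode", rw$r[1], 0, nrow(d),
                           h$outcome_type))
  theta <- weighted_mode_point(rw$r, rw$w, phi)
  point <- function(dd) {
    rw <- ratio_weights(dd)
    weighted_mode_point(rw$r, rw$w, phi)
  }
  se <- boot_se(d, point, n_boot, derive_seed(seed, "weighted_mode_boot"))
  new_mr_estimate("weighted_mode", theta, se, nrow(d), h$outcome_type)
}

#' Run the univariable estimator suite with instrument-count dispatch
#'
#' Applies the estimator dispatch rule used throughout the screen: a single
#' instrument gives the Wald ratio only; two instruments give IVW-MRE only;
#' three or more add the MR-Egger, weighted-median and weighted-mode
#' sensitivity estimators.
#'
#' @param h a `harmonized_set` with at least 1 variant.
#' @param n_boot bootstrap resamples for the median/mode standard errors.
#' @param seed bootstrap seed.
#' @return named list of `mr_estimate` objects (class `mr_result`).
#' @export
run_univariable <- function(h, n_boot = 1000L, seed = 1L) {
  d <- hdata(h)
  if (nrow(d) == 0) stop("empty harmonized set")
  out <- if (nrow(d) == 1) {
    list(wald = wald_ratio(d$bx, d$bx_se, d$by, d$by_se, h$outcome_type))
  } else if (nrow(d) == 2) {
    list(ivw_mre = ivw_mre(h))
  } else {
    list(ivw_mre = ivw_mre(h),
         egger = mr_egger(h),
         weighted_median = mr_weighted_median(h, n_boot, seed),
         weighted_mode = mr_weighted_mode(h, 1, n_boot, seed))
  }
  structure(out, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  out <- do.call(rbind, lapply(unclass(x), as.data.frame))
  rownames(out) <- NULL
  out
}
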
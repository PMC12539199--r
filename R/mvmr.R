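#' Multivariable MR fit
#'
#' Weighted regression of outcome betas on the K exposure-beta columns
#' through the origin with weights `1/by_se^2`. Coefficients are the direct
#' effects of each exposure conditional on the others. Standard errors use
#' the weighted-regression covariance with the multiplicative residual scale
#' `Q/(L-K)` (not floored). Conditional F-statistics ([conditional_f()]) and
#' the adapted heterogeneity statistic ([mvmr_qa()]) are attached.
#' Exposure columns that are identically zero are flagged `NA` and dropped
#' from the regression rather than propagating a singular fit; any remaining
#' rank deficiency is an error.
#'
#' @param h a `harmonized_mvmr` set (see [harmonize_mvmr()]) with
#'   `L > K` variants.
#' @return an object of class `mvmr_fit` with elements `exposure_ids`,
#'   `theta`, `se`, `ci_low`, `ci_high`, `pval`, `n_snp`, `conditional_f`,
#'   `q_a`, `q_a_pval` and, for binary outcomes, `or`/`or_ci_*`.
#' @export
mvmr_fit <- function(h) {
  X <- h$bx
  y <- h$by
  L <- nrow(X); K <- ncol(X)
  if (is.null(L) || L <= K)
    stop(sprintf("multivariable MR needs more variants (%d) than exposures (%d)",
                 L %||% 0, K))
  zero_col <- colSums(abs(X)) == 0
  Xf <- X[, !zero_col, drop = FALSE]
  Kf <- ncol(Xf)
  if (Kf == 0) stop("all exposure-beta columns are zero")
  if (qr(Xf)$rank < Kf)
    stop("rank-deficient exposure matrix: exposures are collinear across instruments")
  w <- 1 / h$by_se^2
  XtWX <- crossprod(Xf, Xf * w)
  XtWy <- crossprod(Xf, y * w)
  theta_f <- drop(solve(XtWX, XtWy))
  resid <- y - drop(Xf %*% theta_f)
  q <- sum(w * resid^2)
  scale <- q / (L - Kf)
  cov_f <- scale * solve(XtWX)
  se_f <- sqrt(diag(cov_f))

  theta <- se <- rep(NA_real_, K)
  theta[!zero_col] <- theta_f
  se[!zero_col] <- se_f
  names(theta) <- names(se) <- h$exposure_ids
  if (any(zero_col))
    warning("exposure column(s) with all-zero betas flagged NA: ",
            paste(h$exposure_ids[zero_col], collapse = ", "), call. = FALSE)

  qa <- mvmr_qa(h, theta)
  fit <- list(exposure_ids = h$exposure_ids, theta = theta, se = se,
              ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
              pval = ifelse(se > 0, norm_pval(theta / se),
                            ifelse(theta == 0, 1, .Machine$double.xmin)),
              n_snp = L, q = q,
              conditional_f = if (Kf == K) conditional_f(h) else
                rep(NA_real_, K),
              q_a = qa$statistic, q_a_pval = qa$pval,
              outcome_type = h$outcome_type, dropped = h$exposure_ids[zero_col])
  if (identical(h$outcome_type, "binary")) {
    fit$or <- exp(theta)
    fit$or_ci_low <- exp(fit$ci_low)
    fit$or_ci_high <- exp(fit$ci_high)
  }
  structure(fit, class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariable MR fit: %d exposures, %d SNPs\n",
              length(x$exposure_ids), x$n_snp))
  tab <- data.frame(exposure = x$exposure_ids,
                    theta = round(x$theta, digits),
                    se = round(x$se, digits),
                    ci_low = round(x$ci_low, digits),
                    ci_high = round(x$ci_high, digits),
                    pval = signif(x$pval, 3),
                    cond_F = round(x$conditional_f, 1))
  print(tab, row.names = FALSE)
  cat(sprintf("Q_A = %.*f (p = %.3g)\n", digits, x$q_a, x$q_a_pval))
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) object$theta

#' @export
confint.mvmr_fit <- function(object, parm, level = 0.95, ...) {
  ci <- cbind(object$ci_low, object$ci_high)
  rownames(ci) <- object$exposure_ids
  colnames(ci) <- c("2.5 %", "97.5 %")
  ci
}

#' @export
as.data.frame.mvmr_fit <- function(x, ...) {
  data.frame(exposure = x$exposure_ids, theta = unname(x$theta),
             se = unname(x$se), ci_low = unname(x$ci_low),
             ci_high = unname(x$ci_high), pval = unname(x$pval),
             n_snp = x$n_snp, conditional_f = unname(x$conditional_f),
             q_a = x$q_a, q_a_pval = x$q_a_pval, stringsAsFactors = FALSE)
}

#' Conditional F-statistics for instrument strength
#'
#' For each exposure k, its instrument-beta column is regressed (through the
#' origin, weights `1/bx_se_k^2`) on the other exposures' columns; the
#' weighted residual sum of squares `Q_xk` measures the variation in
#' exposure k's associations not explained by the other exposures, and the
#' conditional F-statistic is `Q_xk / (L - K + 1)`. Covariances between
#' exposures' summary statistics are treated as zero (summary-data setting).
#' With a single exposure this reduces to the mean univariable F.
#'
#' @param h a `harmonized_mvmr` set.
#' @return numeric vector of length K.
#' @export
conditional_f <- function(h) {
  X <- h$bx; S <- h$bx_se
  L <- nrow(X); K <- ncol(X)
  vapply(seq_len(K), function(k) {
    yk <- X[, k]
    v <- 1 / S[, k]^2
    if (K == 1) {
      qxk <- sum(v * yk^2)
    } else {
      Z <- X[, -k, drop = FALSE]
      ZtVZ <- crossprod(Z, Z * v)
      fit <- tryCatch(drop(Z %*% solve(ZtVZ, crossprod(Z, yk * v))),
                      error = function(e) rep(0, L))
      qxk <- sum(v * (yk - fit)^2)
    }
    qxk / (L - K + 1)
  }, numeric(1))
}

#' Adapted heterogeneity statistic Q_A for multivariable MR
#'
#' `Q_A = sum_j w_j (by_j - sum_k theta_k bx_kj)^2` with weights
#' `w_j = 1 / (by_se_j^2 + sum_k theta_k^2 bx_se_kj^2)`, which account for
#' uncertainty in the exposure betas at the fitted coefficients (single
#' pass, no iteration). The p-value is from a chi-square distribution with
#' `L - K` degrees of freedom. When all exposure SEs are zero this reduces
#' to the ordinary Cochran Q of the multivariable fit.
#'
#' @param h a `harmonized_mvmr` set.
#' @param theta fitted coefficient vector (NAs treated as zero).
#' @return list with `statistic` and `pval`.
#' @export
mvmr_qa <- function(h, theta) {
  th <- ifelse(is.na(theta), 0, theta)
  L <- nrow(h$bx); K <- ncol(h$bx)
  resid <- h$by - drop(h$bx %*% th)
  wden <- h$by_se^2 + drop((h$bx_se^2) %*% th^2)
  if (any(!is.finite(1 / wden))) stop("non-finite Q_A weights")
  qa <- sum(resid^2 / wden)
  list(statistic = qa,
       pval = stats::pchisq(qa, df = max(L - K, 1), lower.tail = FALSE))
}

#' Per-mediator multivariable MR scan of direct exposure effects
#'
#' For each mediator, fits a two-exposure multivariable MR of the outcome on
#' the exposure and that mediator, and compares the direct exposure effect
#' with the univariable (total) IVW-MRE effect. The attenuation fraction is
#' `1 - theta_direct / theta_total`, suppressed (with a reason flag) when
#' the total effect is not distinguishable from zero. A lower-powered
#' exposure GWAS can be supplied for the multivariable step to avoid
#' diluting mediator instrument strength; the univariable total effect
#' always uses the primary exposure instruments.
#'
#' @param exposure_instruments [select_instruments()] result for the
#'   exposure (primary GWAS).
#' @param exposure_sumstats full exposure summary statistics used in the
#'   multivariable fits (e.g. the lower-powered GWAS); defaults to the
#'   instruments' own records when `NULL` is not supplied.
#' @param mediators named list; each element a list with `instruments`
#'   (instrument_set) and `sumstats` (full summary statistics for that
#'   mediator).
#' @param outcome outcome summary statistics.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param mvmr_exposure_instruments optional instrument set from the
#'   lower-powered exposure GWAS to use in the multivariable fits.
#' @return list with `fits` (named list of `mvmr_fit`), `table` (one row per
#'   mediator: total and direct effects, attenuation fraction and flag,
#'   conditional F, Q_A) and `skipped` (mediators without usable
#'   instruments, with reasons).
#' @export
direct_effect_scan <- function(exposure_instruments, exposure_sumstats,
                               mediators, outcome,
                               outcome_type = "binary",
                               mvmr_exposure_instruments = NULL) {
  h_total <- harmonize(exposure_instruments, outcome,
                       outcome_type = outcome_type)
  if (h_total$n_snp < 2)
    stop("cannot estimate the univariable total effect: fewer than 2 instruments")
  total <- ivw_mre(h_total)
  mv_instr <- mvmr_exposure_instruments %||% exposure_instruments

  fits <- list(); rows <- list(); skipped <- list()
  for (m in names(mediators)) {
    med <- mediators[[m]]
    med_df <- if (inherits(med$instruments, "instrument_set"))
      med$instruments$variants else med$instruments
    if (is.null(med_df) || nrow(med_df) < 1) {
      skipped[[m]] <- "no_mediator_instruments"
      next
    }
    hm <- suppressWarnings(
      harmonize_mvmr(list(mv_instr, med$instruments),
                     list(exposure_sumstats, med$sumstats),
                     outcome, outcome_type = outcome_type))
    if (hm$n_snp <= 2) {
      skipped[[m]] <- "insufficient_harmonized_variants"
      next
    }
    fit <- mvmr_fit(hm)
    fits[[m]] <- fit
    theta_direct <- unname(fit$theta[1])
    se_direct <- unname(fit$se[1])
    flag <- "ok"
    atten <- 1 - theta_direct / total$theta
    if (abs(total$theta) < 1.96 * total$se) {
      atten <- NA_real_
      flag <- "undefined_ratio_total_near_zero"
    }
    rows[[m]] <- data.frame(
      mediator = m, theta_total = total$theta, se_total = total$se,
      theta_direct = theta_direct, se_direct = se_direct,
      direct_ci_low = unname(fit$ci_low[1]),
      direct_ci_high = unname(fit$ci_high[1]),
      attenuation = atten, attenuation_flag = flag,
      conditional_f_exposure = unname(fit$conditional_f[1]),
      conditional_f_mediator = unname(fit$conditional_f[2]),
      q_a = fit$q_a, q_a_pval = fit$q_a_pval, n_snp = fit$n_snp,
      stringsAsFactors = FALSE)
  }
  table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mediator = character(0))
  rownames(table) <- NULL
  list(fits = fits, table = table, total = total,
       skipped = unlist(skipped) %||% character(0))
}
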
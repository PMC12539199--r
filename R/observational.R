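#' Inverse rank-normal transformation
#'
#' Maps values to standard-normal quantiles of their offset ranks:
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties (so a middle rank
#' maps exactly to 0 for odd n). Missing values stay missing and are excluded
#' from ranking. Output is rank-invariant: any strictly monotone transform of
#' the input gives identical output.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @return transformed vector, in normalised SD units.
#' @export
irnt <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) stop("all values missing")
  if (n < 2) stop("IRNT needs at least 2 non-missing values")
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Classify registry records as incident case, prevalent case or control
#'
#' A participant with a recorded diagnosis is an incident case when the age
#' at assessment is strictly less than the age at diagnosis, and a prevalent
#' case otherwise (equal ages count as prevalent under the strict rule).
#' Participants with no diagnosis record are controls. Prevalent cases are
#' excluded from analysis downstream.
#'
#' @param age_at_assessment numeric vector of ages (non-negative).
#' @param age_at_diagnosis numeric vector, `NA` for no cancer record.
#' @return factor with levels `incident`, `prevalent`, `control`.
#' @export
define_incident_cases <- function(age_at_assessment, age_at_diagnosis) {
  if (any(age_at_assessment < 0, na.rm = TRUE) ||
      any(age_at_diagnosis < 0, na.rm = TRUE))
    stop("ages must be non-negative")
  status <- ifelse(is.na(age_at_diagnosis), "control",
                   ifelse(age_at_assessment < age_at_diagnosis,
                          "incident", "prevalent"))
  factor(status, levels = c("incident", "prevalent", "control"))
}

result_row <- function(fit, xname, model_tag, binary) {
  co <- summary(fit)$coefficients
  if (!xname %in% rownames(co))
    stop(sprintf("term '%s' dropped from the model (collinear design?)", xname))
  est <- co[xname, 1]; se <- co[xname, 2]
  out <- data.frame(term = xname, estimate = est, se = se,
                    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                    pval = norm_pval(est / se), model_tag = model_tag,
                    n_used = length(fit$residuals),
                    stringsAsFactors = FALSE)
  if (binary) {
    out$or <- exp(est)
    out$or_ci_low <- exp(out$ci_low)
    out$or_ci_high <- exp(out$ci_high)
  }
  class(out) <- c("regression_result", "data.frame")
  out
}

build_frame <- function(y, x, covariates) {
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, covariates)
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Covariate-adjusted linear regression (continuous outcomes)
#'
#' Least-squares coefficient for `x` with covariates, complete-case rows
#' only; normal-approximation CI and p-value.
#'
#' @param y continuous outcome (IRNT applied upstream where applicable).
#' @param x continuous exposure.
#' @param covariates optional data frame of adjustment covariates.
#' @param model_tag label, e.g. `"age_centre"` or `"fully_adjusted"`.
#' @return one-row data frame of class `regression_result`.
#' @export
fit_linear <- function(y, x, covariates = NULL, model_tag = "age_centre") {
  df <- build_frame(y, x, covariates)
  if (nrow(df) <= ncol(df)) stop("too few complete cases for the design")
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("collinear design: some coefficients are not estimable")
  result_row(fit, ".x", model_tag, binary = FALSE)
}

#' Covariate-adjusted logistic regression (binary outcomes)
#'
#' Maximum-likelihood log-odds coefficient via iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 50 iterations); odds ratio
#' and CI on the exponential scale. Separation (non-convergence with a
#' diverging coefficient) is an explicit error.
#'
#' @inheritParams fit_linear
#' @param y binary outcome with both classes present.
#' @return one-row data frame of class `regression_result` with `or` columns.
#' @export
fit_logistic <- function(y, x, covariates = NULL, model_tag = "age_centre") {
  if (length(unique(stats::na.omit(y))) < 2)
    stop("logistic regression needs both outcome classes present")
  df <- build_frame(y, x, covariates)
  if (length(unique(df$.y)) < 2)
    stop("logistic regression needs both outcome classes present")
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 20, na.rm = TRUE))
    stop("logistic fit did not converge (possible separation)")
  if (any(is.na(stats::coef(fit))))
    stop("collinear design: some coefficients are not estimable")
  result_row(fit, ".x", model_tag, binary = TRUE)
}

#' Metabolome-wide covariate-adjusted scan
#'
#' Runs one regression per mediator. In the `exposure_to_mediator` direction
#' each (IRNT-transformed) mediator is regressed on the exposure
#' (discovery scan; Bonferroni flag at `0.05 / n_mediators`). In the
#' `mediator_to_outcome` direction the binary outcome is regressed on each
#' mediator (hypothesis-driven scan; uncorrected flag at `0.05`).
#'
#' @param cohort data frame of per-individual measurements.
#' @param exposure column name of the exposure (raw units; IRNT applied
#'   internally), or of the binary outcome for the outcome direction.
#' @param mediators character vector of mediator column names (raw units;
#'   IRNT applied internally).
#' @param covariates character vector of covariate column names.
#' @param model_tag model label carried into the results.
#' @param direction `"exposure_to_mediator"` or `"mediator_to_outcome"`.
#' @return data frame with one row per mediator: the regression result plus
#'   `mediator`, `discovery` flag and the `threshold` applied.
#' @export
metabolome_scan <- function(cohort, exposure, mediators,
                            covariates = character(0),
                            model_tag = "age_centre",
                            direction = c("exposure_to_mediator",
                                          "mediator_to_outcome")) {
  direction <- match.arg(direction)
  if (length(mediators) == 0)
    return(data.frame(mediator = character(0)))
  covs <- if (length(covariates) > 0)
    cohort[, covariates, drop = FALSE] else NULL
  threshold <- if (direction == "exposure_to_mediator")
    0.05 / length(mediators) else 0.05
  rows <- lapply(mediators, function(m) {
    res <- if (direction == "exposure_to_mediator") {
      fit_linear(irnt(cohort[[m]]), irnt(cohort[[exposure]]), covs, model_tag)
    } else {
      fit_logistic(cohort[[exposure]], irnt(cohort[[m]]), covs, model_tag)
    }
    res$mediator <- m
    res
  })
  out <- do.call(rbind, rows)
  out$threshold <- threshold
  out$discovery <- out$pval < threshold
  rownames(out) <- NULL
  out
}
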
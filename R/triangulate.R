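#' Configuration for the sequential triangulation screen
#'
#' Thresholds and run parameters for Parts I-IV. Shipped defaults are the
#' screen's canonical choices: IVW p < 0.05 with sign-consistent sensitivity
#' estimators at Part I; Bonferroni `part2_alpha / n_mediators` at the
#' discovery step (0.05/249 for a full metabolomics panel); uncorrected
#' p < 0.05 at the hypothesis-driven Part III together with the
#' triple-sign mediation-direction rule; instrument selection at
#' p < 5e-9 (adiposity-like) and p < 5e-8 (metabolite-like) with
#' r-squared < 0.001 clumping.
#'
#' @param part1_p Part I IVW p-value threshold.
#' @param part2_alpha family-wise alpha divided by the mediator panel size at
#'   Part II.
#' @param part3_p Part III uncorrected p-value threshold.
#' @param exposure_p_threshold,mediator_p_threshold instrument selection
#'   p-value thresholds.
#' @param clump_r2 LD clumping r-squared threshold.
#' @param n_boot bootstrap resamples for median/mode standard errors.
#' @param seed seed for all bootstrap substreams.
#' @param catalogue_p phenome-catalogue lookup threshold (Part V).
#' @param n_iter random-metabolite redraws in the enrichment null.
#' @param use_observational gate Part II on sign agreement with the
#'   observational arm when a cohort is available.
#' @return list of class `triangulation_config`.
#' @export
triangulation_config <- function(part1_p = 0.05, part2_alpha = 0.05,
                                 part3_p = 0.05,
                                 exposure_p_threshold = 5e-9,
                                 mediator_p_threshold = 5e-8,
                                 clump_r2 = 0.001, n_boot = 1000L,
                                 seed = 1L, catalogue_p = 1e-10,
                                 n_iter = 100L, use_observational = TRUE) {
  cfg <- list(part1_p = part1_p, part2_alpha = part2_alpha,
              part3_p = part3_p,
              exposure_p_threshold = exposure_p_threshold,
              mediator_p_threshold = mediator_p_threshold,
              clump_r2 = clump_r2, n_boot = as.integer(n_boot),
              seed = as.integer(seed), catalogue_p = catalogue_p,
              n_iter = as.integer(n_iter),
              use_observational = isTRUE(use_observational))
  for (f in c("part1_p", "part2_alpha", "part3_p", "exposure_p_threshold",
              "mediator_p_threshold", "clump_r2", "catalogue_p")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v >= 1)
      stop_field(f, "must be a single number in (0, 1)")
  }
  structure(cfg, class = "triangulation_config")
}

decision_row <- function(stage, entity, passed, reason) {
  data.frame(stage = stage, entity = entity, passed = passed,
             reason_code = reason, stringsAsFactors = FALSE)
}

sign0 <- function(x) sign(round(x, 15))

# Part I rule: primary (IVW, or Wald when only one instrument) p below
# threshold, and every available sensitivity estimator sign-consistent with
# it. No p-value requirement on the sensitivity methods.
decide_part1 <- function(estimates, p_threshold) {
  primary <- estimates$ivw_mre %||% estimates$wald
  if (primary$pval >= p_threshold)
    return(list(passed = FALSE, reason = "p_above_threshold"))
  sens <- estimates[setdiff(names(estimates), c("ivw_mre", "wald"))]
  if (length(sens) > 0) {
    signs <- vapply(sens, function(e) sign0(e$theta), numeric(1))
    if (any(signs != 0 & signs != sign0(primary$theta)))
      return(list(passed = FALSE, reason = "sign_discordant_methods"))
  }
  list(passed = TRUE, reason = "passed")
}

decide_part2 <- function(pval, mr_sign, obs_sign, threshold) {
  if (is.na(pval)) return(list(passed = FALSE, reason = "insufficient_instruments"))
  if (pval >= threshold)
    return(list(passed = FALSE, reason = "p_above_threshold"))
  if (!is.null(obs_sign) && !is.na(obs_sign) &&
      obs_sign != 0 && mr_sign != 0 && obs_sign != mr_sign)
    return(list(passed = FALSE, reason = "sign_discordant_arms"))
  list(passed = TRUE, reason = "passed")
}

decide_part3 <- function(pval, sign_xm, sign_my, sign_xy, threshold) {
  if (is.na(pval)) return(list(passed = FALSE, reason = "insufficient_instruments"))
  if (pval >= threshold)
    return(list(passed = FALSE, reason = "p_above_threshold"))
  if (sign_xm * sign_my != sign_xy)
    return(list(passed = FALSE, reason = "direction_inconsistent_mediation"))
  list(passed = TRUE, reason = "passed")
}

obs_covariate_sets <- function(cohort) {
  base <- intersect(c("age", "centre"), names(cohort))
  extra <- intersect(c("smoking", "alcohol", "education", "activity_met",
                       "hrt", "menopause", "age_menarche", "age_first_birth"),
                     names(cohort))
  list(age_centre = base, fully_adjusted = c(base, extra))
}

# Observational analysis subset: incident cases and controls only.
obs_analysis_frame <- function(cohort) {
  status <- define_incident_cases(cohort$age, cohort$age_at_diagnosis)
  keep <- status != "prevalent"
  df <- cohort[keep, , drop = FALSE]
  df$.case <- as.integer(status[keep] == "incident")
  df
}

#' Part I: exposure-to-outcome MR with parallel observational estimate
#'
#' Runs the univariable estimator suite for each exposure against each
#' outcome, gates on the first (overall) outcome, and — when a cohort is
#' supplied — reports age/centre-adjusted and fully adjusted observational
#' logistic estimates alongside.
#'
#' @param exposures named list of [select_instruments()] results.
#' @param outcomes named list of outcome summary statistics (first element
#'   is the gating outcome).
#' @param cohort optional observational cohort data frame.
#' @param config a [triangulation_config()].
#' @return list with `estimates` (data frame), `observational`,
#'   `decisions`, `passes`.
#' @export
part1_exposure_outcome <- function(exposures, outcomes, cohort = NULL,
                                   config = triangulation_config()) {
  stopifnot(length(exposures) >= 1)
  gate_outcome <- names(outcomes)[1]
  est_rows <- list(); decisions <- list(); passes <- character(0)
  for (ex in names(exposures)) {
    for (oc in names(outcomes)) {
      h <- harmonize(exposures[[ex]], outcomes[[oc]],
                     outcome_type = "binary")
      ests <- run_univariable(h, n_boot = config$n_boot,
                              seed = derive_seed(config$seed,
                                                 paste("p1", ex, oc)))
      tab <- as.data.frame(ests)
      tab$exposure <- ex; tab$outcome <- oc
      est_rows[[paste(ex, oc)]] <- tab
      if (oc == gate_outcome) {
        dec <- decide_part1(ests, config$part1_p)
        decisions[[ex]] <- decision_row("part1", ex, dec$passed, dec$reason)
        if (dec$passed) passes <- c(passes, ex)
      }
    }
  }
  observational <- NULL
  if (!is.null(cohort) && config$use_observational) {
    df <- obs_analysis_frame(cohort)
    covs <- obs_covariate_sets(df)
    observational <- do.call(rbind, lapply(names(covs), function(tag) {
      res <- fit_logistic(df$.case, irnt(df$adiposity_raw),
                          df[, covs[[tag]], drop = FALSE], tag)
      res$exposure <- "adiposity"
      res
    }))
  }
  list(estimates = do.call(rbind, est_rows),
       observational = observational,
       decisions = do.call(rbind, decisions), passes = passes)
}

#' Part II: exposure-to-mediator discovery scan
#'
#' IVW-MRE estimate of the exposure effect on each mediator; a mediator
#' passes when its p-value clears the Bonferroni threshold
#' `part2_alpha / panel size` and (when the observational arm is available)
#' the observational and MR point estimates agree in sign.
#'
#' @param exposure an [select_instruments()] result (a Part-I pass).
#' @param mediator_sumstats stacked mediator summary statistics
#'   (`trait_id` distinguishes mediators).
#' @param cohort optional observational cohort.
#' @param config a [triangulation_config()].
#' @return list with `estimates`, `observational`, `decisions`, `passes`,
#'   `threshold`.
#' @export
part2_exposure_mediators <- function(exposure, mediator_sumstats,
                                     cohort = NULL,
                                     config = triangulation_config()) {
  meds <- unique(mediator_sumstats$trait_id)
  threshold <- config$part2_alpha / length(meds)
  obs <- NULL
  if (!is.null(cohort) && config$use_observational) {
    raw_cols <- paste0(meds, "_raw")
    raw_cols <- raw_cols[raw_cols %in% names(cohort)]
    if (length(raw_cols) > 0) {
      df <- obs_analysis_frame(cohort)
      obs <- metabolome_scan(df, "adiposity_raw", raw_cols,
                             covariates = obs_covariate_sets(df)$age_centre,
                             model_tag = "age_centre",
                             direction = "exposure_to_mediator")
      obs$mediator <- sub("_raw$", "", obs$mediator)
    }
  }
  est_rows <- list(); decisions <- list(); passes <- character(0)
  for (m in meds) {
    rec <- mediator_sumstats[mediator_sumstats$trait_id == m, , drop = FALSE]
    h <- suppressWarnings(harmonize(exposure, rec, outcome_type = "continuous"))
    if (h$n_snp < 1) {
      decisions[[m]] <- decision_row("part2", m, FALSE,
                                     "insufficient_instruments")
      next
    }
    est <- if (h$n_snp >= 2) ivw_mre(h) else
      wald_ratio(h$data$bx, h$data$bx_se, h$data$by, h$data$by_se)
    tab <- as.data.frame(est); tab$mediator <- m
    est_rows[[m]] <- tab
    obs_sign <- if (!is.null(obs) && m %in% obs$mediator)
      sign0(obs$estimate[obs$mediator == m][1]) else NULL
    dec <- decide_part2(est$pval, sign0(est$theta), obs_sign, threshold)
    decisions[[m]] <- decision_row("part2", m, dec$passed, dec$reason)
    if (dec$passed) passes <- c(passes, m)
  }
  list(estimates = do.call(rbind, est_rows), observational = obs,
       decisions = do.call(rbind, decisions), passes = passes,
       threshold = threshold)
}

#' Part III: mediator-to-outcome MR with the mediation-direction rule
#'
#' Selects each passing mediator's own instruments, estimates its effect on
#' every outcome (Wald ratio for one instrument, IVW-MRE otherwise), and
#' gates on the overall outcome with the uncorrected `part3_p` threshold
#' plus the triple-sign rule: sign(exposure->mediator) x
#' sign(mediator->outcome) must equal sign(exposure->outcome).
#'
#' @param mediator_ids Part-II passes.
#' @param mediator_sumstats stacked mediator summary statistics.
#' @param outcomes named list of outcome summary statistics.
#' @param xm_signs named numeric: sign of the exposure->mediator estimate
#'   per mediator.
#' @param xy_sign sign of the exposure->outcome (overall) estimate.
#' @param ld optional LD table for clumping.
#' @param config a [triangulation_config()].
#' @return list with `estimates`, `instruments`, `decisions`, `passes`.
#' @export
part3_mediators_outcome <- function(mediator_ids, mediator_sumstats, outcomes,
                                    xm_signs, xy_sign, ld = NULL,
                                    config = triangulation_config()) {
  gate_outcome <- names(outcomes)[1]
  est_rows <- list(); decisions <- list(); passes <- character(0)
  instruments <- list()
  for (m in mediator_ids) {
    rec <- mediator_sumstats[mediator_sumstats$trait_id == m, , drop = FALSE]
    instr <- suppressWarnings(select_instruments(
      rec, config$mediator_p_threshold,
      ld_info = if (is.null(ld)) "assume-independent" else ld,
      r2_threshold = config$clump_r2))
    instruments[[m]] <- instr
    if (instr$status == "empty") {
      decisions[[m]] <- decision_row("part3", m, FALSE,
                                     "insufficient_instruments")
      next
    }
    for (oc in names(outcomes)) {
      h <- suppressWarnings(harmonize(instr, outcomes[[oc]],
                                      outcome_type = "binary"))
      if (h$n_snp < 1) {
        if (oc == gate_outcome)
          decisions[[m]] <- decision_row("part3", m, FALSE,
                                         "insufficient_instruments")
        next
      }
      est <- if (h$n_snp >= 2) ivw_mre(h) else
        wald_ratio(h$data$bx, h$data$bx_se, h$data$by, h$data$by_se,
                   outcome_type = "binary")
      tab <- as.data.frame(est); tab$mediator <- m; tab$outcome <- oc
      est_rows[[paste(m, oc)]] <- tab
      if (oc == gate_outcome) {
        dec <- decide_part3(est$pval, xm_signs[[m]], sign0(est$theta),
                            xy_sign, config$part3_p)
        decisions[[m]] <- decision_row("part3", m, dec$passed, dec$reason)
        if (dec$passed) passes <- c(passes, m)
      }
    }
  }
  list(estimates = do.call(rbind, est_rows), instruments = instruments,
       decisions = do.call(rbind, decisions), passes = passes)
}

#' Part IV: multivariable MR attenuation of the direct exposure effect
#'
#' Wraps [direct_effect_scan()] for the Part-III passes and returns the
#' attenuation table (univariable total vs multivariable direct exposure
#' effect, attenuation fraction, conditional F, Q_A) plus a decision row per
#' mediator.
#'
#' @param mediator_ids Part-III passes.
#' @param exposure_instruments primary exposure instrument set.
#' @param exposure_sumstats exposure summary statistics for the
#'   multivariable step (lower-powered GWAS when available).
#' @param mediator_instruments named list of Part-III instrument sets.
#' @param mediator_sumstats stacked mediator summary statistics.
#' @param outcome gating outcome summary statistics.
#' @param config a [triangulation_config()].
#' @param mvmr_exposure_instruments optional lower-powered instrument set.
#' @return list with `attenuation` (table), `fits`, `decisions`.
#' @export
part4_attenuation <- function(mediator_ids, exposure_instruments,
                              exposure_sumstats, mediator_instruments,
                              mediator_sumstats, outcome,
                              config = triangulation_config(),
                              mvmr_exposure_instruments = NULL) {
  mediators <- lapply(stats::setNames(mediator_ids, mediator_ids), function(m)
    list(instruments = mediator_instruments[[m]],
         sumstats = mediator_sumstats[mediator_sumstats$trait_id == m, ,
                                      drop = FALSE]))
  scan <- direct_effect_scan(exposure_instruments, exposure_sumstats,
                             mediators, outcome, outcome_type = "binary",
                             mvmr_exposure_instruments = mvmr_exposure_instruments)
  decisions <- do.call(rbind, lapply(mediator_ids, function(m) {
    ok <- m %in% scan$table$mediator
    decision_row("part4", m, ok,
                 if (ok) "passed" else "insufficient_instruments")
  }))
  list(attenuation = scan$table, fits = scan$fits, total = scan$total,
       decisions = decisions)
}

#' Run the full four-part triangulation screen
#'
#' Executes Parts I-IV sequentially on a study bundle, short-circuiting when
#' a stage passes nothing, and returns a fully decision-audited report.
#' Deterministic given the study and configuration (all random substreams
#' derive from `config$seed`).
#'
#' @param study an [generate_study()] bundle, or any list with the same
#'   elements (`exposure`, `mediators`, `outcomes`, optionally
#'   `exposure_lowpower`, `observational`, `ld`).
#' @param config a [triangulation_config()].
#' @return object of class `triangulation_report`: per-stage results,
#'   the complete `decisions` table, the attenuation table, pass lists and
#'   provenance (config digest and seed). The subset-chain invariant
#'   (part4 passes within part3 passes within part2 passes) is checked on
#'   every run.
#' @export
run_triangulation <- function(study, config = triangulation_config()) {
  exposure_instr <- select_instruments(study$exposure,
                                       config$exposure_p_threshold,
                                       ld_info = if (is.null(study$ld))
                                         "assume-independent" else study$ld,
                                       r2_threshold = config$clump_r2)
  if (exposure_instr$status == "empty")
    stop("part1: no exposure instruments pass the selection threshold")

  report <- list(stages = list(), decisions = NULL, attenuation = NULL,
                 passes = list(), short_circuit = NA_character_,
                 provenance = list(seed = config$seed,
                                   config_digest = object_digest(unclass(config))))
  class(report) <- "triangulation_report"

  p1 <- part1_exposure_outcome(list(adiposity = exposure_instr),
                               study$outcomes, study$observational, config)
  report$stages$part1 <- p1
  report$decisions <- p1$decisions
  report$passes$part1 <- p1$passes
  if (length(p1$passes) == 0 || is.null(study$mediators)) {
    report$short_circuit <- "part1"
    return(report)
  }
  gate <- names(study$outcomes)[1]
  xy_sign <- sign0(p1$estimates$theta[p1$estimates$method == "ivw_mre" &
                                        p1$estimates$outcome == gate][1])

  p2 <- part2_exposure_mediators(exposure_instr, study$mediators,
                                 study$observational, config)
  report$stages$part2 <- p2
  report$decisions <- rbind(report$decisions, p2$decisions)
  report$passes$part2 <- p2$passes
  if (length(p2$passes) == 0) {
    report$short_circuit <- "part2"
    return(report)
  }
  xm_signs <- stats::setNames(
    sign0(p2$estimates$theta[match(p2$passes, p2$estimates$mediator)]),
    p2$passes)

  p3 <- part3_mediators_outcome(p2$passes, study$mediators, study$outcomes,
                                xm_signs, xy_sign, study$ld, config)
  report$stages$part3 <- p3
  report$decisions <- rbind(report$decisions, p3$decisions)
  report$passes$part3 <- p3$passes
  if (length(p3$passes) == 0) {
    report$short_circuit <- "part3"
    check_subset_chain(report)
    return(report)
  }

  mv_instr <- NULL
  exposure_ss <- study$exposure
  if (!is.null(study$exposure_lowpower)) {
    exposure_ss <- study$exposure_lowpower
    mv_instr <- suppressWarnings(select_instruments(
      study$exposure_lowpower, config$exposure_p_threshold,
      r2_threshold = config$clump_r2))
    if (mv_instr$status == "empty") mv_instr <- NULL
  }
  p4 <- part4_attenuation(p3$passes, exposure_instr, exposure_ss,
                          p3$instruments, study$mediators,
                          study$outcomes[[gate]], config,
                          mvmr_exposure_instruments = mv_instr)
  report$stages$part4 <- p4
  report$decisions <- rbind(report$decisions, p4$decisions)
  report$passes$part4 <- p4$attenuation$mediator
  report$attenuation <- p4$attenuation
  check_subset_chain(report)
  report
}

check_subset_chain <- function(report) {
  p <- report$passes
  if (!is.null(p$part3) && !all(p$part3 %in% p$part2))
    stop("invariant violated: part3 passes not a subset of part2 passes")
  if (!is.null(p$part4) && !all(p$part4 %in% p$part3))
    stop("invariant violated: part4 passes not a subset of part3 passes")
  invisible(TRUE)
}

#' @export
print.triangulation_report <- function(x, ...) {
  cat("Triangulation report\n")
  for (s in c("part1", "part2", "part3", "part4")) {
    p <- x$passes[[s]]
    if (is.null(p)) next
    cat(sprintf("  %s passes: %s\n", s,
                if (length(p) == 0) "(none)" else paste(p, collapse = ", ")))
  }
  if (!is.na(x$short_circuit))
    cat(sprintf("  short-circuited at %s\n", x$short_circuit))
  if (!is.null(x$attenuation) && nrow(x$attenuation) > 0) {
    cat("  attenuation:\n")
    print(x$attenuation[, c("mediator", "theta_total", "theta_direct",
                            "attenuation", "attenuation_flag")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a triangulation report to stable JSON
#'
#' Timestamp-free, so identical configurations give byte-identical output.
#' @param report a `triangulation_report`.
#' @return JSON string.
#' @export
report_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "mvmr_fit") || inherits(x, "mr_estimate"))
      return(as.data.frame(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  jsonlite::toJSON(strip(unclass(report)), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}
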
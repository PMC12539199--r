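#' Canonical summary-statistics columns
#'
#' `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, `n`, `trait_id`.
#' @keywords internal
sumstats_columns <- c("variant_id", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "pval", "n", "trait_id")

.valid_bases <- c("A", "C", "G", "T")

#' Read GWAS summary statistics from a TSV file
#'
#' Reads a tab-separated file with a header, optionally renaming columns via
#' `column_map`, and validates every row against the field invariants
#' (`se > 0`, `pval` in (0, 1], distinct single-base alleles, `eaf` missing
#' or in (0, 1)). Rows violating an invariant are dropped with a warning
#' naming the row numbers and reasons (available in the `"rejected"`
#' attribute); indels and multi-allelic records are rejected the same way.
#' Missing mandatory columns, unparseable numeric fields and duplicated
#' variant ids within a trait are errors.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names to
#'   file column names, e.g. `c(variant_id = "SNP", pval = "P")`; `NULL` if
#'   the file already uses canonical names.
#' @return a validated data frame of summary statistics.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  df <- read_tsv(path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                     src, canon, path))
      names(df)[names(df) == src] <- canon
    }
  }
  validate_sumstats(df, context = path)
}

#' @rdname read_sumstats
#' @param df a data frame holding summary statistics in canonical columns.
#' @param context label used in messages.
#' @export
validate_sumstats <- function(df, context = "sumstats") {
  missing_cols <- setdiff(setdiff(sumstats_columns, "eaf"), names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing mandatory column(s): %s", context,
                 paste(missing_cols, collapse = ", ")))
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num) &
                   !(is.character(raw) & toupper(raw) %in% c("NA", "INF")))
    if (length(bad) > 0)
      stop(sprintf("%s: unparseable numeric in column '%s' at row(s) %s",
                   context, col, paste(utils::head(bad, 5), collapse = ", ")))
    if (is.character(raw)) num[toupper(raw) == "INF"] <- Inf
    df[[col]] <- num
  }
  df$variant_id <- as.character(df$variant_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(idx, why) reason[idx & is.na(reason)] <<- why
  flag(!(df$effect_allele %in% .valid_bases &
           df$other_allele %in% .valid_bases), "not_biallelic_snp")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(!is.na(df$se) & df$se <= 0, "nonpositive_se")
  flag(is.na(df$se), "missing_se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval_out_of_range")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf_out_of_range")
  flag(is.na(df$beta), "missing_beta")

  bad <- which(!is.na(reason))
  if (length(bad) > 0) {
    warning(sprintf("%s: rejected %d row(s): %s", context, length(bad),
                    paste(sprintf("row %d (%s)", bad, reason[bad]),
                          collapse = "; ")), call. = FALSE)
    rejected <- data.frame(row = bad, variant_id = df$variant_id[bad],
                           reason = reason[bad], stringsAsFactors = FALSE)
    df <- df[-bad, , drop = FALSE]
  } else {
    rejected <- data.frame(row = integer(0), variant_id = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  }
  dup <- df$variant_id[duplicated(paste(df$trait_id, df$variant_id))]
  if (length(dup) > 0)
    stop(sprintf("%s: duplicate variant_id within a trait: %s", context,
                 paste(unique(dup), collapse = ", ")))
  rownames(df) <- NULL
  df <- df[, sumstats_columns]
  attr(df, "rejected") <- rejected
  df
}

#' Write summary statistics to a canonical TSV
#' @param df summary-statistics data frame.
#' @param path output path.
#' @export
write_sumstats <- function(df, path) {
  write_tsv_atomic(df[, sumstats_columns], path)
}

#' Select and clump genetic instruments
#'
#' Filters variants at a p-value threshold, then greedily clumps: the
#' smallest-p unclaimed variant is retained and all unclaimed variants with
#' `r2 >= r2_threshold` against it are discarded; ties at equal p break
#' lexicographically on variant id. Variants with non-finite standard errors
#' (e.g. monomorphic flags) are excluded. Mean instrument strength is
#' `mean((beta/se)^2)` over the retained set.
#'
#' @param records summary-statistics data frame (one trait).
#' @param p_threshold selection threshold (strict `<`); the shipped defaults
#'   elsewhere are 5e-9 for adiposity-like and 5e-8 for metabolite-like
#'   traits.
#' @param ld_info `"assume-independent"` or a data frame `id_a`, `id_b`, `r2`.
#' @param r2_threshold clumping threshold (default 0.001).
#' @return an object of class `instrument_set`: list with `trait_id`,
#'   `variants` (retained rows, selection order), `mean_f`, `p_threshold`,
#'   `r2_threshold`, `status` (`"ok"` or `"empty"`).
#' @export
select_instruments <- function(records, p_threshold,
                               ld_info = "assume-independent",
                               r2_threshold = 0.001) {
  if (length(unique(records$trait_id)) > 1)
    stop("select_instruments expects records for a single trait")
  cand <- records[is.finite(records$se) & records$se > 0 &
                    records$pval < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no variant passes the selection p-value threshold; empty instrument set",
            call. = FALSE)
    return(structure(list(trait_id = records$trait_id[1] %||% NA_character_,
                          variants = cand, mean_f = NA_real_,
                          p_threshold = p_threshold,
                          r2_threshold = r2_threshold, status = "empty"),
                     class = "instrument_set"))
  }
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  if (identical(ld_info, "assume-independent")) {
    kept <- cand
  } else {
    r2 <- function(a, b) {
      hit <- (ld_info$id_a == a & ld_info$id_b == b) |
        (ld_info$id_a == b & ld_info$id_b == a)
      if (any(hit)) max(ld_info$r2[hit]) else 0
    }
    remaining <- cand$variant_id
    kept_ids <- character(0)
    while (length(remaining) > 0) {
      lead <- remaining[1]
      kept_ids <- c(kept_ids, lead)
      remaining <- remaining[-1]
      if (length(remaining) > 0) {
        drop <- vapply(remaining, function(id) r2(lead, id) >= r2_threshold,
                       logical(1))
        remaining <- remaining[!drop]
      }
    }
    kept <- cand[match(kept_ids, cand$variant_id), , drop = FALSE]
  }
  rownames(kept) <- NULL
  structure(list(trait_id = kept$trait_id[1], variants = kept,
                 mean_f = mean((kept$beta / kept$se)^2),
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 status = "ok"),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for '%s': %d variants (p < %g, r2 < %g), mean F = %.1f\n",
              x$trait_id, nrow(x$variants), x$p_threshold, x$r2_threshold,
              x$mean_f))
  invisible(x)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect alleles. Same-orientation
#' pairs are kept; swapped-allele pairs have the outcome beta sign flipped and
#' frequency complemented; palindromic (A/T, C/G) pairs are dropped or
#' frequency-oriented per policy; allele-incompatible pairs and variants
#' absent from the outcome are dropped. Every input variant receives exactly
#' one action.
#'
#' @param exposure an [select_instruments()] result or a summary-statistics
#'   data frame of exposure instruments.
#' @param outcome outcome summary-statistics data frame.
#' @param palindrome_policy `"drop_all"`, or a list
#'   `list(mode = "drop_ambiguous", eaf_window = c(0.42, 0.58))`: palindromic
#'   pairs with missing frequency or exposure frequency inside the window are
#'   dropped; otherwise orientation is inferred from allele frequency.
#' @param outcome_type `"continuous"` or `"binary"` (log-odds outcome);
#'   carried through to the estimators for odds-ratio reporting.
#' @return object of class `harmonized_set`: data frame `data` with columns
#'   `variant_id`, `bx`, `bx_se`, `by`, `by_se`, `action`; `actions` for all
#'   input variants; `exposure_id`, `outcome_id`, `outcome_type`, `n_snp`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = list(mode = "drop_ambiguous",
                                               eaf_window = c(0.42, 0.58)),
                      outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  exp_df <- if (inherits(exposure, "instrument_set")) exposure$variants else exposure
  if (nrow(exp_df) == 0) stop("empty exposure instrument set")
  pol_mode <- if (identical(palindrome_policy, "drop_all")) "drop_all"
  else palindrome_policy$mode %||% "drop_ambiguous"
  window <- if (pol_mode == "drop_ambiguous")
    palindrome_policy$eaf_window %||% c(0.42, 0.58) else c(0, 1)

  idx <- match(exp_df$variant_id, outcome$variant_id)
  n <- nrow(exp_df)
  ea <- exp_df$effect_allele; oa <- exp_df$other_allele
  o_ea <- outcome$effect_allele[idx]; o_oa <- outcome$other_allele[idx]
  o_beta <- outcome$beta[idx]; o_se <- outcome$se[idx]
  o_eaf <- outcome$eaf[idx]
  pal <- is_palindromic(ea, oa)

  action <- rep(NA_character_, n)
  by <- by_se <- rep(NA_real_, n)
  action[is.na(idx)] <- "dropped_missing"

  same <- !is.na(idx) & !pal & o_ea == ea & o_oa == oa
  swap <- !is.na(idx) & !pal & o_ea == oa & o_oa == ea
  action[same] <- "kept"; by[same] <- o_beta[same]; by_se[same] <- o_se[same]
  action[swap] <- "flipped"; by[swap] <- -o_beta[swap]; by_se[swap] <- o_se[swap]
  action[is.na(action) & !is.na(idx) & !pal] <- "dropped_incompatible"

  pidx <- which(pal & !is.na(idx))
  if (length(pidx) > 0) {
    if (pol_mode == "drop_all") {
      action[pidx] <- "dropped_palindromic"
    } else {
      f <- exp_df$eaf[pidx]; fo <- o_eaf[pidx]
      ambiguous <- is.na(f) | is.na(fo) |
        (f > window[1] & f < window[2]) |
        (fo > window[1] & fo < window[2])
      action[pidx[ambiguous]] <- "dropped_palindromic"
      ok <- pidx[!ambiguous]
      # orient by frequency: flip when the two frequencies disagree in side
      flip <- sign(exp_df$eaf[ok] - 0.5) != sign(o_eaf[ok] - 0.5)
      action[ok] <- ifelse(flip, "flipped", "kept")
      by[ok] <- ifelse(flip, -o_beta[ok], o_beta[ok])
      by_se[ok] <- o_se[ok]
    }
  }

  keep <- action %in% c("kept", "flipped")
  data <- data.frame(variant_id = exp_df$variant_id[keep],
                     bx = exp_df$beta[keep], bx_se = exp_df$se[keep],
                     by = by[keep], by_se = by_se[keep],
                     action = action[keep], stringsAsFactors = FALSE)
  if (nrow(data) == 0)
    warning("no variants survived harmonization; empty harmonized set",
            call. = FALSE)
  structure(list(data = data,
                 actions = data.frame(variant_id = exp_df$variant_id,
                                      action = action,
                                      stringsAsFactors = FALSE),
                 exposure_id = exp_df$trait_id[1],
                 outcome_id = outcome$trait_id[1],
                 outcome_type = outcome_type,
                 n_snp = nrow(data)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set %s -> %s: %d variants retained\n",
              x$exposure_id, x$outcome_id, x$n_snp))
  print(table(x$actions$action))
  invisible(x)
}

#' Construct a harmonized set directly from aligned vectors
#'
#' Convenience constructor for already-aligned effect vectors (e.g. in tests
#' and simulations).
#' @param bx,bx_se exposure effects and standard errors.
#' @param by,by_se outcome effects and standard errors.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param variant_id optional ids.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(bx, bx_se, by, by_se,
                           outcome_type = c("continuous", "binary"),
                           variant_id = NULL) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(length(bx) == length(bx_se), length(bx) == length(by),
            length(bx) == length(by_se))
  structure(list(data = data.frame(
    variant_id = variant_id %||% sprintf("v%03d", seq_along(bx)),
    bx = bx, bx_se = bx_se, by = by, by_se = by_se,
    action = "kept", stringsAsFactors = FALSE),
    actions = NULL, exposure_id = "exposure", outcome_id = "outcome",
    outcome_type = outcome_type, n_snp = length(bx)),
    class = "harmonized_set")
}

#' Harmonize several exposures and an outcome for multivariable MR
#'
#' Takes the union of the instruments of K exposures, keeps the variants
#' present in every exposure's summary statistics and in the outcome
#' (intersection policy — absent associations are never imputed as zero),
#' aligns all effects to the first exposure's effect alleles, and drops
#' palindromic pairs per policy.
#'
#' @param instruments list of K [select_instruments()] results.
#' @param exposures list of K full summary-statistics data frames (betas for
#'   the instrument union on each exposure).
#' @param outcome outcome summary-statistics data frame.
#' @inheritParams harmonize
#' @return object of class `harmonized_mvmr`: matrices `bx`, `bx_se`
#'   (L x K), vectors `by`, `by_se`, `variant_id`, `exposure_ids`,
#'   `outcome_type`, `n_snp`, plus per-variant `actions`.
#' @export
harmonize_mvmr <- function(instruments, exposures, outcome,
                           palindrome_policy = list(mode = "drop_ambiguous",
                                                    eaf_window = c(0.42, 0.58)),
                           outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(length(instruments) == length(exposures), length(exposures) >= 1)
  k <- length(exposures)
  exposure_ids <- vapply(exposures, function(e) e$trait_id[1], character(1))
  union_ids <- unique(unlist(lapply(instruments, function(s) {
    df <- if (inherits(s, "instrument_set")) s$variants else s
    df$variant_id
  })))
  ref <- exposures[[1]]
  action <- stats::setNames(rep("kept", length(union_ids)), union_ids)

  present <- vapply(union_ids, function(id) {
    all(vapply(exposures, function(e) id %in% e$variant_id, logical(1))) &&
      id %in% outcome$variant_id
  }, logical(1))
  action[!present] <- "dropped_missing"

  ids <- union_ids[present]
  ridx <- match(ids, ref$variant_id)
  pal <- is_palindromic(ref$effect_allele[ridx], ref$other_allele[ridx])
  pol_mode <- if (identical(palindrome_policy, "drop_all")) "drop_all"
  else palindrome_policy$mode %||% "drop_ambiguous"
  window <- palindrome_policy$eaf_window %||% c(0.42, 0.58)
  if (pol_mode == "drop_all") {
    action[ids[pal]] <- "dropped_palindromic"
  } else {
    amb <- pal & (is.na(ref$eaf[ridx]) |
                    (ref$eaf[ridx] > window[1] & ref$eaf[ridx] < window[2]))
    action[ids[amb]] <- "dropped_palindromic"
  }
  ids <- ids[action[ids] == "kept"]

  align <- function(df, id, ref_row) {
    r <- df[match(id, df$variant_id), ]
    if (r$effect_allele == ref_row$effect_allele &&
        r$other_allele == ref_row$other_allele)
      return(c(r$beta, r$se))
    if (r$effect_allele == ref_row$other_allele &&
        r$other_allele == ref_row$effect_allele)
      return(c(-r$beta, r$se))
    if (is_palindromic(r$effect_allele, r$other_allele) &&
        is_palindromic(ref_row$effect_allele, ref_row$other_allele)) {
      flip <- sign(r$eaf - 0.5) != sign(ref_row$eaf - 0.5)
      return(c(if (flip) -r$beta else r$beta, r$se))
    }
    c(NA_real_, NA_real_)
  }

  L <- length(ids)
  bx <- bx_se <- matrix(NA_real_, L, k,
                        dimnames = list(ids, exposure_ids))
  by <- by_se <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    ref_row <- ref[match(ids[i], ref$variant_id), ]
    for (kk in seq_len(k)) {
      ab <- align(exposures[[kk]], ids[i], ref_row)
      bx[i, kk] <- ab[1]; bx_se[i, kk] <- ab[2]
    }
    ob <- align(outcome, ids[i], ref_row)
    by[i] <- ob[1]; by_se[i] <- ob[2]
  }
  bad <- apply(is.na(bx), 1, any) | is.na(by)
  if (any(bad)) {
    action[ids[bad]] <- "dropped_incompatible"
    keep <- !bad
    bx <- bx[keep, , drop = FALSE]; bx_se <- bx_se[keep, , drop = FALSE]
    by <- by[keep]; by_se <- by_se[keep]; ids <- ids[keep]
  }
  if (length(ids) == 0)
    warning("no variants survived multivariable harmonization", call. = FALSE)
  structure(list(bx = bx, bx_se = bx_se, by = by, by_se = by_se,
                 variant_id = ids, exposure_ids = exposure_ids,
                 outcome_id = outcome$trait_id[1],
                 outcome_type = outcome_type, n_snp = length(ids),
                 actions = data.frame(variant_id = union_ids,
                                      action = unname(action[union_ids]),
                                      stringsAsFactors = FALSE)),
            class = "harmonized_mvmr")
}
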
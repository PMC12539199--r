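#' Count catalogued trait associations of an instrument set
#'
#' A variant counts once towards a trait when any catalogue row for that
#' (variant, trait) pair has `pval < p_threshold` (strict, so a row at
#' exactly the threshold is excluded). Per-domain counts aggregate distinct
#' variants across the domain's traits.
#'
#' @param instrument_ids character vector of variant ids (non-empty).
#' @param catalogue data frame with columns `variant_id`, `trait`, `domain`,
#'   `pval`.
#' @param p_threshold lookup threshold in (0, 1); default 1e-10.
#' @return list with `trait_counts` (trait, domain, count) and
#'   `domain_counts` (domain, count), including zero rows for catalogued
#'   traits with no hits.
#' @export
count_associations <- function(instrument_ids, catalogue,
                               p_threshold = 1e-10) {
  if (length(instrument_ids) == 0) stop("empty instrument list")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0, 1)")
  traits <- unique(catalogue[, c("trait", "domain")])
  traits <- traits[order(traits$trait), , drop = FALSE]
  hits <- catalogue[catalogue$variant_id %in% instrument_ids &
                      catalogue$pval < p_threshold, , drop = FALSE]
  tc <- vapply(traits$trait, function(tr)
    length(unique(hits$variant_id[hits$trait == tr])), integer(1))
  domains <- sort(unique(traits$domain))
  dc <- vapply(domains, function(d)
    length(unique(hits$variant_id[hits$domain == d])), integer(1))
  list(trait_counts = data.frame(trait = traits$trait,
                                 domain = traits$domain,
                                 count = unname(tc),
                                 stringsAsFactors = FALSE, row.names = NULL),
       domain_counts = data.frame(domain = domains, count = unname(dc),
                                  stringsAsFactors = FALSE, row.names = NULL))
}

#' Off-target enrichment scan against a random-metabolite null
#'
#' Compares the phenome-catalogue association profile of the signal
#' metabolites' pooled instruments with a null distribution built by
#' redrawing, `n_iter` times, the same number of metabolites uniformly
#' without replacement from the non-signal pool and pooling their
#' instruments (the redraw unit is the metabolite, preserving per-metabolite
#' instrument structure). Empirical p-values use the add-one rule
#' `(1 + #\{null >= observed\}) / (n_iter + 1)`. Proportions (counts divided
#' by the instrument-set size) are reported alongside counts since redraw
#' sets may differ in instrument number.
#'
#' @param signal_mediators character vector of signal metabolite ids.
#' @param pool_mediators character vector of non-signal metabolite ids
#'   (disjoint from the signal set, at least as many).
#' @param instruments named list mapping every metabolite id to its
#'   instrument variant ids.
#' @param catalogue phenome catalogue data frame.
#' @param p_threshold lookup threshold (default 1e-10).
#' @param n_iter number of redraws (default 100).
#' @param seed redraw seed (deterministic given seed and inputs).
#' @return object of class `enrichment_result`: `traits` and `domains`
#'   tables (observed count/proportion, null mean/sd, mean null proportion,
#'   empirical p), `null_counts` (traits x n_iter matrix), `n_iter`,
#'   `p_threshold`, `n_signal_instruments`.
#' @export
enrichment_scan <- function(signal_mediators, pool_mediators, instruments,
                            catalogue, p_threshold = 1e-10, n_iter = 100L,
                            seed = 1L) {
  if (length(intersect(signal_mediators, pool_mediators)) > 0)
    stop("signal and pool metabolite sets must be disjoint")
  if (length(pool_mediators) < length(signal_mediators))
    stop("pool smaller than the signal set; cannot redraw")
  missing_instr <- setdiff(c(signal_mediators, pool_mediators),
                           names(instruments))
  if (length(missing_instr) > 0)
    stop("no instruments for: ", paste(missing_instr, collapse = ", "))

  sig_ids <- unique(unlist(instruments[signal_mediators]))
  obs <- count_associations(sig_ids, catalogue, p_threshold)
  traits <- obs$trait_counts$trait
  domains <- obs$domain_counts$domain

  null_counts <- matrix(0L, length(traits), n_iter,
                        dimnames = list(traits, NULL))
  null_dom <- matrix(0L, length(domains), n_iter,
                     dimnames = list(domains, NULL))
  null_prop <- matrix(0, length(traits), n_iter)
  null_dom_prop <- matrix(0, length(domains), n_iter)
  with_seed(derive_seed(seed, "enrichment_redraws"), {
    for (b in seq_len(n_iter)) {
      draw <- sample(pool_mediators, length(signal_mediators))
      ids <- unique(unlist(instruments[draw]))
      cb <- count_associations(ids, catalogue, p_threshold)
      null_counts[, b] <- cb$trait_counts$count
      null_dom[, b] <- cb$domain_counts$count
      null_prop[, b] <- cb$trait_counts$count / length(ids)
      null_dom_prop[, b] <- cb$domain_counts$count / length(ids)
    }
  })
  emp_p <- function(observed, null_mat)
    (1 + rowSums(null_mat >= observed)) / (n_iter + 1)

  traits_tab <- data.frame(
    trait = traits, domain = obs$trait_counts$domain,
    observed_count = obs$trait_counts$count,
    observed_prop = obs$trait_counts$count / length(sig_ids),
    null_mean = rowMeans(null_counts),
    null_sd = apply(null_counts, 1, stats::sd),
    null_mean_prop = rowMeans(null_prop),
    empirical_p = emp_p(obs$trait_counts$count, null_counts),
    stringsAsFactors = FALSE, row.names = NULL)
  domains_tab <- data.frame(
    domain = domains,
    observed_count = obs$domain_counts$count,
    observed_prop = obs$domain_counts$count / length(sig_ids),
    null_mean = rowMeans(null_dom),
    null_sd = apply(null_dom, 1, stats::sd),
    null_mean_prop = rowMeans(null_dom_prop),
    empirical_p = emp_p(obs$domain_counts$count, null_dom),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(traits = traits_tab, domains = domains_tab,
                 null_counts = null_counts, n_iter = n_iter,
                 p_threshold = p_threshold,
                 n_signal_instruments = length(sig_ids)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Off-target enrichment scan: %d signal instruments, %d redraws, p < %g\n",
              x$n_signal_instruments, x$n_iter, x$p_threshold))
  print(utils::head(top_traits_report(x, 10), 10), row.names = FALSE)
  invisible(x)
}

#' Ranked table of most-enriched traits
#'
#' Traits ranked by observed proportion minus mean null proportion
#' (descending); ties broken by empirical p, then trait name.
#'
#' @param result an `enrichment_result`.
#' @param k maximum rows (>= 1).
#' @return data frame of at most `k` rows with an `excess_prop` column.
#' @export
top_traits_report <- function(result, k = 30L) {
  if (k < 1) stop("k must be at least 1")
  tab <- result$traits
  if (is.null(tab) || nrow(tab) == 0) return(data.frame(trait = character(0)))
  tab$excess_prop <- tab$observed_prop - tab$null_mean_prop
  tab <- tab[order(-tab$excess_prop, tab$empirical_p, tab$trait), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, k)
}
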
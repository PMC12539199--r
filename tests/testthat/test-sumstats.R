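write_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("reading validates rows, maps columns and round-trips losslessly", {
  good <- make_sumstats(3)
  p <- write_fixture(good)
  got <- read_sumstats(p)
  expect_equal(nrow(got), 3)
  expect_equal(got$beta, good$beta, tolerance = 1e-12)

  # column mapping
  renamed <- good
  names(renamed)[names(renamed) == "pval"] <- "P"
  p2 <- write_fixture(renamed)
  got2 <- read_sumstats(p2, column_map = c(pval = "P"))
  expect_equal(got2$pval, good$pval, tolerance = 1e-12)

  # write -> read round trip
  p3 <- tempfile(fileext = ".tsv")
  write_sumstats(got, p3)
  again <- read_sumstats(p3)
  expect_equal(again, got, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("invalid rows are rejected with reasons; structural problems are errors", {
  bad <- make_sumstats(5)
  bad$se[2] <- 0                      # nonpositive SE
  bad$effect_allele[3] <- "AT"        # indel
  bad$pval[4] <- 1.5                  # out of range
  p <- write_fixture(bad)
  expect_warning(got <- read_sumstats(p), "rejected 3 row")
  expect_equal(nrow(got), 2)
  rej <- attr(got, "rejected")
  expect_setequal(rej$reason, c("nonpositive_se", "not_biallelic_snp",
                                "pval_out_of_range"))
  # duplicate id within a trait
  dup <- make_sumstats(3)
  dup$variant_id[2] <- dup$variant_id[1]
  expect_error(read_sumstats(write_fixture(dup)), "duplicate")
  # missing mandatory column
  nocol <- make_sumstats(3)
  nocol$se <- NULL
  expect_error(read_sumstats(write_fixture(nocol)), "missing mandatory")
  # unparseable numeric
  txt <- make_sumstats(3)
  txt$beta <- as.character(txt$beta)
  txt$beta[2] <- "oops"
  expect_error(read_sumstats(write_fixture(txt)), "unparseable")
})

test_that("instrument selection filters by p and computes mean F", {
  rec <- make_sumstats(3)
  rec$pval <- c(1e-10, 1e-9, 0.01)
  sel <- select_instruments(rec, 5e-9)
  expect_equal(nrow(sel$variants), 2)
  # mean F from (beta/se) = (6, 8): (36 + 64) / 2 = 50
  rec2 <- make_sumstats(2)
  rec2$beta <- c(0.6, 0.8); rec2$se <- c(0.1, 0.1)
  rec2$pval <- c(1e-10, 1e-12)
  expect_equal(select_instruments(rec2, 5e-8)$mean_f, 50)
  # empty selection is an explicit status, not silence
  expect_warning(empty <- select_instruments(rec, 1e-30), "no variant")
  expect_identical(empty$status, "empty")
})

test_that("greedy clumping keeps the smaller-p variant of a correlated pair", {
  rec <- make_sumstats(2)
  rec$pval <- c(1e-9, 1e-12)
  ld <- data.frame(id_a = rec$variant_id[1], id_b = rec$variant_id[2],
                   r2 = 0.5)
  sel <- select_instruments(rec, 5e-8, ld_info = ld, r2_threshold = 0.001)
  expect_equal(sel$variants$variant_id, rec$variant_id[2])
})

test_that("greedy clumping equals brute force over maximal independent sets", {
  # brute force: enumerate maximal independent sets in the r2 >= threshold
  # graph; choose the one whose sorted (p, id) sequence is lexicographically
  # smallest under the selection ordering
  brute_clump <- function(rec, ld, thr) {
    n <- nrow(rec)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(nrow(ld))) {
      a <- match(ld$id_a[i], rec$variant_id)
      b <- match(ld$id_b[i], rec$variant_id)
      if (!is.na(a) && !is.na(b) && ld$r2[i] >= thr)
        adj[a, b] <- adj[b, a] <- TRUE
    }
    ord <- order(rec$pval, rec$variant_id)
    rank_of <- integer(n); rank_of[ord] <- seq_len(n)
    best <- NULL; best_key <- NULL
    for (mask in seq_len(2^n) - 1L) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) == 0) next
      if (any(adj[idx, idx])) next
      outside <- setdiff(seq_len(n), idx)
      maximal <- all(vapply(outside, function(o) any(adj[o, idx]),
                            logical(1)))
      if (!maximal) next
      key <- sort(rank_of[idx])
      length(key) <- n            # pad so shorter prefixes compare last
      key[is.na(key)] <- n + 1L
      less_key <- function(a, b) {
        d <- which(a != b)
        length(d) > 0 && a[d[1]] < b[d[1]]
      }
      if (is.null(best_key) || less_key(key, best_key)) {
        best <- idx; best_key <- key
      }
    }
    sort(rec$variant_id[best])
  }
  for (s in 1:5) {
    set.seed(600 + s)
    n <- 8
    rec <- make_sumstats(n, seed = 600 + s)
    rec$pval <- runif(n, 1e-12, 1e-9)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.3
    ld <- data.frame(id_a = rec$variant_id[pairs[keep, 1]],
                     id_b = rec$variant_id[pairs[keep, 2]],
                     r2 = runif(sum(keep), 0.2, 0.9))
    sel <- select_instruments(rec, 5e-8, ld_info = ld, r2_threshold = 0.1)
    expect_setequal(sel$variants$variant_id, brute_clump(rec, ld, 0.1))
  }
})

test_that("harmonization keeps, flips and drops per the allele rules", {
  ex <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   effect_allele = c("A", "A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "G", "C"),
                   eaf = c(0.3, 0.3, 0.50, 0.3, 0.3),
                   beta = rep(0.1, 5), se = rep(0.01, 5),
                   pval = rep(1e-10, 5), n = 1000L, trait_id = "x",
                   stringsAsFactors = FALSE)
  out <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                    effect_allele = c("A", "G", "A", "C"),
                    other_allele = c("G", "A", "T", "T"),
                    eaf = c(0.3, 0.7, 0.5, 0.4),
                    beta = c(0.05, 0.05, 0.02, 0.01),
                    se = rep(0.01, 4), pval = rep(0.01, 4), n = 1000L,
                    trait_id = "y", stringsAsFactors = FALSE)
  h <- harmonize(ex, out)
  acts <- setNames(h$actions$action, h$actions$variant_id)
  expect_identical(unname(acts[c("rs1", "rs2", "rs3", "rs4", "rs5")]),
                   c("kept", "flipped", "dropped_palindromic",
                     "dropped_incompatible", "dropped_missing"))
  expect_equal(h$data$by[h$data$variant_id == "rs1"], 0.05)
  expect_equal(h$data$by[h$data$variant_id == "rs2"], -0.05)
  # every input variant receives exactly one action
  expect_equal(nrow(h$actions), 5)
  expect_false(any(is.na(h$actions$action)))
})

test_that("palindromic variants orient by frequency outside the ambiguity window", {
  ex <- data.frame(variant_id = c("rs1", "rs2"), effect_allele = "A",
                   other_allele = "T", eaf = c(0.2, 0.2), beta = 0.1,
                   se = 0.01, pval = 1e-10, n = 1000L, trait_id = "x",
                   stringsAsFactors = FALSE)
  out <- data.frame(variant_id = c("rs1", "rs2"), effect_allele = "A",
                    other_allele = "T", eaf = c(0.22, 0.81), beta = 0.05,
                    se = 0.01, pval = 0.01, n = 1000L, trait_id = "y",
                    stringsAsFactors = FALSE)
  h <- harmonize(ex, out)
  expect_equal(h$data$by, c(0.05, -0.05))
  # drop_all policy removes them regardless
  expect_warning(h2 <- harmonize(ex, out, palindrome_policy = "drop_all"),
                 "no variants survived")
  expect_equal(h2$n_snp, 0)
})

test_that("harmonization is idempotent and orientation-invariant", {
  ex <- make_sumstats(6, trait = "x", seed = 8)
  out <- make_sumstats(6, trait = "y", seed = 9)
  out$effect_allele <- ex$effect_allele
  out$other_allele <- ex$other_allele
  out$eaf <- ex$eaf
  h1 <- harmonize(ex, out)
  expect_true(all(h1$actions$action == "kept"))
  # flipping both alleles and the beta sign of an outcome row changes nothing
  out2 <- out
  out2$effect_allele[2] <- out$other_allele[2]
  out2$other_allele[2] <- out$effect_allele[2]
  out2$beta[2] <- -out$beta[2]
  out2$eaf[2] <- 1 - out$eaf[2]
  h2 <- harmonize(ex, out2)
  expect_equal(h2$data$by, h1$data$by, tolerance = 1e-15)
})

test_that("multivariable harmonization intersects and aligns to the first exposure", {
  ex1 <- make_sumstats(6, trait = "x", seed = 10)
  ex2 <- make_sumstats(5, trait = "m", seed = 11)
  ex2$effect_allele <- ex1$effect_allele[1:5]
  ex2$other_allele <- ex1$other_allele[1:5]
  out <- make_sumstats(6, trait = "y", seed = 12)
  out$effect_allele <- ex1$effect_allele
  out$other_allele <- ex1$other_allele
  # swap outcome alleles for one variant; its by must come back sign-flipped
  out$effect_allele[3] <- ex1$other_allele[3]
  out$other_allele[3] <- ex1$effect_allele[3]
  i1 <- select_instruments(ex1, 1)
  i2 <- select_instruments(ex2, 1)
  h <- harmonize_mvmr(list(i1, i2), list(ex1, ex2), out)
  expect_equal(h$n_snp, 5)   # rs6 missing from exposure 2
  expect_equal(ncol(h$bx), 2)
  v3 <- match(ex1$variant_id[3], h$variant_id)
  expect_equal(h$by[v3], -out$beta[3])
})
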
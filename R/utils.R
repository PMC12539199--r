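#' @keywords internal
"_PACKAGE"

# Deterministic substream seed from a master seed and a text label.
# Keeps the result strictly below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 1009)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Two-sided p from the normal approximation; clamped into (0, 1].
norm_pval <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z)] <- .Machine$double.xmin
  pmax(p, .Machine$double.xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
}

# Write a table atomically (temp file + rename) so partial runs never leave
# truncated outputs behind.
write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Stable md5 of an R object's JSON serialization, used for run provenance.
object_digest <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
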
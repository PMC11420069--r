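#' @keywords internal
"_PACKAGE"

# days per month, non-leap year (monthly climatology has no leap days)
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# CO2 mass per unit carbon mass
CO2_PER_C <- 44 / 12

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a reproducible child seed (< 2^31) from a root seed and a tag
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}

# serialize doubles so that read.csv() recovers them bit-for-bit
fmt_full <- function(x) {
  if (is.double(x)) formatC(x, digits = 17, format = "g") else x
}

write_table_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt_full(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

stop_parse <- function(file, row, col, msg) {
  stop(sprintf("%s: row %d, column '%s': %s", file, row, col, msg), call. = FALSE)
}

# first row/column failing `bad` predicate triggers a parse error
check_nonneg <- function(df, cols, file) {
  for (col in cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0)
      stop_parse(file, bad[1], col, sprintf("negative or non-finite value (%s)",
                 format(df[[col]][bad[1]])))
  }
  invisible(TRUE)
}
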
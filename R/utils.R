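# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so no hidden global randomness leaks.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed < 2^31 from a base seed and a stream tag.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103515245 + stream * 12345) %% 2147483647
}

# Write a data.frame as deterministic TSV (fixed numeric formatting so that
# identical inputs give byte-identical files).
write_tsv <- function(df, path, digits = 10) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = digits, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
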
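# Internal helpers shared across modules.

# Canonical unordered-pair key; gene IDs must not contain "\r".
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# One metadata comment line for TSV outputs (no timestamps: outputs must be
# byte-identical across reruns with the same inputs).
outputHeader <- function(params = character()) {
  v <- as.character(utils::packageVersion("mgcMiner"))
  extra <- if (length(params))
    paste0(" ", paste(names(params), unname(params), sep = "=", collapse = " "))
  else ""
  sprintf("# mgcMiner %s%s", v, extra)
}

writeTsv <- function(df, path, params = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(outputHeader(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
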
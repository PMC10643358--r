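# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Provenance header written at the top of every output file.
provenance_line <- function(params = list()) {
  ver <- as.character(utils::packageVersion("landqtl"))
  ps <- if (length(params))
    paste(names(params), vapply(params, function(x)
      paste(format(x), collapse = ","), ""), sep = "=", collapse = " ")
  else ""
  paste0("# landqtl v", ver, if (nzchar(ps)) paste0(" | ", ps))
}

write_tsv_prov <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_line(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
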
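# write via a temp file in the destination directory, then rename, so a
# failed run never leaves a partial output file
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file onto ", sQuote(path), call. = FALSE)
  }
  invisible(path)
}

# stable TSV output: "." decimal separator, 6 significant digits
write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 6))
  atomic_write(path, function(tmp) {
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
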
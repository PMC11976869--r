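# Write a data frame as TSV with an optional leading "#" comment block
# (parameter echo), header row, no quoting of plain fields.
write_tsv_commented <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments) && length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# One-line echo of a DigestConfig / rule for provenance comments.
echo_params <- function(...) {
  args <- list(...)
  vapply(names(args), function(nm) paste0(nm, "=", args[[nm]]),
         character(1), USE.NAMES = FALSE)
}
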
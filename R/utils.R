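# Shared internal helpers: error signalling and code normalisation.

stop_validation <- function(msg, ...) {
  abort(msg, class = "ffqscore_validation_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "ffqscore_io_error", ...)
}

stop_stat <- function(msg, ...) {
  abort(msg, class = "ffqscore_stat_error", ...)
}

# Answer codes are case-insensitive; whitespace is trimmed on read.
norm_code <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Write a tibble as CSV with '#'-prefixed provenance header lines.
write_csv_prov <- function(df, path, provenance = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance) > 0) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path, ...) {
  if (!file.exists(path)) {
    stop_io(sprintf("file not found: %s", path))
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

provenance_header <- function(schema_id = NA, reference = NA, seed = NA) {
  c(
    sprintf("ffqscore %s", as.character(utils::packageVersion("ffqscore"))),
    sprintf("schema: %s", schema_id),
    sprintf("reference: %s", reference),
    sprintf("seed: %s", seed),
    sprintf("generated: %s", "run-time")
  )
}
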
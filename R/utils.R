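# run code under a locally-seeded RNG, restoring the caller's stream after
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# header comment written at the top of output files, so reruns are auditable
.output_header <- function(seed = NULL, command = NULL) {
  c(paste0("# lingedge ",
           as.character(utils::packageVersion("lingedge"))),
    if (!is.null(command)) paste0("# command: ", command),
    if (!is.null(seed)) paste0("# seed: ", seed))
}

# write a data frame as CSV with an audit header
.write_csv_with_header <- function(df, file, seed = NULL, command = NULL) {
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.output_header(seed, command), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
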
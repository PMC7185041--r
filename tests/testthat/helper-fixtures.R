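# Small in-code fixtures shared across test files.

# a capture data.frame in the canonical (post-read) layout
make_captures <- function(band_id, species_code, station_id, date, age) {
  x <- data.frame(band_id = band_id, species_code = species_code,
                  station_id = station_id, date = as.Date(date), age = age,
                  stringsAsFactors = FALSE)
  x$year <- as.integer(format(x$date, "%Y"))
  x <- x[order(x$band_id, x$year, x$date), ]
  key <- paste(x$band_id, x$year)
  x$capture_index <- stats::ave(seq_len(nrow(x)), key, FUN = seq_along)
  rownames(x) <- NULL
  x
}

# write a raw capture CSV (pre-read layout) and return the path
write_raw_captures <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a small, fast generator configuration for unit tests (not the study-scale
# default); used where only mechanics, not effect sizes, are under test
tiny_config <- function(...) {
  args <- list(n_natural = 3, n_disturbed = 3, n_reclaimed = 2, n_years = 3,
               n_species = 5, mean_captures = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

table1 <- community_table()
totals <- study_totals()
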
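#' Default column mapping for capture files
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in a delimited capture export. Override entries to adapt
#' MAPS-dialect exports without editing the file.
#'
#' @param band_id,species_code,station_id,date,age column names in the file.
#' @return named character vector (canonical name -> file column name).
#' @export
capture_schema <- function(band_id = "band_id", species_code = "species_code",
                           station_id = "station_id", date = "date",
                           age = "age") {
  c(band_id = band_id, species_code = species_code, station_id = station_id,
    date = date, age = age)
}

#' Read and validate banding capture records
#'
#' Reads a delimited capture file (header + ISO-8601 dates), validates it
#' against the four-code age vocabulary ([age_classes()]), and returns one
#' row per capture event. Rows with unrecognized age codes or unparseable
#' dates are dropped and counted in the parse report (attribute
#' `"parse_report"`, also emitted as a message). A `capture_index` ordinal is
#' assigned within each band-year by date and file order.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema named vector from [capture_schema()] mapping canonical names
#'   to file columns.
#' @param years optional integer vector; records outside this study window
#'   are dropped (counted in the report).
#' @param sep field separator (default comma).
#' @param quiet suppress the parse-report message.
#' @return data.frame of validated captures with columns `band_id`,
#'   `species_code`, `station_id`, `year`, `date`, `age`, `capture_index`,
#'   carrying a `"parse_report"` attribute.
#' @export
read_captures <- function(path, schema = capture_schema(), years = NULL,
                          sep = ",", quiet = FALSE) {
  if (!file.exists(path)) abort("capture file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(raw) == 0L) abort("capture file is empty: ", path)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols))
    abort("capture file lacks required column(s): ",
          paste(missing_cols, collapse = ", "))

  x <- data.frame(
    band_id      = as.character(raw[[schema[["band_id"]]]]),
    species_code = toupper(as.character(raw[[schema[["species_code"]]]])),
    station_id   = as.character(raw[[schema[["station_id"]]]]),
    age          = toupper(trimws(as.character(raw[[schema[["age"]]]]))),
    stringsAsFactors = FALSE
  )
  x$date <- as.Date(as.character(raw[[schema[["date"]]]]), format = "%Y-%m-%d")

  n_read <- nrow(x)
  bad_age <- !(x$age %in% age_classes())
  bad_date <- is.na(x$date)
  keep <- !bad_age & !bad_date
  x <- x[keep, , drop = FALSE]
  x$year <- as.integer(format(x$date, "%Y"))
  n_window <- 0L
  if (!is.null(years)) {
    in_window <- x$year %in% as.integer(years)
    n_window <- sum(!in_window)
    x <- x[in_window, , drop = FALSE]
  }
  if (nrow(x) == 0L) abort("no valid capture records after validation: ", path)

  # ordinal within band-year, by date then original file order
  x <- x[order(x$band_id, x$year, x$date), , drop = FALSE]
  key <- paste(x$band_id, x$year)
  x$capture_index <- stats::ave(seq_len(nrow(x)), key, FUN = seq_along)
  rownames(x) <- NULL
  x <- x[, c("band_id", "species_code", "station_id", "year", "date", "age",
             "capture_index")]

  report <- list(n_read = n_read, n_kept = nrow(x),
                 n_dropped_bad_age = sum(bad_age),
                 n_dropped_bad_date = sum(bad_date & !bad_age),
                 n_dropped_out_of_window = n_window)
  attr(x, "parse_report") <- report
  if (!quiet)
    message(sprintf(
      "read_captures: %d rows read, %d kept (%d bad age, %d bad date, %d outside window)",
      report$n_read, report$n_kept, report$n_dropped_bad_age,
      report$n_dropped_bad_date, report$n_dropped_out_of_window))
  x
}

#' Write capture records back to CSV
#'
#' Inverse of [read_captures()] for the canonical schema; used for
#' round-tripping generator output.
#'
#' @param records capture data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(records, path) {
  out <- records[, c("band_id", "species_code", "station_id", "date", "age")]
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse capture events to year-unique individuals
#'
#' One banded bird contributes one analysis row per calendar year in which it
#' was captured (a "year-unique individual"); birds recaptured in later years
#' are counted again in those years. The resolved age class for a band-year
#' is determinate (SY or ASY) if any capture that year carried a determinate
#' determination; when both SY and ASY were recorded within the same year
#' (a within-year conflict) the latest determination by date wins, since
#' later determinations reflect photographic review of earlier field calls.
#' Band-years with only AHY determinations resolve to AHY. Band-years
#' consisting solely of HY (juvenile) captures are excluded here — adult age
#' structure is defined on SY/ASY/AHY birds only.
#'
#' Station and species are attributed from the first capture of the year
#' (by date, then capture order).
#'
#' @param records validated capture data.frame from [read_captures()].
#' @return data.frame with columns `band_id`, `species_code`, `station_id`,
#'   `year`, `resolved_age`, one row per band-year, with attribute
#'   `"conflict_report"` (count and band-years of within-year SY/ASY
#'   conflicts).
#' @export
resolve_year_unique <- function(records) {
  stopifnot(all(c("band_id", "year", "age") %in% names(records)))
  ord <- order(records$band_id, records$year, records$date,
               records$capture_index)
  x <- records[ord, , drop = FALSE]
  key <- paste(x$band_id, x$year, sep = "\r")
  grp <- split(seq_len(nrow(x)), factor(key, levels = unique(key)))

  rows <- lapply(grp, function(ii) {
    ages <- x$age[ii]
    adult <- ages != "HY"
    if (!any(adult)) return(NULL)            # HY-only band-year: excluded
    det <- which(adult & ages %in% .determinate)
    conflict <- length(unique(ages[det])) > 1L
    resolved <- if (length(det)) ages[det[length(det)]] else "AHY"
    first <- ii[which(adult)[1L]]
    data.frame(band_id = x$band_id[first], species_code = x$species_code[first],
               station_id = x$station_id[first], year = x$year[first],
               resolved_age = resolved, conflict = conflict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(band_id = character(), species_code = character(),
                      station_id = character(), year = integer(),
                      resolved_age = character(), conflict = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  conflicts <- out[out$conflict, c("band_id", "year")]
  out$conflict <- NULL
  attr(out, "conflict_report") <- list(n_conflicts = nrow(conflicts),
                                       conflicts = conflicts)
  out
}

#' Select target species by mean annual adult sample size
#'
#' A species enters the community analysis when its mean number of adult
#' year-unique individuals (SY, ASY and AHY combined) per study year meets
#' the threshold.
#'
#' @param individuals year-unique data.frame from [resolve_year_unique()].
#' @param n_years number of study years over which to average.
#' @param min_mean_per_year inclusion threshold (default 20 birds/year).
#' @return sorted character vector of retained species codes.
#' @export
filter_target_species <- function(individuals, n_years,
                                  min_mean_per_year = 20) {
  stopifnot(n_years >= 1)
  counts <- table(individuals$species_code)
  sort(names(counts)[counts / n_years >= min_mean_per_year])
}

#' Per-species sample summaries
#'
#' Counts of year-unique individuals by resolved age class, and the number
#' of stations at which each species was captured.
#'
#' @param individuals year-unique data.frame from [resolve_year_unique()].
#' @return data.frame with columns `species_code`, `n_stations`,
#'   `n_year_inds`, `n_SY`, `n_ASY`, `n_AHY`, one row per species, sorted by
#'   species code.
#' @export
summarize_species <- function(individuals) {
  if (nrow(individuals) == 0L)
    return(data.frame(species_code = character(), n_stations = integer(),
                      n_year_inds = integer(), n_SY = integer(),
                      n_ASY = integer(), n_AHY = integer(),
                      stringsAsFactors = FALSE))
  sp <- sort(unique(individuals$species_code))
  tab <- function(age) {
    cnt <- table(factor(individuals$species_code[individuals$resolved_age == age],
                        levels = sp))
    as.integer(cnt)
  }
  n_sta <- vapply(sp, function(s)
    length(unique(individuals$station_id[individuals$species_code == s])), 1L)
  out <- data.frame(
    species_code = sp,
    n_stations = as.integer(n_sta),
    n_year_inds = as.integer(table(factor(individuals$species_code, levels = sp))),
    n_SY = tab("SY"), n_ASY = tab("ASY"), n_AHY = tab("AHY"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
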
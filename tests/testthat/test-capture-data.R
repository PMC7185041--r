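test_that("read_captures validates, drops bad rows, and reports", {
  raw <- data.frame(
    band_id = c("B1", "B2", "B3"), species_code = c("TEWA", "TEWA", "REVI"),
    station_id = "ST01", date = c("2012-06-10", "2012-06-20", "2012-07-01"),
    age = c("SY", "ASY", "AHY"))
  p <- write_raw_captures(raw)
  x <- read_captures(p, quiet = TRUE)
  expect_equal(nrow(x), 3L)
  expect_equal(attr(x, "parse_report")$n_kept, 3L)
  expect_equal(x$year, rep(2012L, 3))

  raw2 <- rbind(raw, data.frame(band_id = "B4", species_code = "TEWA",
                                station_id = "ST01", date = "2012-06-11",
                                age = "UNK"))
  x2 <- read_captures(write_raw_captures(raw2), quiet = TRUE)
  expect_equal(nrow(x2), 3L)
  expect_equal(attr(x2, "parse_report")$n_dropped_bad_age, 1L)

  raw3 <- rbind(raw, data.frame(band_id = "B5", species_code = "TEWA",
                                station_id = "ST01", date = "not-a-date",
                                age = "SY"))
  x3 <- read_captures(write_raw_captures(raw3), quiet = TRUE)
  expect_equal(attr(x3, "parse_report")$n_dropped_bad_date, 1L)

  # missing required column and empty file are hard errors
  p_bad <- write_raw_captures(raw[, -5])
  expect_error(read_captures(p_bad, quiet = TRUE), "required column")
  p_empty <- write_raw_captures(raw[0, ])
  expect_error(read_captures(p_empty, quiet = TRUE), "empty")

  # custom schema maps arbitrary column names
  raw4 <- setNames(raw, c("BAND", "SPEC", "STA", "DATE", "AGE"))
  x4 <- read_captures(write_raw_captures(raw4),
                      schema = capture_schema(band_id = "BAND",
                                              species_code = "SPEC",
                                              station_id = "STA",
                                              date = "DATE", age = "AGE"),
                      quiet = TRUE)
  expect_equal(x4$band_id, x$band_id)
})

test_that("generator output round-trips through write/read unchanged", {
  sim <- simulate_study(tiny_config(), seed = 11)
  cap <- sim$captures
  p <- tempfile(fileext = ".csv")
  write_captures(cap, p)
  back <- read_captures(p, quiet = TRUE)
  ord <- function(d) {
    d <- d[order(d$band_id, d$year, d$capture_index), ]
    rownames(d) <- NULL
    d
  }
  a <- ord(cap); b <- ord(back)
  for (col in c("band_id", "species_code", "station_id", "year", "age"))
    expect_identical(a[[col]], b[[col]], info = col)
  expect_equal(a$date, b$date)
})

test_that("resolve_year_unique applies determinate-over-AHY and latest-wins", {
  # three captures in one year: AHY, AHY, then SY after photo review
  x <- make_captures(rep("B1", 3), rep("TEWA", 3), rep("ST01", 3),
                     c("2012-06-05", "2012-06-15", "2012-07-10"),
                     c("AHY", "AHY", "SY"))
  r <- resolve_year_unique(x)
  expect_equal(nrow(r), 1L)
  expect_equal(r$resolved_age, "SY")

  # SY and ASY in the same year: conflict, latest by date wins
  x2 <- make_captures(rep("B1", 2), rep("TEWA", 2), rep("ST01", 2),
                      c("2012-06-05", "2012-07-10"), c("SY", "ASY"))
  r2 <- resolve_year_unique(x2)
  expect_equal(r2$resolved_age, "ASY")
  expect_equal(attr(r2, "conflict_report")$n_conflicts, 1L)

  # captures in two different years give two year-unique rows
  x3 <- make_captures(rep("B1", 2), rep("TEWA", 2), rep("ST01", 2),
                      c("2012-06-05", "2014-06-05"), c("SY", "ASY"))
  expect_equal(nrow(resolve_year_unique(x3)), 2L)

  # HY-only band-years are excluded; AHY-only resolves to AHY
  x4 <- make_captures(c("B1", "B2"), c("TEWA", "TEWA"), "ST01",
                      c("2012-07-20", "2012-06-05"), c("HY", "AHY"))
  r4 <- resolve_year_unique(x4)
  expect_equal(r4$band_id, "B2")
  expect_equal(r4$resolved_age, "AHY")

  # station attributed to first capture of the year
  x5 <- make_captures(rep("B1", 2), rep("TEWA", 2), c("ST02", "ST01"),
                      c("2012-06-05", "2012-06-20"), c("AHY", "SY"))
  expect_equal(resolve_year_unique(x5)$station_id, "ST02")
})

test_that("resolve_year_unique is idempotent and conserves generator counts", {
  sim <- simulate_study(tiny_config(), seed = 3)
  r <- resolve_year_unique(sim$captures)
  expect_equal(nrow(r), sim$truth$n_adult_bird_years)

  # feeding the resolved table back (one capture per bird-year) is identity
  r2_in <- data.frame(band_id = r$band_id, species_code = r$species_code,
                      station_id = r$station_id, year = r$year,
                      date = as.Date(paste0(r$year, "-06-15")),
                      age = r$resolved_age, capture_index = 1L,
                      stringsAsFactors = FALSE)
  r2 <- resolve_year_unique(r2_in)
  ord <- order(r$band_id, r$year)
  expect_equal(r2$resolved_age[order(r2$band_id, r2$year)],
               r$resolved_age[ord])
  expect_equal(nrow(r2), nrow(r))
})

test_that("filter_target_species applies the 20-per-year mean threshold", {
  mk <- function(code, n) data.frame(
    band_id = sprintf("%s%04d", code, seq_len(n)), species_code = code,
    station_id = "ST01", year = 2011L, resolved_age = "SY",
    stringsAsFactors = FALSE)
  inds <- rbind(mk("RBGR", 134), mk("NOWA", 127), mk("XXXX", 119))
  expect_equal(filter_target_species(inds, n_years = 6),
               c("NOWA", "RBGR"))   # 22.3 and 21.2 in; 19.8 out
  expect_equal(filter_target_species(inds, n_years = 6,
                                     min_mean_per_year = 19),
               c("NOWA", "RBGR", "XXXX"))
})

test_that("summarize_species conserves totals and handles empty input", {
  sim <- simulate_study(tiny_config(), seed = 5)
  r <- resolve_year_unique(sim$captures)
  s <- summarize_species(r)
  expect_equal(s$n_SY + s$n_ASY + s$n_AHY, s$n_year_inds)
  expect_equal(sum(s$n_year_inds), nrow(r))
  expect_true(all(s$n_stations <= length(unique(sim$captures$station_id))))

  empty <- summarize_species(r[0, ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("species_code", "n_stations", "n_year_inds",
                        "n_SY", "n_ASY", "n_AHY"))
})
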
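test_that("parse_records excludes rows lacking critical metadata and counts them", {
  raw <- data.frame(
    id = c("a", "b", "c", "d"),
    lat = c(48, 48, NA, 48), lon = c(-96, -96, -96, -96),
    when = c("2015-06-01", "", "2015-06-01", "2015-06-01"),
    val = c("12", "10", "10", "-3"),
    stringsAsFactors = FALSE
  )
  schema <- list(site_id = "id", latitude = "lat", longitude = "lon",
                 date = "when", value = "val")
  res <- parse_records(raw, schema, variable = "calcium")
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$site_id, "a")
  expect_equal(unname(res$counts["missing_metadata"]), 2L)
  expect_equal(unname(res$counts["negative_value"]), 1L)
  expect_error(parse_records(raw, list(site_id = "id"), variable = "calcium"),
               "schema_map")
  expect_error(parse_records(raw, c(schema, list(units = "nope")),
                             variable = "calcium"), "absent column")
})

test_that("keyword filter is a case-insensitive substring match that cannot fire on missing fields", {
  rec <- make_records(4,
    site_name = c("CITY WASTEWATER OUTFALL", NA, "Clearwater Lake",
                  "ok site"),
    site_type = c(NA, NA, NA, "Wastewater lagoon"))
  res <- filter_site_keywords(rec, qc_config())
  # "Clearwater" does not contain "WASTEWATER"; missing names are kept
  expect_equal(res$records$site_name, c(NA, "Clearwater Lake"))
  expect_equal(unname(res$counts["keyword"]), 2L)
})

test_that("fraction selection prefers dissolved, treats unspecified as dissolved, drops rare fractions", {
  rec <- make_records(5,
    site_id = c("s1", "s1", "s2", "s3", "s3"),
    fraction = c("dissolved", "total", "filterable", "unspecified", "total"),
    value = c(10.1, 10.4, 9.9, 12.0, 12.5))
  res <- select_fraction(rec, qc_config())
  kept <- res$records[order(res$records$site_id), ]
  expect_equal(kept$site_id, c("s1", "s3"))
  expect_equal(kept$value, c(10.1, 12.0))
  expect_equal(unname(res$counts["fraction"]), 3L)
  # no dissolved in group: any non-excluded fraction is retained
  rec2 <- make_records(1, fraction = "total", value = 7)
  expect_equal(select_fraction(rec2, qc_config())$records$value, 7)
})

test_that("unit harmonization converts to mg/L and drops blank or unknown units", {
  rec <- make_records(4,
    units_raw = c("µg/L", "", "mEq/L", "furlongs"),
    value = c(500, 12, 1, 1))
  res <- suppressWarnings(harmonize_units(rec, qc_config()))
  expect_equal(res$records$value, c(0.5, 20.04))
  expect_equal(unname(res$counts["no_units"]), 1L)
  expect_equal(unname(res$counts["unit_unrecognized"]), 1L)
  expect_warning(harmonize_units(rec, qc_config()), "unrecognized")
  # pH records pass through untouched whatever the units field holds
  ph <- make_records(1, variable = "ph", value = 7.7, units_raw = "")
  expect_equal(harmonize_units(ph, qc_config())$records$value, 7.7)
})

test_that("calcium bounds: exclusion, regional clamping, detection-limit handling", {
  cfg <- qc_config()
  inside <- c(-100, 31)   # inside the default clamp box
  outside <- c(-96, 48)
  rec <- make_records(6,
    longitude = c(outside[1], inside[1], outside[1], outside[1], outside[1],
                  outside[1]),
    latitude = c(outside[2], inside[2], outside[2], outside[2], outside[2],
                 outside[2]),
    value = c(600, 600, 0.03, 0.03, 0.04, 10),
    below_detection = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    detection_limit = c(NA, NA, NA, NA, 0.05, NA))
  res <- apply_calcium_bounds(rec, cfg)
  expect_equal(res$records$value, c(500, 0.05, 0.05, 10))
  expect_equal(unname(res$counts), c(1L, 1L, 1L, 2L),
               ignore_attr = TRUE)  # above, below, clamped, dl-set
  expect_equal(names(res$counts),
               c("ca_above_max", "ca_below_min", "clamped",
                 "below_detection_set"))
  # idempotence: re-applying changes nothing
  res2 <- apply_calcium_bounds(res$records, cfg)
  expect_identical(res2$records$value, res$records$value)
  expect_true(all(res2$counts == 0))
})

test_that("pH bounds are inclusive at 2.5 and 12.5", {
  rec <- make_records(5, variable = "ph",
                      value = c(2.4, 2.5, 7.9, 12.5, 13.0))
  res <- apply_ph_bounds(rec, qc_config())
  expect_equal(res$records$value, c(2.5, 7.9, 12.5))
  expect_equal(unname(res$counts["ph_out_of_range"]), 2L)
  res2 <- apply_ph_bounds(res$records, qc_config())
  expect_equal(unname(res2$counts["ph_out_of_range"]), 0L)
})

test_that("record-local QC rules commute and conserve counts", {
  rec <- make_records(8,
    site_name = c("WASTEWATER PLANT", rep("Lake", 7)),
    value = c(10, 700, 0.01, 10, 20, 30, 40, 50),
    site_id = paste0("s", 1:8))
  cfg <- qc_config()
  ab <- apply_calcium_bounds(filter_site_keywords(rec, cfg)$records, cfg)
  ba <- filter_site_keywords(apply_calcium_bounds(rec, cfg)$records, cfg)
  expect_equal(ab$records[order(ab$records$site_id), ]$value,
               ba$records[order(ba$records$site_id), ]$value)
  qc <- qc_pipeline(list(records = rec,
                         counts = c(missing_metadata = 0L)), cfg)
  expect_equal(qc$report$n_input,
               qc$report$n_kept + sum(unlist(qc$report$exclusions)))
})

test_that("per-source year_min retains older records only for the configured sources", {
  rec <- make_records(4,
    source_id = c("modern", "modern", "territories", "territories"),
    date = as.Date(c("1995-05-01", "2010-05-01", "1985-05-01", "1960-05-01")))
  cfg <- qc_config(year_min = c(modern = 2000, territories = 1980))
  res <- filter_year(rec, cfg)
  expect_equal(format(res$records$date, "%Y"), c("2010", "1985"))
  expect_equal(unname(res$counts["too_old"]), 2L)
})

test_that("compare_fractions reports n, Pearson r, p-value and OLS slope per pair", {
  mk <- function(site, frac, val) {
    make_records(length(site), site_id = site, fraction = frac, value = val)
  }
  # identity line: r = 1, slope = 1
  rec <- rbind(
    mk(c("a", "b", "c"), "dissolved", c(1, 2, 3)),
    mk(c("a", "b", "c"), "total", c(1, 2, 3)),
    # doubled values: OLS slope of total_recoverable on dissolved = 2
    mk(c("a", "b", "c"), "total_recoverable", c(2, 4, 6)),
    # too few pairs: metrics unavailable
    mk("a", "soluble", 1.5))
  tab <- compare_fractions(rec)
  tot <- tab[tab$fraction == "total", ]
  expect_equal(tot$r, 1, tolerance = 1e-12)
  expect_equal(tot$slope, 1, tolerance = 1e-12)
  tr <- tab[tab$fraction == "total_recoverable", ]
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$n, 3L)
  sol <- tab[tab$fraction == "soluble", ]
  expect_true(is.na(sol$r) && is.na(sol$slope))
  expect_equal(nrow(compare_fractions(make_records(0))), 0L)
})
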
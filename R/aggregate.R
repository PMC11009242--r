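#' Collapse records to site-date medians
#'
#' Duplicate and pseudo-duplicate records (lab/field replicates, repeated
#' database entries, simultaneous samples from different depths) are
#' handled by taking the median of all records for each site on each date.
#' Each site-date row also carries the mean, standard deviation (n-1
#' denominator, missing for a single record), min, max, and the 25th/75th
#' percentiles (linear-interpolation quantiles).
#'
#' @param records Canonical records for a single variable.
#' @return Data frame with one row per (site_id, date):
#'   `site_id`, `date`, `median`, `mean`, `sd`, `min`, `max`, `q25`, `q75`,
#'   `n_records`, plus carried-through `latitude`, `longitude`, `region`,
#'   `source_id`, `variable`.
#' @export
site_date_median <- function(records) {
  assert_cols(records, c("site_id", "date", "value"), "records")
  if (length(unique(records$variable)) > 1L) {
    stop("site_date_median expects records for a single variable",
         call. = FALSE)
  }
  key <- paste(records$site_id, records$date, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  first <- vapply(idx, `[[`, integer(1), 1L)
  stats <- lapply(idx, function(i) value_stats(records$value[i]))
  getn <- function(f) vapply(stats, function(s) s[[f]], numeric(1))
  out <- data.frame(
    site_id = records$site_id[first],
    date = records$date[first],
    median = getn("median"), mean = getn("mean"), sd = getn("sd"),
    min = getn("min"), max = getn("max"), q25 = getn("q25"),
    q75 = getn("q75"), n_records = as.integer(getn("n")),
    latitude = records$latitude[first], longitude = records$longitude[first],
    region = records$region[first], source_id = records$source_id[first],
    variable = records$variable[first],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$site_id, out$date), , drop = FALSE]
}

#' Aggregate site-date medians into per-site summaries
#'
#' Summary statistics (median, mean, sd, min, max, q25, q75) are computed
#' over a site's site-date medians -- not over raw records -- so heavily
#' re-sampled dates carry no extra weight. The per-site median is the value
#' used for spatial interpolation, being robust to outliers.
#'
#' Coordinates must agree across a site's rows to 6 decimal degrees;
#' conflicting coordinates raise an error naming the site rather than being
#' silently averaged.
#'
#' @param sdm Result of [site_date_median()].
#' @return Data frame with one row per site: summary statistics plus
#'   `n_dates`, `n_records`, `years` (slash-separated), `sources`,
#'   `latitude`, `longitude`, `region`.
#' @export
site_summary <- function(sdm) {
  assert_cols(sdm, c("site_id", "date", "median", "n_records"), "sdm")
  idx <- split(seq_len(nrow(sdm)), sdm$site_id)
  for (site in names(idx)) {
    i <- idx[[site]]
    if (length(unique(round(sdm$latitude[i], 6))) > 1L ||
        length(unique(round(sdm$longitude[i], 6))) > 1L) {
      stop(sprintf("site '%s' has conflicting coordinates", site),
           call. = FALSE)
    }
  }
  first <- vapply(idx, `[[`, integer(1), 1L)
  stats <- lapply(idx, function(i) value_stats(sdm$median[i]))
  getn <- function(f) vapply(stats, function(s) s[[f]], numeric(1))
  data.frame(
    site_id = sdm$site_id[first],
    median = getn("median"), mean = getn("mean"), sd = getn("sd"),
    min = getn("min"), max = getn("max"), q25 = getn("q25"), q75 = getn("q75"),
    n_dates = as.integer(getn("n")),
    n_records = vapply(idx, function(i) sum(sdm$n_records[i]), integer(1)),
    years = vapply(idx, function(i)
      paste(sort(unique(format(sdm$date[i], "%Y"))), collapse = "/"),
      character(1)),
    sources = vapply(idx, function(i)
      paste(sort(unique(sdm$source_id[i])), collapse = "/"), character(1)),
    latitude = sdm$latitude[first], longitude = sdm$longitude[first],
    region = sdm$region[first], variable = sdm$variable[first],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Within-site versus across-site variability
#'
#' Contrasts temporal variability at individual sites with spatial
#' variability across sites: if the median within-site interquartile range
#' is small relative to the IQR of site medians, a temporally aggregated
#' value per site is an adequate basis for spatial interpolation.
#'
#' @param sdm Result of [site_date_median()].
#' @return List with `iqr_across_sites` (IQR of per-site medians),
#'   `median_within_site_iqr` and `q75_within_site_iqr` (over sites with at
#'   least two dates), and `per_site` (data frame of per-site IQRs).
#' @export
within_site_variability <- function(sdm) {
  sites <- site_summary(sdm)
  idx <- split(sdm$median, sdm$site_id)
  iqr1 <- function(v) diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
  per <- vapply(idx, iqr1, numeric(1))
  multi <- vapply(idx, function(v) length(v) >= 2L, logical(1))
  list(
    iqr_across_sites = iqr1(sites$median),
    median_within_site_iqr = if (any(multi)) median(per[multi]) else NA_real_,
    q75_within_site_iqr = if (any(multi))
      quantile(per[multi], 0.75, names = FALSE, type = 7) else NA_real_,
    per_site = data.frame(site_id = names(per), iqr = unname(per),
                          n_dates = lengths(idx), stringsAsFactors = FALSE,
                          row.names = NULL)
  )
}
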
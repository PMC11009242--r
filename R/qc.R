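#' Quality-control configuration
#'
#' Bundles the thresholds and rules used by [qc_pipeline()] and the
#' individual filtering steps. Defaults follow standard practice for
#' continental freshwater compilations: calcium concentrations above
#' 500 mg/L are implausible outside a few evaporite-dominated river
#' systems, 0.05 mg/L is a common analytical detection limit, and pH
#' outside 2.5--12.5 indicates unit or entry errors.
#'
#' @param ca_max Upper plausibility bound for calcium, mg/L.
#' @param ca_min Lower bound / conventional detection limit, mg/L.
#' @param ph_min,ph_max Inclusive plausibility bounds for pH.
#' @param year_min Earliest retained year. May be a single year or a named
#'   vector keyed by `source_id` so that data-sparse sources can retain
#'   older records. `NA` disables the rule.
#' @param exclusion_keywords Uppercase substrings; a record whose site name
#'   or site type contains any of them (case-insensitively) is excluded.
#' @param clamp_region Longitude/latitude bounding box
#'   `c(lon_min, lon_max, lat_min, lat_max)` within which over-limit calcium
#'   values are clamped to `ca_max` instead of excluded. The default box is
#'   a synthetic stand-in covering the Pecos and Wichita river systems in
#'   Texas, where natural concentrations above 500 mg/L occur. `NULL`
#'   disables clamping.
#' @param excluded_fractions Fraction labels always dropped (too rare to
#'   validate against dissolved measurements).
#'
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(ca_max = 500, ca_min = 0.05,
                      ph_min = 2.5, ph_max = 12.5,
                      year_min = 2000,
                      exclusion_keywords = c("WASTEWATER", "EFFLUENT",
                                             "MARINE", "ESTUAR", "MINE DRAIN"),
                      clamp_region = c(-104.9, -98, 29, 34.5),
                      excluded_fractions = c("filterable", "fixed")) {
  stopifnot(ca_min < ca_max, ph_min < ph_max)
  structure(list(
    ca_max = ca_max, ca_min = ca_min, ph_min = ph_min, ph_max = ph_max,
    year_min = year_min, exclusion_keywords = exclusion_keywords,
    clamp_region = clamp_region, excluded_fractions = excluded_fractions
  ), class = "qc_config")
}

.fraction_levels <- c("dissolved", "total", "total_recoverable", "recoverable",
                      "extractable", "soluble", "filterable", "fixed",
                      "unspecified")

normalize_fraction <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unspecified"
  x <- gsub("[ -]+", "_", x)
  x[!x %in% .fraction_levels] <- "unspecified"
  x
}

empty_counts <- function(...) {
  keys <- c(...)
  setNames(integer(length(keys)), keys)
}

#' Parse raw water-quality tables into canonical records
#'
#' Reads a delimited table (or takes a data frame) holding one measurement
#' per row and maps its columns to the canonical record schema via
#' `schema_map`. Rows lacking critical metadata -- coordinates, a parseable
#' date, or a value -- and rows with impossible (negative) values are
#' excluded and counted.
#'
#' @param raw A data frame, or path to a CSV/TSV file.
#' @param schema_map Named list/vector mapping canonical field names
#'   (`site_id`, `latitude`, `longitude`, `date`, `value`; optionally
#'   `variable`, `units`, `fraction`, `below_detection`, `detection_limit`,
#'   `site_name`, `site_type`, `region`, `source_id`, `record_id`) to the
#'   source column names.
#' @param variable Variable label (`"calcium"` or `"ph"`) applied to all
#'   rows when the table has no variable column.
#'
#' @return A list with elements `records` (canonical data frame) and
#'   `counts` (named integer vector of per-rule exclusions).
#' @export
parse_records <- function(raw, schema_map, variable = NULL) {
  if (is.character(raw)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", raw)) "\t" else ","
    raw <- read.csv(raw, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  schema_map <- as.list(schema_map)
  required <- c("site_id", "latitude", "longitude", "date", "value")
  miss <- setdiff(required, names(schema_map))
  if (length(miss)) {
    stop("schema_map must name columns for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unlist(schema_map), names(raw))
  if (length(bad)) {
    stop("schema_map refers to absent column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  get_col <- function(field, default = NA) {
    if (!is.null(schema_map[[field]])) raw[[schema_map[[field]]]]
    else rep(default, nrow(raw))
  }

  n_input <- nrow(raw)
  rec <- data.frame(
    record_id = as.character(get_col("record_id",
                                     default = NA) %||% NA),
    site_id = as.character(get_col("site_id")),
    source_id = as.character(get_col("source_id", default = "src")),
    latitude = suppressWarnings(as.numeric(get_col("latitude"))),
    longitude = suppressWarnings(as.numeric(get_col("longitude"))),
    date = rep(as.Date(NA), n_input),
    variable = tolower(as.character(get_col("variable",
                                            default = variable %||% NA))),
    value = suppressWarnings(as.numeric(get_col("value"))),
    units_raw = as.character(get_col("units", default = "")),
    fraction = normalize_fraction(get_col("fraction", default = "")),
    below_detection = as.logical(get_col("below_detection", default = FALSE)),
    detection_limit = suppressWarnings(as.numeric(get_col("detection_limit",
                                                          default = NA))),
    site_name = as.character(get_col("site_name", default = NA)),
    site_type = as.character(get_col("site_type", default = NA)),
    region = as.character(get_col("region", default = NA)),
    stringsAsFactors = FALSE
  )
  if (all(is.na(rec$record_id))) rec$record_id <- as.character(seq_len(n_input))
  rec$below_detection[is.na(rec$below_detection)] <- FALSE
  rec$date <- suppressWarnings(as.Date(as.character(get_col("date")),
                                       tryFormats = c("%Y-%m-%d", "%Y/%m/%d",
                                                      "%d/%m/%Y", "%m/%d/%Y")))
  if (any(is.na(rec$variable)) || !all(rec$variable %in% c("calcium", "ph"))) {
    stop("variable must be 'calcium' or 'ph' (supply `variable` or a column)",
         call. = FALSE)
  }

  counts <- empty_counts("missing_metadata", "negative_value")
  missing_meta <- is.na(rec$latitude) | is.na(rec$longitude) |
    is.na(rec$date) | is.na(rec$value) | is.na(rec$site_id) | rec$site_id == ""
  counts["missing_metadata"] <- sum(missing_meta)
  negative <- !missing_meta & rec$value < 0
  counts["negative_value"] <- sum(negative)
  rec <- rec[!missing_meta & !negative, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, counts = counts)
}

#' Exclude records at contaminated or non-freshwater sites by keyword
#'
#' Case-insensitive substring match of `exclusion_keywords` against the
#' site name and site type fields; either match excludes the record. The
#' rule cannot fire when both fields are missing.
#'
#' @param records Canonical records data frame.
#' @param config A [qc_config()].
#' @return `list(records =, counts =)`.
#' @export
filter_site_keywords <- function(records, config = qc_config()) {
  kw <- toupper(config$exclusion_keywords)
  hit <- rep(FALSE, nrow(records))
  for (field in c("site_name", "site_type")) {
    v <- toupper(records[[field]])
    v[is.na(v)] <- ""
    for (k in kw) hit <- hit | grepl(k, v, fixed = TRUE)
  }
  list(records = records[!hit, , drop = FALSE],
       counts = c(keyword = sum(hit)))
}

#' Convert calcium measurements to consistent units (mg/L)
#'
#' Recognizes common unit dialects (`mg/L`, `ppm`, `ug/L`, `ueq/L`,
#' `meq/L`); milliequivalents convert via the Ca2+ equivalent weight
#' 40.08 / 2 = 20.04 g/eq. Records with blank units are excluded, as are
#' unrecognized unit strings (with a warning). pH records pass through
#' unchanged: their values are dimensionless pH units.
#'
#' @inheritParams filter_site_keywords
#' @return `list(records =, counts =)`.
#' @export
harmonize_units <- function(records, config = qc_config()) {
  is_ca <- records$variable == "calcium"
  u <- tolower(gsub("[[:space:]]", "", records$units_raw))
  u <- sub("^µ", "u", u)
  factor <- rep(NA_real_, nrow(records))
  factor[u %in% c("mg/l", "mgl-1", "mg/las ca", "ppm", "mg/lca")] <- 1
  factor[u %in% c("ug/l", "ugl-1", "ppb")] <- 1e-3
  factor[u %in% c("meq/l", "meql-1")] <- 20.04
  factor[u %in% c("ueq/l", "ueql-1")] <- 20.04e-3

  blank <- is_ca & (is.na(records$units_raw) | trimws(records$units_raw) == "")
  unrec <- is_ca & !blank & is.na(factor)
  if (any(unrec)) {
    warning(sprintf("%d calcium record(s) with unrecognized units excluded: %s",
                    sum(unrec),
                    paste(unique(records$units_raw[unrec]), collapse = ", ")))
  }
  keep <- !(blank | unrec)
  out <- records[keep, , drop = FALSE]
  ca <- out$variable == "calcium"
  out$value[ca] <- out$value[ca] * factor[keep][ca]
  out$detection_limit[ca] <- out$detection_limit[ca] * factor[keep][ca]
  out$units_raw[ca] <- "mg/L"
  list(records = out,
       counts = c(no_units = sum(blank), unit_unrecognized = sum(unrec)))
}

#' Select the preferred calcium fraction within each sample group
#'
#' Within each (site, date) group, dissolved measurements are preferred
#' when present; records labelled with an unspecified fraction are treated
#' as equivalent to dissolved. Otherwise any fraction not in
#' `excluded_fractions` is retained. Filterable and fixed fractions are
#' always dropped. pH records pass through unchanged.
#'
#' @inheritParams filter_site_keywords
#' @return `list(records =, counts =)`.
#' @export
select_fraction <- function(records, config = qc_config()) {
  ca <- records$variable == "calcium"
  if (!any(ca)) return(list(records = records, counts = c(fraction = 0L)))
  r <- records[ca, , drop = FALSE]
  frac <- r$fraction
  frac[frac == "unspecified"] <- "dissolved"
  always_drop <- frac %in% config$excluded_fractions
  grp <- paste(r$site_id, r$date, sep = "\r")
  has_dissolved <- ave(frac == "dissolved", grp, FUN = any)
  drop <- always_drop | (has_dissolved & frac != "dissolved")
  kept <- rbind(records[!ca, , drop = FALSE], r[!drop, , drop = FALSE])
  rownames(kept) <- NULL
  list(records = kept, counts = c(fraction = sum(drop)))
}

#' Apply calcium plausibility bounds and detection-limit handling
#'
#' Values above `ca_max` are excluded unless the site lies inside the
#' configured clamp region (naturally calcium-rich river systems), where
#' they are clamped to `ca_max` to preserve spatial coverage. Values below
#' `ca_min` that are flagged below-detection, or that carry an explicit
#' detection limit, are set to `ca_min` for consistency; other sub-limit
#' values are excluded.
#'
#' @inheritParams filter_site_keywords
#' @return `list(records =, counts =)` where counts include the
#'   modification tallies `clamped` and `below_detection_set` (which do not
#'   reduce the number of records kept).
#' @export
apply_calcium_bounds <- function(records, config = qc_config()) {
  ca <- records$variable == "calcium"
  v <- records$value
  in_clamp <- rep(FALSE, nrow(records))
  if (!is.null(config$clamp_region)) {
    b <- config$clamp_region
    in_clamp <- !is.na(records$longitude) &
      records$longitude >= b[1] & records$longitude <= b[2] &
      records$latitude >= b[3] & records$latitude <= b[4]
  }
  over <- ca & v > config$ca_max
  clamp <- over & in_clamp
  drop_over <- over & !in_clamp
  under <- ca & v < config$ca_min
  flagged <- records$below_detection |
    (!is.na(records$detection_limit) & records$detection_limit >= records$value)
  set_dl <- under & flagged
  drop_under <- under & !flagged

  out <- records
  out$value[clamp] <- config$ca_max
  out$value[set_dl] <- config$ca_min
  out <- out[!(drop_over | drop_under), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       counts = c(ca_above_max = sum(drop_over), ca_below_min = sum(drop_under),
                  clamped = sum(clamp), below_detection_set = sum(set_dl)))
}

#' Apply pH plausibility bounds
#'
#' Keeps pH records with `ph_min <= value <= ph_max` (bounds inclusive);
#' calcium records pass through unchanged.
#'
#' @inheritParams filter_site_keywords
#' @return `list(records =, counts =)`.
#' @export
apply_ph_bounds <- function(records, config = qc_config()) {
  ph <- records$variable == "ph"
  drop <- ph & (records$value < config$ph_min | records$value > config$ph_max)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, counts = c(ph_out_of_range = sum(drop)))
}

#' Exclude records older than the configured minimum year
#'
#' `year_min` may be a single year or a named vector keyed by `source_id`,
#' so data-sparse sources can retain older records.
#'
#' @inheritParams filter_site_keywords
#' @return `list(records =, counts =)`.
#' @export
filter_year <- function(records, config = qc_config()) {
  ym <- config$year_min
  if (is.null(ym) || all(is.na(ym))) {
    return(list(records = records, counts = c(too_old = 0L)))
  }
  yr <- as.integer(format(records$date, "%Y"))
  if (!is.null(names(ym))) {
    lim <- ym[records$source_id]
    lim[is.na(lim)] <- if ("" %in% names(ym)) ym[[""]] else min(ym)
  } else {
    lim <- rep(ym, nrow(records))
  }
  drop <- !is.na(yr) & yr < lim
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, counts = c(too_old = sum(drop)))
}

#' Run the full record-level QC pipeline
#'
#' Applies, in order: keyword exclusion, year filter, unit harmonization,
#' fraction selection, calcium bounds and detection-limit handling, and pH
#' bounds. The individual rules are record-local and commute; the order
#' only affects which rule claims a record excluded by several.
#'
#' @param parsed Result of [parse_records()], or a canonical records data
#'   frame (in which case parse-level counts are zero).
#' @param config A [qc_config()].
#' @return `list(records =, report =)` where `report` is a `qc_report`:
#'   `n_input`, `n_kept`, per-rule `exclusions`, and `modifications`.
#' @export
qc_pipeline <- function(parsed, config = qc_config()) {
  if (is.data.frame(parsed)) {
    parsed <- list(records = parsed, counts = empty_counts())
  }
  rec <- parsed$records
  n_input <- nrow(rec) + sum(parsed$counts)
  counts <- parsed$counts
  for (step in list(filter_site_keywords, filter_year, harmonize_units,
                    select_fraction, apply_calcium_bounds, apply_ph_bounds)) {
    res <- step(rec, config)
    rec <- res$records
    counts <- c(counts, res$counts)
  }
  mod_keys <- c("clamped", "below_detection_set")
  report <- structure(list(
    n_input = n_input,
    n_kept = nrow(rec),
    exclusions = as.list(counts[setdiff(names(counts), mod_keys)]),
    modifications = as.list(counts[intersect(names(counts), mod_keys)])
  ), class = "qc_report")
  stopifnot(report$n_input ==
              report$n_kept + sum(unlist(report$exclusions)))
  list(records = rec, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d records in, %d kept (%.1f%%)\n", x$n_input,
              x$n_kept, if (x$n_input) 100 * x$n_kept / x$n_input else 100))
  ex <- unlist(x$exclusions)
  for (k in names(ex)) if (ex[[k]] > 0) cat(sprintf("  excluded %-22s %d\n", k, ex[[k]]))
  mo <- unlist(x$modifications)
  for (k in names(mo)) if (mo[[k]] > 0) cat(sprintf("  modified %-22s %d\n", k, mo[[k]]))
  invisible(x)
}

#' Compare calcium fractions measured on the same samples
#'
#' For samples -- (site, date) pairs -- where dissolved calcium and a
#' second fraction were both measured, computes the pair count, Pearson
#' correlation with its two-sided p-value, and the ordinary least-squares
#' slope of the second fraction regressed on dissolved. Strong correlations
#' with slope near 1 justify pooling fractions when dissolved data are
#' absent. Fraction pairs with fewer than 3 samples are reported with the
#' statistics marked unavailable.
#'
#' @param records Canonical calcium records (before fraction selection).
#' @return Data frame with columns `fraction`, `n`, `r`, `p_value`, `slope`.
#' @export
compare_fractions <- function(records) {
  out <- data.frame(fraction = character(), n = integer(), r = numeric(),
                    p_value = numeric(), slope = numeric(),
                    stringsAsFactors = FALSE)
  r <- records[records$variable == "calcium", , drop = FALSE]
  if (nrow(r) == 0L) return(out)
  key <- paste(r$site_id, r$date, sep = "\r")
  per <- function(frac) {
    sel <- r$fraction == frac
    tapply(r$value[sel], key[sel], median)
  }
  diss <- per("dissolved")
  others <- setdiff(unique(r$fraction), c("dissolved", "unspecified"))
  for (frac in sort(others)) {
    o <- per(frac)
    common <- intersect(names(diss), names(o))
    x <- unname(diss[common]); y <- unname(o[common])
    n <- length(common)
    if (n >= 3L && sd(x) > 0 && sd(y) > 0) {
      ct <- cor.test(x, y)
      slope <- unname(coef(lm(y ~ x))[2])
      out[nrow(out) + 1L, ] <- list(frac, n, unname(ct$estimate),
                                    ct$p.value, slope)
    } else {
      out[nrow(out) + 1L, ] <- list(frac, n, NA_real_, NA_real_, NA_real_)
    }
  }
  out
}
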
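#' Simulate site values from a Gaussian random field
#'
#' Draws site locations uniformly over a planar domain and samples a
#' zero-mean Gaussian process with covariance
#' \eqn{C(h) = c_1 \rho_\kappa(h)} plus independent nugget noise of
#' variance \eqn{c_0}, by dense Cholesky factorization -- the simplest
#' exact method at the supported problem sizes (`n_sites` up to 3000).
#' The field is then shifted by `mean` and optionally transformed with an
#' exponential link, which yields the right-skewed, strictly positive
#' distribution typical of freshwater calcium concentrations; the identity
#' link with a mean near 7.9 emulates pH.
#'
#' @param model A [variogram_model()] describing the generating structure.
#' @param n_sites Number of sites (<= 3000).
#' @param domain Planar extent `c(xmin, xmax, ymin, ymax)` in metres
#'   (working CRS). The default is a 1000 km square within the projection's
#'   well-behaved zone.
#' @param mean Mean of the Gaussian field (on the log scale when
#'   `transform = "exponential"`).
#' @param transform `"identity"` or `"exponential"`.
#' @param seed Seed; fully determines the output.
#' @return A list of class `synthetic_truth`: `sites` (data frame with
#'   `site_id`, `x`, `y`, `longitude`, `latitude`, `z` (Gaussian value),
#'   `true_value` (transformed)), `model`, `mean`, `transform`, `seed`.
#' @export
simulate_gaussian_field <- function(model, n_sites, domain = c(-5e5, 5e5, 0, 1e6),
                                    mean = 0, transform = c("identity",
                                                            "exponential"),
                                    seed = 1) {
  stopifnot(inherits(model, "variogram_model"), n_sites >= 1,
            n_sites <= 3000)
  transform <- match.arg(transform)
  set.seed(seed)
  x <- runif(n_sites, domain[1], domain[2])
  y <- runif(n_sites, domain[3], domain[4])
  D <- as.matrix(dist(cbind(x, y)))
  C <- model$psill * matern_stein_rho(D, model$range, model$kappa)
  diag(C) <- model$psill + model$nugget
  L <- NULL
  for (jit in c(0, 1e-10, 1e-8, 1e-6) * max(model$psill + model$nugget, 1)) {
    L <- tryCatch(chol(C + diag(jit, n_sites)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) stop("covariance not positive definite after jitter",
                       call. = FALSE)
  z <- mean + as.vector(t(L) %*% rnorm(n_sites))
  value <- if (transform == "exponential") exp(z) else z
  ll <- albers_inverse(x, y)
  structure(list(
    sites = data.frame(site_id = sprintf("S%04d", seq_len(n_sites)),
                       x = x, y = y, longitude = ll$lon, latitude = ll$lat,
                       z = z, true_value = value, stringsAsFactors = FALSE),
    model = model, mean = mean, transform = transform, seed = seed
  ), class = "synthetic_truth")
}

#' Default generating model for a calcium-like field
#'
#' Log-scale Matern structure whose exponential transform spans roughly
#' 1--150 mg/L with a median near 20 mg/L, mimicking the strongly
#' right-skewed continental distribution of site median calcium.
#' @return A [variogram_model()].
#' @export
calcium_field_model <- function() variogram_model(0, 0.8, 2e5, kappa = 0.5)

#' Default generating model for a pH-like field
#'
#' Identity-scale structure centred at pH 7.9 with a spatial standard
#' deviation under one pH unit.
#' @return A [variogram_model()].
#' @export
ph_field_model <- function() variogram_model(0, 0.5, 2e5, kappa = 0.5)

#' Build a messy observation table from a synthetic truth
#'
#' Expands each site into a random number of dated visits (geometric,
#' mean about `mean_visits`) each with one or more replicate records, and
#' plants known contamination so QC rules can be verified exactly:
#' keyword-named sites, calcium values pushed above 500 mg/L, values
#' censored below 0.05 mg/L (half flagged below-detection, half not),
#' out-of-range pH, records with blank units, and paired dissolved/total
#' fraction records. Replicate noise is multiplicative lognormal for
#' calcium (preserving positivity) and additive for pH.
#'
#' All contamination categories are planted on disjoint record sets, so
#' each QC rule's exclusion count must equal the registry count exactly.
#'
#' @param truth A `synthetic_truth` from [simulate_gaussian_field()].
#' @param variable `"calcium"` or `"ph"`.
#' @param mean_visits Mean visits per site (geometric distribution).
#' @param max_replicates Replicates per visit are uniform on
#'   `1:max_replicates`.
#' @param noise_sd Replicate noise: lognormal sigma for calcium, additive
#'   sd for pH.
#' @param contamination Named list of planted record counts:
#'   `keyword_sites` (sites renamed with an exclusion keyword),
#'   `over_limit`, `below_detection_flagged`, `below_detection_unflagged`,
#'   `no_units`, `ph_out_of_range`, `fraction_pairs` (extra paired
#'   total-fraction records).
#' @param seed Seed; fully determines the table.
#' @return List with `table` (raw observation data frame), `schema`
#'   (schema_map for [parse_records()]), and `registry` (planted counts).
#' @export
make_observation_table <- function(truth, variable = c("calcium", "ph"),
                                   mean_visits = 4, max_replicates = 3,
                                   noise_sd = 0.05,
                                   contamination = list(),
                                   seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  variable <- match.arg(variable)
  plant <- modifyList(list(
    keyword_sites = 0L, over_limit = 0L, below_detection_flagged = 0L,
    below_detection_unflagged = 0L, no_units = 0L, ph_out_of_range = 0L,
    fraction_pairs = 0L
  ), contamination)
  set.seed(seed)
  s <- truth$sites
  n_sites <- nrow(s)
  visits <- pmin(1L + rgeom(n_sites, 1 / mean_visits), 60L)
  site_rows <- rep(seq_len(n_sites), visits)
  dates <- as.Date("2010-01-01") +
    sample.int(4000, length(site_rows), replace = TRUE)
  reps <- sample.int(max_replicates, length(site_rows), replace = TRUE)
  row_site <- rep(site_rows, reps)
  row_date <- rep(dates, reps)
  n_rec <- length(row_site)

  true_v <- s$true_value[row_site]
  value <- if (variable == "calcium") {
    true_v * exp(rnorm(n_rec, 0, noise_sd))
  } else {
    true_v + rnorm(n_rec, 0, noise_sd)
  }

  tab <- data.frame(
    StationID = s$site_id[row_site],
    Lat = s$latitude[row_site],
    Lon = s$longitude[row_site],
    SampleDate = format(row_date, "%Y-%m-%d"),
    Result = value,
    Units = if (variable == "calcium") "mg/L" else "pH units",
    Fraction = if (variable == "calcium") "" else NA,
    BelowDL = FALSE,
    DL = NA_real_,
    StationName = paste("Lake", s$site_id[row_site]),
    StationType = "Lake/Pond",
    Province = paste0("R", 1 + (match(s$site_id[row_site], s$site_id) %% 3)),
    stringsAsFactors = FALSE
  )

  # keyword contamination renames whole sites; their records are excluded
  kw_sites <- integer(0)
  if (plant$keyword_sites > 0L) {
    kw_sites <- sample.int(n_sites, plant$keyword_sites)
    hit <- row_site %in% kw_sites
    tab$StationName[hit] <- paste("CITY WASTEWATER OUTFALL",
                                  s$site_id[row_site][hit])
  }
  clean <- which(!(row_site %in% kw_sites))

  take <- function(n) {
    n <- min(n, length(clean))
    picked <- if (n > 0L) sample(clean, n) else integer(0)
    clean <<- setdiff(clean, picked)
    picked
  }
  if (variable == "calcium") {
    i <- take(plant$over_limit)
    tab$Result[i] <- runif(length(i), 501, 2500)
    i <- take(plant$below_detection_flagged)
    tab$Result[i] <- runif(length(i), 0.001, 0.049)
    tab$BelowDL[i] <- TRUE
    i <- take(plant$below_detection_unflagged)
    tab$Result[i] <- runif(length(i), 0.001, 0.049)
    i <- take(plant$no_units)
    tab$Units[i] <- ""
  } else {
    i <- take(plant$ph_out_of_range)
    tab$Result[i] <- sample(c(runif(length(i), 0, 2.4),
                              runif(length(i), 12.6, 14)), length(i))
  }
  # paired fractions: duplicate records (one per site-date, so each pair is
  # one comparison sample) as explicit dissolved/total measurements
  if (variable == "calcium" && plant$fraction_pairs > 0L) {
    key <- paste(row_site, as.numeric(row_date))
    cand <- clean[!duplicated(key[clean])]
    npair <- min(plant$fraction_pairs, length(cand))
    i <- if (npair > 0L) sample(cand, npair) else integer(0)
    clean <- setdiff(clean, i)
    tab$Fraction[i] <- "Dissolved"
    extra <- tab[i, , drop = FALSE]
    extra$Fraction <- "Total"
    extra$Result <- extra$Result * exp(rnorm(npair, 0, 0.01))
    tab <- rbind(tab, extra)
  }
  rownames(tab) <- NULL

  # The registry is derived from the finished table, so records that land
  # in a contamination class naturally (e.g. a simulated value drifting
  # above 500 mg/L) are counted alongside the planted ones. The generator
  # domain lies outside the default calcium clamp region, so every
  # over-limit record is an exclusion, never a clamp.
  kw <- grepl("WASTEWATER", tab$StationName, fixed = TRUE)
  alive <- !kw
  no_units <- alive & tab$Units == ""
  is_total <- alive & !no_units & !is.na(tab$Fraction) &
    tab$Fraction == "Total"
  alive <- alive & !no_units & !is_total
  registry <- list(keyword = sum(kw), no_units = sum(no_units),
                   fraction = sum(is_total))
  if (variable == "calcium") {
    over <- alive & tab$Result > 500
    below <- alive & tab$Result < 0.05
    registry$ca_above_max <- sum(over)
    registry$below_detection_set <- sum(below & tab$BelowDL)
    registry$ca_below_min <- sum(below & !tab$BelowDL)
    registry$ph_out_of_range <- 0L
  } else {
    registry$ph_out_of_range <- sum(alive & (tab$Result < 2.5 |
                                               tab$Result > 12.5))
    registry$ca_above_max <- 0L
    registry$below_detection_set <- 0L
    registry$ca_below_min <- 0L
  }
  schema <- list(site_id = "StationID", latitude = "Lat", longitude = "Lon",
                 date = "SampleDate", value = "Result", units = "Units",
                 fraction = "Fraction", below_detection = "BelowDL",
                 detection_limit = "DL", site_name = "StationName",
                 site_type = "StationType", region = "Province")
  list(table = tab, schema = schema, registry = registry,
       variable = variable, seed = seed)
}
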
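#' Write site and site-date tables with metadata sidecars
#'
#' Mirrors the deposit convention of the source compilations: a "sites"
#' CSV (one summary row per site) and a "site-date" CSV, each accompanied
#' by a `metadata_*.csv` listing column definitions.
#'
#' @param sites Result of [site_summary()].
#' @param sdm Result of [site_date_median()].
#' @param dir Output directory (created if absent).
#' @param variable Variable label used in file names.
#' @return Named character vector of file paths, invisibly.
#' @export
write_site_tables <- function(sites, sdm, dir, variable) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_sites <- file.path(dir, sprintf("sites_%s_%d.csv", variable, nrow(sites)))
  f_sdm <- file.path(dir, sprintf("site-date_%s_%d.csv", variable, nrow(sdm)))
  write.csv(sites, f_sites, row.names = FALSE, na = "")
  write.csv(sdm, f_sdm, row.names = FALSE, na = "")
  meta <- function(df, role) {
    data.frame(column = names(df),
               definition = vapply(names(df), function(nm) switch(nm,
                 site_id = "site identifier",
                 date = "sample date (ISO 8601)",
                 median = paste("median of", role),
                 mean = paste("mean of", role),
                 sd = paste("standard deviation (n-1) of", role),
                 min = paste("minimum of", role), max = paste("maximum of", role),
                 q25 = "25th percentile (linear interpolation)",
                 q75 = "75th percentile (linear interpolation)",
                 n_records = "number of records aggregated",
                 n_dates = "number of dates with data",
                 years = "years with data, slash-separated",
                 sources = "contributing source ids, slash-separated",
                 latitude = "latitude, decimal degrees",
                 longitude = "longitude, decimal degrees",
                 x = "easting, metres (ESRI:102008)",
                 y = "northing, metres (ESRI:102008)",
                 region = "administrative region label",
                 variable = "measured variable",
                 "") , character(1)),
               stringsAsFactors = FALSE)
  }
  write.csv(meta(sites, "site-date medians"),
            file.path(dir, paste0("metadata_", basename(f_sites))),
            row.names = FALSE)
  write.csv(meta(sdm, "daily records"),
            file.path(dir, paste0("metadata_", basename(f_sdm))),
            row.names = FALSE)
  invisible(c(sites = f_sites, site_date = f_sdm))
}

default_methods <- function(model_free, model_zn) {
  list(
    nn = method_spec("nn"),
    idw_or = method_spec("idw", nmax = 15, idp = 1.2),
    idw_om = method_spec("idw", nmax = 14, idp = 2.2),
    ok = method_spec("ok", model = model_free, nmax = 100, nmin = 15),
    okzn = method_spec("okzn", model = model_zn, nmax = 100, nmin = 15)
  )
}

#' Run the end-to-end interpolation pipeline
#'
#' Composes the full workflow from a single configuration: parse and QC
#' records, aggregate to site medians, project, fit the variogram (free
#' and zero-nugget), either compare methods by cross-validation or
#' interpolate a grid with one method, and write all outputs plus a
#' manifest. Outputs are deterministic given the configuration and seed.
#'
#' @param config A list, or path to a YAML file, with entries:
#' \describe{
#'   \item{input}{path to the raw records CSV (or a data frame).}
#'   \item{schema}{schema_map for [parse_records()].}
#'   \item{variable}{`"calcium"` or `"ph"` (required).}
#'   \item{qc}{optional list of [qc_config()] overrides.}
#'   \item{method}{`"nn"`, `"idw"`, `"ok"`, `"okzn"` or `"compare"`.}
#'   \item{idw}{optional list with `nmax`, `idp` for an IDW run.}
#'   \item{neighborhood}{optional list with `nmax`, `nmin` for kriging.}
#'   \item{grid}{optional list with `cell_size`, `padding` (metres).}
#'   \item{cv}{optional: `type` (`"loo"` or `"kfold"`), `k`.}
#'   \item{mask}{optional path to a GeoJSON polygon file (geographic
#'     coordinates) used to mask the rasters.}
#'   \item{seed}{integer seed for all randomized steps (required).}
#'   \item{outdir}{output directory (required).}
#' }
#' @return List with the kept `records`, QC `report`, `sites`,
#'   `variogram` models, and either `cv` results + `selection` (compare
#'   mode) or the interpolated `field`; `paths` names every file written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (req in c("variable", "outdir", "seed")) {
    if (is.null(config[[req]])) {
      stop("config is missing required entry '", req, "'", call. = FALSE)
    }
  }
  variable <- match.arg(config$variable, c("calcium", "ph"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  qc_cfg <- do.call(qc_config, config$qc %||% list())

  parsed <- parse_records(config$input, config$schema, variable = variable)
  qc <- qc_pipeline(parsed, qc_cfg)
  jsonlite::write_json(unclass(qc$report),
                       file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  sdm <- site_date_median(qc$records)
  sites <- project_points(site_summary(sdm))
  tables <- write_site_tables(sites, sdm, outdir, variable)

  ev <- empirical_variogram(sites$x, sites$y, sites$median,
                            seed = config$seed)
  vg_free <- fit_variogram(ev, fix_nugget_zero = FALSE)
  vg_zn <- fit_variogram(ev, fix_nugget_zero = TRUE)
  write_variogram_json(vg_free, file.path(outdir, "variogram_ok.json"))
  write_variogram_json(vg_zn, file.path(outdir, "variogram_okzn.json"))

  nb <- config$neighborhood %||% list()
  methods <- default_methods(vg_free, vg_zn)
  methods$ok <- modifyList(methods$ok, nb)
  methods$okzn <- modifyList(methods$okzn, nb)
  if (!is.null(config$idw)) {
    methods$idw_or <- modifyList(methods$idw_or, config$idw)
    methods$idw_om <- NULL
  }

  out <- list(records = qc$records, report = qc$report, sites = sites,
              variogram = list(ok = vg_free, okzn = vg_zn),
              paths = tables)
  method <- tolower(config$method %||% "okzn")

  if (method == "compare") {
    cv_type <- (config$cv %||% list())$type %||% "loo"
    run_cv <- function(spec) {
      if (cv_type == "kfold") {
        kfold_cv(sites, sites$median, spec, k = (config$cv$k %||% 5),
                 seed = config$seed)
      } else loocv(sites, sites$median, spec)
    }
    cvs <- lapply(methods, run_cv)
    reports <- lapply(cvs, summary)
    sel <- select_method(reports)
    cv_all <- do.call(rbind, lapply(names(cvs), function(m)
      cbind(method = m, as.data.frame(cvs[[m]]))))
    write.csv(cv_all, file.path(outdir, "cv_results.csv"), row.names = FALSE)
    write.csv(sel$table, file.path(outdir, "cv_metrics.csv"),
              row.names = FALSE)
    out$cv <- cvs
    out$metrics <- reports
    out$selection <- sel
    out$paths <- c(out$paths,
                   cv_results = file.path(outdir, "cv_results.csv"),
                   cv_metrics = file.path(outdir, "cv_metrics.csv"))
  } else {
    if (!method %in% names(methods) && method %in% c("idw")) {
      methods$idw <- methods$idw_or
    }
    spec <- methods[[method]] %||%
      stop("unknown method '", method, "'", call. = FALSE)
    gcfg <- config$grid %||% list()
    grid <- grid_spec(sites, cell_size = gcfg$cell_size %||% 10000,
                      padding = gcfg$padding %||% 0)
    field <- interpolate_grid(sites, sites$median, spec, grid,
                              variable = variable)
    pred_path <- file.path(outdir, sprintf("%s_%s_prediction.tif",
                                           variable, method))
    write_geotiff(field, pred_path, "prediction")
    out$paths <- c(out$paths, prediction = pred_path)
    if (!is.null(field$variance)) {
      var_path <- file.path(outdir, sprintf("%s_%s_variance.tif",
                                            variable, method))
      write_geotiff(field, var_path, "variance")
      out$paths <- c(out$paths, variance = var_path)
    }
    if (!is.null(config$mask)) {
      polys <- project_polygons(read_polygons_geojson(config$mask))
      masked <- mask_raster(field, polys)
      mpath <- file.path(outdir, sprintf("%s_%s_prediction_masked.tif",
                                         variable, method))
      write_geotiff(masked, mpath, "prediction")
      out$paths <- c(out$paths, prediction_masked = mpath)
      if (!is.null(masked$variance)) {
        mvpath <- file.path(outdir, sprintf("%s_%s_variance_masked.tif",
                                            variable, method))
        write_geotiff(masked, mvpath, "variance")
        out$paths <- c(out$paths, variance_masked = mvpath)
      }
      out$field_masked <- masked
    }
    out$field <- field
  }

  manifest <- list(
    package = "aquainterp",
    version = as.character(utils::packageVersion("aquainterp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    variable = variable, method = method, seed = config$seed,
    n_input = qc$report$n_input, n_kept = qc$report$n_kept,
    n_sites = nrow(sites),
    created = "see file mtime"
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$paths <- c(out$paths, manifest = file.path(outdir, "manifest.json"),
                 qc_report = file.path(outdir, "qc_report.json"))
  out
}
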
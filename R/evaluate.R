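#' Interpolation error metrics
#'
#' Computes the five comparison metrics between observed values \eqn{Z_i}
#' and interpolated values \eqn{Z'_i}:
#' Pearson correlation `r`; mean absolute error
#' \eqn{MAE = \sum |Z'_i - Z_i| / n}; root-mean-square error
#' \eqn{RMSE = \sqrt{\sum (Z'_i - Z_i)^2 / n}}; mean bias error
#' \eqn{MBE = \sum (Z'_i - Z_i) / n} (positive means over-prediction); and
#' median symmetric accuracy
#' \eqn{MSA = \exp(\mathrm{median}(|\ln(Z_i / Z'_i)|)) - 1}, a robust,
#' symmetric measure of typical proportional error.
#'
#' Pairs with a missing prediction are excluded and counted. MSA uses only
#' strictly positive pairs (the log ratio is undefined otherwise); the
#' number of pairs dropped for MSA is reported. `r` is missing when either
#' vector has zero variance.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return An object of class `metric_report`: `r`, `rmse`, `mae`, `mbe`,
#'   `msa`, `n`, `n_missing`, `n_msa`.
#' @export
error_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  n_missing <- sum(!ok)
  z <- observed[ok]
  zp <- predicted[ok]
  n <- length(z)
  if (n < 2L) stop("need at least 2 complete observation pairs",
                   call. = FALSE)
  e <- zp - z
  r <- if (sd(z) > 0 && sd(zp) > 0) cor(z, zp) else NA_real_
  pos <- z > 0 & zp > 0
  msa <- if (any(pos)) exp(median(abs(log(z[pos] / zp[pos])))) - 1
         else NA_real_
  structure(list(
    r = r, rmse = sqrt(mean(e^2)), mae = mean(abs(e)), mbe = mean(e),
    msa = msa, n = n, n_missing = n_missing, n_msa = sum(pos)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d (missing %d): r %.*g  RMSE %.*g  MAE %.*g  MBE %.*g  MSA %.*g\n",
              x$n, x$n_missing, digits, x$r, digits, x$rmse, digits, x$mae,
              digits, x$mbe, digits, x$msa))
  invisible(x)
}

metric_row <- function(m) {
  data.frame(r = m$r, rmse = m$rmse, mae = m$mae, mbe = m$mbe, msa = m$msa,
             n = m$n, n_missing = m$n_missing)
}

# shared CV engine: predict each held-out index set from the rest
cv_engine <- function(sites, values, spec, holdout_sets, fold_labels) {
  out <- vector("list", length(holdout_sets))
  for (f in seq_along(holdout_sets)) {
    ho <- holdout_sets[[f]]
    tr <- setdiff(seq_len(nrow(sites)), ho)
    res <- predict_with_method(sites[ho, , drop = FALSE],
                               sites[tr, , drop = FALSE], values[tr], spec)
    out[[f]] <- data.frame(
      site_id = if ("site_id" %in% names(sites)) sites$site_id[ho] else ho,
      region = if ("region" %in% names(sites)) sites$region[ho]
               else NA_character_,
      observed = values[ho], predicted = res$prediction,
      fold = fold_labels[f], stringsAsFactors = FALSE
    )
  }
  cv <- do.call(rbind, out)
  cv <- cv[order(match(cv$site_id,
                       if ("site_id" %in% names(sites)) sites$site_id
                       else seq_len(nrow(sites)))), , drop = FALSE]
  rownames(cv) <- NULL
  attr(cv, "method") <- spec$method
  class(cv) <- c("cv_result", class(cv))
  cv
}

#' Leave-one-out cross-validation
#'
#' Each site is dropped in turn and its value predicted from all remaining
#' sites; the paired observed/predicted values summarize predictive
#' accuracy via [error_metrics()]. For kriging methods the variogram model
#' in `spec$model` is fitted once on the full data and reused for every
#' fold: removing a single site from a large data set cannot materially
#' change the variogram, and refitting per fold would be prohibitive.
#'
#' @param sites Data frame with `x`/`y` (and optionally `site_id`,
#'   `region`) columns.
#' @param values Values at the sites.
#' @param spec Method specification (see [interpolate_grid()]).
#' @return A `cv_result` data frame: `site_id`, `region`, `observed`,
#'   `predicted`, `fold` (`"loo"`).
#' @export
loocv <- function(sites, values, spec) {
  cv_engine(sites, values, spec,
            holdout_sets = as.list(seq_len(nrow(sites))),
            fold_labels = rep("loo", nrow(sites)))
}

#' k-fold cross-validation
#'
#' Sites are partitioned into `k` random folds (uniform permutation under
#' `seed`); each fold is predicted from the others. `k = n` reproduces
#' leave-one-out exactly.
#'
#' @inheritParams loocv
#' @param k Number of folds (>= 2).
#' @param seed Seed for the fold assignment (mandatory: fold assignment
#'   must be reproducible).
#' @return A `cv_result` data frame with integer `fold` labels.
#' @export
kfold_cv <- function(sites, values, spec, k = 5, seed) {
  n <- nrow(sites)
  stopifnot(k >= 2, k <= n)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  cv_engine(sites, values, spec,
            holdout_sets = split(seq_len(n), fold),
            fold_labels = seq_len(k))
}

#' Summarize a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A `metric_report` over all held-out pairs.
#' @export
summary.cv_result <- function(object, ...) {
  error_metrics(object$observed, object$predicted)
}

#' Optimize inverse-distance weighting parameters by cross-validation
#'
#' Searches the mixed integer/continuous parameter space of IDW -- the
#' neighbour count `nmax` and the distance power `idp` -- for the pair
#' minimizing RMSE or MAE under k-fold cross-validation. The search scans
#' an integer grid on `nmax` and runs a golden-section line search on
#' `idp` for each candidate; fold assignments and per-fold neighbour
#' rankings are computed once and reused, so the search is deterministic
#' and fast.
#'
#' @inheritParams loocv
#' @param objective `"rmse"` or `"mae"`.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param nmax_grid Integer candidates for `nmax`.
#' @param idp_range Search interval for `idp`.
#' @return List `nmax`, `idp`, `objective`, `value`, and the per-`nmax`
#'   profile data frame.
#' @export
optimize_idw <- function(sites, values, objective = c("rmse", "mae"),
                         k = 5, seed = 1, nmax_grid = 1:30,
                         idp_range = c(0, 5)) {
  objective <- match.arg(objective)
  n <- nrow(sites)
  stopifnot(k >= 2, k <= n, all(nmax_grid >= 1))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  kmax <- min(max(nmax_grid), n - max(table(fold)))
  nmax_grid <- unique(pmin(nmax_grid, kmax))

  # per-fold neighbour rankings up to kmax, computed once
  folds <- lapply(seq_len(k), function(f) {
    ho <- which(fold == f)
    tr <- which(fold != f)
    nb <- knn_search(sites$x[ho], sites$y[ho], sites$x[tr], sites$y[tr], kmax)
    list(obs = values[ho], z = matrix(values[tr][nb$idx], nrow = length(ho)),
         d = nb$dist)
  })

  eval_pair <- function(nmax, idp) {
    err <- unlist(lapply(folds, function(fd) {
      d <- fd$d[, seq_len(nmax), drop = FALSE]
      z <- fd$z[, seq_len(nmax), drop = FALSE]
      w <- ifelse(d == 0, Inf, d^(-idp))
      pred <- numeric(nrow(d))
      exact <- rowSums(d == 0) > 0
      for (i in which(exact)) pred[i] <- z[i, which(d[i, ] == 0)[1]]
      if (any(!exact)) {
        if (idp == 0) {
          pred[!exact] <- rowMeans(z[!exact, , drop = FALSE])
        } else {
          wi <- w[!exact, , drop = FALSE]
          pred[!exact] <- rowSums(wi * z[!exact, , drop = FALSE]) /
            rowSums(wi)
        }
      }
      pred - fd$obs
    }))
    if (objective == "rmse") sqrt(mean(err^2)) else mean(abs(err))
  }

  profile <- data.frame(nmax = nmax_grid, idp = NA_real_, value = NA_real_)
  for (i in seq_along(nmax_grid)) {
    nm <- nmax_grid[i]
    o <- optimize(function(p) eval_pair(nm, p), interval = idp_range,
                  tol = 1e-3)
    profile$idp[i] <- o$minimum
    profile$value[i] <- o$objective
    # the unweighted-mean limit can beat any interior power for nmax = 1-like
    # degenerate cases; check the boundary too
    v0 <- eval_pair(nm, idp_range[1])
    if (v0 < profile$value[i]) {
      profile$idp[i] <- idp_range[1]
      profile$value[i] <- v0
    }
  }
  if (all(!is.finite(profile$value))) {
    stop("IDW objective non-finite for all candidates", call. = FALSE)
  }
  best <- which.min(profile$value)
  list(nmax = nmax_grid[best], idp = profile$idp[best],
       objective = objective, value = profile$value[best], profile = profile)
}

#' Per-region error metrics
#'
#' Computes [error_metrics()] separately for each administrative region
#' (province, territory, state) represented in a cross-validation result,
#' since the predictive accuracy of an interpolator can vary spatially.
#'
#' @param cv A `cv_result` with a `region` column.
#' @param min_n Regions with fewer pairs are skipped.
#' @return Data frame with one metric row per region.
#' @export
regional_metrics <- function(cv, min_n = 2) {
  stopifnot("region" %in% names(cv))
  regions <- sort(unique(cv$region[!is.na(cv$region)]))
  rows <- lapply(regions, function(rg) {
    sub <- cv[!is.na(cv$region) & cv$region == rg, , drop = FALSE]
    if (nrow(sub) < min_n) return(NULL)
    cbind(data.frame(region = rg, stringsAsFactors = FALSE),
          metric_row(error_metrics(sub$observed, sub$predicted)))
  })
  do.call(rbind, rows)
}

#' Rank interpolation methods and select the best
#'
#' Given metric reports for several methods evaluated on the same
#' cross-validation sites, identifies the winner of each metric
#' (higher-is-better: `r`; lower-is-better: RMSE, MAE, |MBE|, MSA) and
#' selects as overall best the method winning the most of the four key
#' metrics r, RMSE, MAE and MBE; MSA is reported but treated as secondary,
#' being a proportional-error measure on a different scale. Ties are
#' reported as joint-best, never silently broken.
#'
#' @param reports Named list of `metric_report`s (names = method labels).
#' @param tol Relative tolerance within which two metric values are
#'   considered tied.
#' @return List with `table` (metrics by method), `winners` (per metric),
#'   `best` (character vector; length > 1 means joint-best).
#' @export
select_method <- function(reports, tol = 1e-9) {
  stopifnot(length(reports) >= 2L, !is.null(names(reports)))
  tab <- do.call(rbind, lapply(reports, metric_row))
  tab <- cbind(data.frame(method = names(reports), stringsAsFactors = FALSE),
               tab)
  rownames(tab) <- NULL
  winners_of <- function(v, lower_better) {
    v <- if (lower_better) v else -v
    best <- min(v, na.rm = TRUE)
    tab$method[!is.na(v) & v <= best + tol * max(abs(best), 1)]
  }
  winners <- list(
    r = winners_of(tab$r, FALSE),
    rmse = winners_of(tab$rmse, TRUE),
    mae = winners_of(tab$mae, TRUE),
    mbe = winners_of(abs(tab$mbe), TRUE),
    msa = winners_of(tab$msa, TRUE)
  )
  key <- c("r", "rmse", "mae", "mbe")
  wins <- table(unlist(winners[key]))
  top <- max(wins)
  best <- sort(names(wins)[wins == top])
  list(table = tab, winners = winners, best = best)
}
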
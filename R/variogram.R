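#' Matern variogram model (Stein's parameterization)
#'
#' Constructs a semivariogram model
#' \deqn{\gamma(h) = c_0 \, 1[h > 0] + c_1 (1 - \rho_\kappa(h))}
#' with Matern correlation in Stein's parameterization,
#' \deqn{\rho_\kappa(h) = \frac{2^{1-\kappa}}{\Gamma(\kappa)}
#'   \left(\frac{2\sqrt{\kappa}\,h}{a}\right)^{\kappa}
#'   K_\kappa\!\left(\frac{2\sqrt{\kappa}\,h}{a}\right),}
#' in which the range parameter `a` stays comparable across smoothness
#' values. At \eqn{\kappa = 0.5} the model reduces to the exponential
#' variogram with effective range \eqn{a/\sqrt{2}}.
#'
#' @param nugget Nugget \eqn{c_0} (value^2, >= 0): micro-scale variation
#'   plus measurement error. Zero makes kriging an exact interpolator.
#' @param psill Partial sill \eqn{c_1} (value^2, >= 0; zero gives the
#'   pure-nugget limit).
#' @param range Range parameter `a`, metres (> 0).
#' @param kappa Smoothness \eqn{\kappa} (> 0).
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(nugget, psill, range, kappa = 0.5) {
  if (!is.finite(range) || range <= 0) stop("range must be > 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (nugget < 0 || psill < 0) stop("nugget and psill must be >= 0",
                                    call. = FALSE)
  structure(list(family = "matern_stein", nugget = nugget, psill = psill,
                 range = range, kappa = kappa),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "Matern/Stein variogram: nugget %.4g, partial sill %.4g, range %.4g m, kappa %.3g\n",
    x$nugget, x$psill, x$range, x$kappa))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  fit: weighted SSE %.4g over %d bins\n",
                x$diagnostics$sse, x$diagnostics$n_bins))
  }
  invisible(x)
}

# Matern correlation, Stein's parameterization; numerically safe at 0 and
# at large arguments (besselK underflows to 0, giving rho -> 0).
matern_stein_rho <- function(h, range, kappa) {
  x <- 2 * sqrt(kappa) * h / range
  rho <- x
  tiny <- x < 1e-10
  rho[tiny] <- 1
  xb <- x[!tiny]
  if (length(xb)) {
    rho[!tiny] <- 2^(1 - kappa) / gamma(kappa) * xb^kappa * besselK(xb, kappa)
  }
  pmin(pmax(rho, 0), 1)  # preserves dim() of h
}

#' Evaluate the Matern/Stein semivariogram
#'
#' @param h Distances (metres, >= 0).
#' @param model A [variogram_model()].
#' @return Semivariances; `gamma(0) = 0` exactly, approaching the nugget as
#'   `h -> 0+` and the total sill `nugget + psill` as `h -> Inf`.
#' @export
matern_stein_gamma <- function(h, model) {
  stopifnot(inherits(model, "variogram_model"), all(h >= 0))
  model$nugget * (h > 0) +
    model$psill * (1 - matern_stein_rho(h, model$range, model$kappa))
}

#' Empirical semivariogram
#'
#' Bins half squared differences \eqn{(z_i - z_j)^2 / 2} of all point pairs
#' by separation distance into `n_bins` equal-width bins up to `cutoff`.
#' For more than `max_exact` points a fixed-seed random subsample of pairs
#' is used to bound memory.
#'
#' @param x,y Planar coordinates, metres.
#' @param values Observed values at the points.
#' @param cutoff Maximum pair distance considered; default one third of the
#'   maximum (or, when subsampled, near-maximum) pairwise distance.
#' @param n_bins Number of distance bins.
#' @param max_exact Point count above which pairs are subsampled.
#' @param n_pairs Number of sampled pairs in the subsampled regime.
#' @param seed Seed for pair subsampling.
#' @return An object of class `empirical_variogram`: data frame `bins`
#'   (`dist`, `gamma`, `n_pairs`) plus `cutoff`.
#' @export
empirical_variogram <- function(x, y, values, cutoff = NULL, n_bins = 15,
                                max_exact = 5000, n_pairs = 2e6, seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n, n >= 2)
  if (n <= max_exact) {
    d <- as.vector(dist(cbind(x, y)))
    dz2 <- as.vector(dist(values))^2 / 2
  } else {
    set.seed(seed)
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    dz2 <- (values[i] - values[j])^2 / 2
  }
  if (all(d == 0)) stop("all points are coincident", call. = FALSE)
  if (is.null(cutoff)) cutoff <- max(d) / 3
  keep <- d > 0 & d <= cutoff
  d <- d[keep]; dz2 <- dz2[keep]
  if (!length(d)) stop("no point pairs within the cutoff", call. = FALSE)
  bin <- pmin(n_bins, 1L + floor(d / cutoff * n_bins))
  gamma_hat <- tapply(dz2, bin, mean)
  dist_mean <- tapply(d, bin, mean)
  counts <- tapply(d, bin, length)
  structure(list(
    bins = data.frame(dist = as.numeric(dist_mean),
                      gamma = as.numeric(gamma_hat),
                      n_pairs = as.integer(counts), row.names = NULL),
    cutoff = cutoff, n_points = n
  ), class = "empirical_variogram")
}

#' Fit a Matern/Stein model to an empirical variogram
#'
#' Weighted least squares with weights \eqn{N_j / \gamma(h_j)^2}
#' (pair count over squared model semivariance), re-evaluated iteratively.
#' The smoothness is chosen by profile search over `kappa_candidates`
#' rather than by gradient steps, since derivatives in the Bessel order are
#' ill-conditioned; each candidate's best weighted SSE decides.
#'
#' @param ev An [empirical_variogram()].
#' @param fix_nugget_zero Force the nugget to zero. A zero nugget makes the
#'   subsequent kriging honour the data exactly; fitting both variants and
#'   comparing them by cross-validation is standard practice.
#' @param kappa_candidates Smoothness values to profile over.
#' @param n_iter Reweighting iterations per candidate.
#' @return A [variogram_model()] with a `diagnostics` element
#'   (`sse`, `kappa_profile`, `n_bins`, `converged`).
#' @export
fit_variogram <- function(ev, fix_nugget_zero = FALSE,
                          kappa_candidates = c(0.05, 0.1, 0.2, 0.3, 0.5,
                                               1, 2, 5, 10),
                          n_iter = 4) {
  stopifnot(inherits(ev, "empirical_variogram"))
  b <- ev$bins
  if (nrow(b) < 4L) stop("need at least 4 variogram bins", call. = FALSE)
  h <- b$dist; g <- b$gamma; N <- b$n_pairs
  g_scale <- max(g)
  if (g_scale <= 0) stop("constant field: empirical variogram is zero",
                         call. = FALSE)

  fit_one <- function(kappa) {
    # parameters on log scale: (c0), c1, a
    gma <- function(par) {
      c0 <- if (fix_nugget_zero) 0 else exp(par[1])
      c1 <- exp(par[if (fix_nugget_zero) 1 else 2])
      a <- exp(par[if (fix_nugget_zero) 2 else 3])
      c0 + c1 * (1 - matern_stein_rho(h, a, kappa))
    }
    w <- N / pmax(g, g_scale * 1e-3)^2
    init <- log(c(if (!fix_nugget_zero) max(g_scale * 0.05, 1e-8) else NULL,
                  g_scale, max(h) / 2))
    par <- init
    value <- Inf
    conv <- FALSE
    for (it in seq_len(n_iter)) {
      obj <- function(p) sum(w * (gma(p) - g)^2)
      o <- tryCatch(optim(par, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)),
                    error = function(e) NULL)
      if (is.null(o)) break
      par <- o$par
      value <- o$value
      conv <- o$convergence == 0
      w <- N / pmax(gma(par), g_scale * 1e-3)^2
    }
    list(par = par, sse = value, converged = conv)
  }

  fits <- lapply(kappa_candidates, fit_one)
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  if (all(!is.finite(sses))) {
    stop("variogram fit failed for every kappa candidate", call. = FALSE)
  }
  best <- which.min(sses)
  par <- fits[[best]]$par
  kappa <- kappa_candidates[best]
  model <- if (fix_nugget_zero) {
    variogram_model(0, exp(par[1]), exp(par[2]), kappa)
  } else {
    variogram_model(exp(par[1]), exp(par[2]), exp(par[3]), kappa)
  }
  model$diagnostics <- list(
    sse = sses[best],
    kappa_profile = data.frame(kappa = kappa_candidates, sse = sses),
    n_bins = nrow(b),
    converged = fits[[best]]$converged
  )
  model
}

#' Serialize a variogram model to JSON
#'
#' Fitted models round-trip through JSON so interpolation runs are
#' reproducible without refitting.
#'
#' @param model A [variogram_model()].
#' @param path Output file path.
#' @export
write_variogram_json <- function(model, path) {
  stopifnot(inherits(model, "variogram_model"))
  out <- model[c("family", "nugget", "psill", "range", "kappa")]
  if (!is.null(model$diagnostics)) {
    out$diagnostics <- list(sse = model$diagnostics$sse,
                            n_bins = model$diagnostics$n_bins,
                            converged = model$diagnostics$converged)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a variogram model from JSON
#'
#' @param path Path written by [write_variogram_json()].
#' @return A [variogram_model()].
#' @export
read_variogram_json <- function(path) {
  j <- jsonlite::read_json(path)
  stopifnot(identical(j$family, "matern_stein"))
  variogram_model(j$nugget, j$psill, j$range, j$kappa)
}
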
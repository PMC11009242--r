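#' Nearest-neighbour prediction
#'
#' Each target takes the value of the closest site by planar distance;
#' ties at equal distance are broken by lowest site index.
#'
#' @param targets Data frame with `x`/`y` columns (metres).
#' @param sites Data frame with `x`/`y` columns.
#' @param values Values at the sites.
#' @return Data frame `x`, `y`, `prediction`, `variance` (all `NA`),
#'   `n_used`.
#' @export
nn_predict <- function(targets, sites, values) {
  stopifnot(nrow(sites) >= 1L, length(values) == nrow(sites))
  nb <- knn_search(targets$x, targets$y, sites$x, sites$y, 1L)
  data.frame(x = targets$x, y = targets$y,
             prediction = values[nb$idx[, 1]],
             variance = NA_real_, n_used = 1L)
}

#' Inverse-distance weighted prediction
#'
#' Weighted mean of the `nmax` nearest site values with weights
#' \eqn{d^{-idp}}. A target coincident with a site returns that site's
#' value exactly; `idp = 0` gives the unweighted mean of the neighbours.
#'
#' @inheritParams nn_predict
#' @param nmax Number of nearest sites used per target.
#' @param idp Inverse-distance power (>= 0).
#' @return Data frame `x`, `y`, `prediction`, `variance` (`NA`), `n_used`.
#' @export
idw_predict <- function(targets, sites, values, nmax = 15, idp = 2) {
  stopifnot(nrow(sites) >= 1L, length(values) == nrow(sites),
            nmax >= 1, idp >= 0)
  nb <- knn_search(targets$x, targets$y, sites$x, sites$y, nmax)
  k <- ncol(nb$idx)
  pred <- numeric(nrow(targets))
  for (t in seq_len(nrow(targets))) {
    d <- nb$dist[t, ]
    z <- values[nb$idx[t, ]]
    if (any(d == 0)) {
      pred[t] <- z[which(d == 0)[1]]
    } else if (length(z) == 1L) {
      pred[t] <- z  # single neighbour: exact, no weight arithmetic
    } else if (idp == 0) {
      pred[t] <- mean(z)
    } else {
      w <- d^(-idp)
      pred[t] <- sum(w * z) / sum(w)
    }
  }
  data.frame(x = targets$x, y = targets$y, prediction = pred,
             variance = NA_real_, n_used = as.integer(k))
}

#' Local ordinary kriging prediction with kriging variance
#'
#' For each target, the ordinary-kriging system is solved on the `nmax`
#' nearest sites: with semivariance matrix \eqn{\Gamma} among neighbours
#' and vector \eqn{\gamma_0} to the target, the augmented system
#' \deqn{\begin{pmatrix}\Gamma & 1\\ 1^\top & 0\end{pmatrix}
#'   \begin{pmatrix}\lambda\\ \mu\end{pmatrix} =
#'   \begin{pmatrix}\gamma_0\\ 1\end{pmatrix}}
#' yields weights summing to one, the prediction \eqn{\lambda^\top z} and
#' the kriging variance \eqn{\lambda^\top \gamma_0 + \mu}. The variance
#' grows with distance from data and, with a zero nugget, is exactly zero
#' at data sites.
#'
#' Targets with fewer than `nmin` distinct neighbours available are
#' returned missing rather than predicted from too little data. An
#' ill-conditioned system is retried with a tiny diagonal jitter
#' (`1e-10` times the sill); if it still fails the target is returned
#' missing with a warning. Tiny negative variances from round-off are
#' clamped to zero.
#'
#' @inheritParams nn_predict
#' @param model A [variogram_model()].
#' @param nmax Maximum neighbours per target (default 100).
#' @param nmin Minimum neighbours required (default 15).
#' @return Data frame `x`, `y`, `prediction`, `variance`, `n_used`.
#' @export
ok_predict <- function(targets, sites, values, model, nmax = 100, nmin = 15) {
  stopifnot(inherits(model, "variogram_model"),
            length(values) == nrow(sites), nmin >= 1, nmin <= nmax)
  n <- nrow(sites)
  dup <- duplicated(round(cbind(sites$x, sites$y), 6))
  if (any(dup)) {
    stop("duplicate site coordinates at row(s): ",
         paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  k <- min(nmax, n)
  nb <- knn_search(targets$x, targets$y, sites$x, sites$y, k)
  nt <- nrow(targets)
  pred <- rep(NA_real_, nt)
  vari <- rep(NA_real_, nt)
  used <- rep(0L, nt)
  sill <- model$nugget + model$psill
  n_singular <- 0L
  for (t in seq_len(nt)) {
    if (k < nmin) next
    idx <- nb$idx[t, ]
    nx <- sites$x[idx]; ny <- sites$y[idx]
    G <- matern_stein_gamma(as.matrix(dist(cbind(nx, ny))), model)
    dim(G) <- c(k, k)
    g0 <- matern_stein_gamma(nb$dist[t, ], model)
    A <- rbind(cbind(G, 1), c(rep(1, k), 0))
    bvec <- c(g0, 1)
    sol <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (is.null(sol)) {
      diag(A)[seq_len(k)] <- diag(A)[seq_len(k)] + 1e-10 * max(sill, 1)
      sol <- tryCatch(solve(A, bvec), error = function(e) NULL)
    }
    if (is.null(sol)) { n_singular <- n_singular + 1L; next }
    lambda <- sol[seq_len(k)]
    mu <- sol[k + 1L]
    pred[t] <- sum(lambda * values[idx])
    vari[t] <- max(0, sum(lambda * g0) + mu)
    used[t] <- k
  }
  if (n_singular > 0L) {
    warning(sprintf("%d target(s) skipped: singular kriging system",
                    n_singular))
  }
  data.frame(x = targets$x, y = targets$y, prediction = pred,
             variance = vari, n_used = used)
}

# normalize a method spec list into a canonical form
method_spec <- function(method, ...) {
  extra <- list(...)
  m <- tolower(method)
  if (!m %in% c("nn", "idw", "ok", "okzn", "ok-zn")) {
    stop("unknown method: ", method, call. = FALSE)
  }
  if (m == "ok-zn") m <- "okzn"
  c(list(method = m), extra)
}

predict_with_method <- function(targets, sites, values, spec) {
  switch(spec$method,
    nn = nn_predict(targets, sites, values),
    idw = idw_predict(targets, sites, values,
                      nmax = spec$nmax %||% 15, idp = spec$idp %||% 2),
    ok = ,
    okzn = ok_predict(targets, sites, values, spec$model,
                      nmax = spec$nmax %||% 100, nmin = spec$nmin %||% 15)
  )
}

#' Interpolate site values onto a grid
#'
#' Predicts at every cell centre of `grid` with the chosen method and
#' returns the prediction raster (plus a kriging-variance raster for
#' ordinary kriging).
#'
#' @param sites Data frame with `x`/`y` columns.
#' @param values Values at the sites.
#' @param spec Method specification: a list with `method` (`"nn"`,
#'   `"idw"`, `"ok"` or `"okzn"`) and method parameters (`nmax`, `idp`,
#'   `nmin`, `model` -- a [variogram_model()] for kriging).
#' @param grid A [grid_spec()].
#' @param variable Variable label stored with the field.
#' @return An object of class `interp_field`: `values` and optional
#'   `variance` matrices (row 1 = north), the `grid`, `variable`, `method`.
#' @export
interpolate_grid <- function(sites, values, spec, grid, variable = "value") {
  stopifnot(inherits(grid, "grid_spec"))
  centres <- build_grid(grid)
  res <- predict_with_method(centres, sites, values, spec)
  vals <- matrix(res$prediction, nrow = grid$n_rows, ncol = grid$n_cols,
                 byrow = TRUE)
  varm <- NULL
  if (spec$method %in% c("ok", "okzn")) {
    varm <- matrix(res$variance, nrow = grid$n_rows, ncol = grid$n_cols,
                   byrow = TRUE)
  }
  structure(list(values = vals, variance = varm, grid = grid,
                 variable = variable, method = spec$method, masked = FALSE),
            class = "interp_field")
}

#' @export
print.interp_field <- function(x, ...) {
  cat(sprintf("interp_field: %s by %s, %d x %d cells%s%s\n", x$variable,
              x$method, x$grid$n_cols, x$grid$n_rows,
              if (!is.null(x$variance)) ", with kriging variance" else "",
              if (isTRUE(x$masked)) ", masked" else ""))
  invisible(x)
}
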
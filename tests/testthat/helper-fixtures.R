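# shared in-code fixtures; all randomness is seeded per call

# canonical records data frame with sensible defaults, overridable per field
make_records <- function(n = 1, ...) {
  over <- list(...)
  n1 <- max(n, 1L)
  base <- data.frame(
    record_id = as.character(seq_len(n1)),
    site_id = paste0("s", seq_len(n1)),
    source_id = "src",
    latitude = rep(48, n1), longitude = rep(-96, n1),
    date = rep(as.Date("2015-06-01"), n1),
    variable = "calcium",
    value = rep(10, n1),
    units_raw = "mg/L",
    fraction = "unspecified",
    below_detection = FALSE,
    detection_limit = NA_real_,
    site_name = paste("Lake", seq_len(n1)),
    site_type = "Lake",
    region = "R1",
    stringsAsFactors = FALSE
  )
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base[seq_len(n), , drop = FALSE]
}

# random planar site layout + values in the working CRS
make_layout <- function(n, seed, extent = 1e5, values = NULL) {
  set.seed(seed)
  data.frame(
    site_id = paste0("s", seq_len(n)),
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    value = values %||% runif(n, 1, 50),
    region = sample(c("A", "B", "C"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exponential-family semivariogram, written independently of the package's
# Matern implementation; oracle for the kappa = 0.5 case
exp_gamma <- function(h, nugget, psill, range_stein) {
  nugget * (h > 0) + psill * (1 - exp(-sqrt(2) * h / range_stein))
}

# dense global ordinary-kriging oracle: full system over ALL sites, built
# from an explicit gamma function (independent of ok_predict internals)
global_ok_oracle <- function(tx, ty, sx, sy, z, gamma_fun) {
  n <- length(sx)
  D <- as.matrix(dist(cbind(sx, sy)))
  G <- gamma_fun(D)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  t(vapply(seq_along(tx), function(i) {
    g0 <- gamma_fun(sqrt((sx - tx[i])^2 + (sy - ty[i])^2))
    sol <- solve(A, c(g0, 1))
    lam <- sol[1:n]
    c(pred = sum(lam * z), var = sum(lam * g0) + sol[n + 1])
  }, numeric(2)))
}
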
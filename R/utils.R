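`%||%` <- function(a, b) if (is.null(a)) b else a

# k nearest sites for each target, brute force in chunks.
# Distances are planar Euclidean in the working CRS. Ties at equal distance
# are broken by lowest site index (order() is stable).
knn_search <- function(tx, ty, sx, sy, k) {
  n <- length(sx)
  stopifnot(n >= 1L, length(tx) == length(ty))
  k <- min(as.integer(k), n)
  nt <- length(tx)
  idx <- matrix(NA_integer_, nt, k)
  dmat <- matrix(NA_real_, nt, k)
  if (nt == 0L) return(list(idx = idx, dist = dmat))
  chunk <- max(1L, 4e6 %/% n)
  for (s in seq(1L, nt, by = chunk)) {
    e <- min(nt, s + chunk - 1L)
    d2 <- outer(tx[s:e], sx, "-")^2 + outer(ty[s:e], sy, "-")^2
    for (i in seq_len(e - s + 1L)) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- o
      dmat[s + i - 1L, ] <- sqrt(d2[i, o])
    }
  }
  list(idx = idx, dist = dmat)
}

# summary statistics used by both aggregation levels; quantiles are the
# default linear-interpolation convention (type 7)
value_stats <- function(v) {
  n <- length(v)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(
    median = q[2], mean = mean(v), sd = if (n > 1L) sd(v) else NA_real_,
    min = min(v), max = max(v), q25 = q[1], q75 = q[3], n = n
  )
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
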
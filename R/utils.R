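# Internal helpers: seed management, Otsu thresholding, Crofton direction
# weights.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic operations in the
# package run through this so they are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed for stream `k` of master `seed`, kept < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483587)
}

# Otsu threshold on a 256-bin histogram. Returns NA for degenerate
# (zero-spread) input; callers decide what an empty split means.
otsu_threshold <- function(x, n_bins = 256L) {
  hr <- cpp_otsu_hist(x, n_bins)
  r <- hr$range
  if (!all(is.finite(r)) || r[1] == r[2]) return(NA_real_)
  h <- hr$counts
  w <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * (r[2] - r[1])
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  mids[k] + 0.5 * (r[2] - r[1]) / n_bins
}

# The 13 lattice directions used by the Crofton surface estimator
# (3 axes, 6 face diagonals, 4 body diagonals), as (dz, dy, dx) steps.
crofton_dirs <- function() {
  rbind(
    c(0L, 0L, 1L), c(0L, 1L, 0L), c(1L, 0L, 0L),
    c(0L, 1L, 1L), c(0L, 1L, -1L), c(1L, 0L, 1L), c(1L, 0L, -1L),
    c(1L, 1L, 0L), c(1L, -1L, 0L),
    c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L)
  )
}

.crofton_cache <- new.env(parent = emptyenv())

# Solid-angle weights of the 13 directions: the fraction of the unit sphere
# closer to each direction (or its antipode) than to any other, computed by
# deterministic Fibonacci-lattice quadrature and cached per spacing.
crofton_weights <- function(spacing) {
  key <- paste(signif(spacing, 12), collapse = "_")
  if (!is.null(.crofton_cache[[key]])) return(.crofton_cache[[key]])
  dirs <- crofton_dirs()
  vecs <- matrix(0, 26, 3)
  for (k in seq_len(13)) {
    v <- dirs[k, ] * spacing
    v <- v / sqrt(sum(v^2))
    vecs[2 * k - 1, ] <- v
    vecs[2 * k, ] <- -v
  }
  n <- 200000L
  i <- seq_len(n) - 1
  golden <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / golden
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(z, rho * sin(theta), rho * cos(theta))
  best <- max.col(pts %*% t(vecs), ties.method = "first")
  cnt <- tabulate(best, nbins = 26L) / n
  w <- cnt[seq(1, 26, by = 2)] + cnt[seq(2, 26, by = 2)]
  .crofton_cache[[key]] <- w
  w
}

voxel_volume <- function(spacing) prod(spacing)

stack_dim <- function(x) as.integer(dim(x))

# full garbage collection plus malloc_trim: the large-array pipeline stages
# allocate C++ scratch buffers the R heap accounting never sees, so collect
# eagerly and hand freed pages back to the OS at stage boundaries
reclaim_memory <- function() {
  gc(FALSE)
  cpp_malloc_trim()
  invisible(NULL)
}
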
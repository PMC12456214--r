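#' Kernel density estimate of a morphometry distribution
#'
#' Gaussian-kernel KDE evaluated on a 512-point grid spanning the data
#' range plus three bandwidths on each side. The default bandwidth is the
#' Silverman rule of thumb `0.9 * min(sd, IQR/1.34) * n^(-1/5)`
#' (`stats::bw.nrd0`, the default of `geom_density()`), so curves are
#' directly comparable with ggplot2 density plots.
#'
#' @param values numeric sample (n >= 2, non-zero spread).
#' @param bandwidth optional bandwidth in the units of `values`.
#' @return a `density_estimate`: list with `grid`, `density`, `bandwidth`,
#'   `n`.
#' @export
estimate_density <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("input error: need at least 2 finite values", call. = FALSE)
  if (diff(range(values)) == 0)
    stop("input error: zero spread", call. = FALSE)
  bw <- if (is.null(bandwidth)) bw.nrd0(values) else bandwidth
  if (bw <= 0) stop("bandwidth must be positive", call. = FALSE)
  dd <- density(values, bw = bw, n = 512L,
                from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  structure(list(grid = dd$x, density = dd$y, bandwidth = bw,
                 n = length(values)), class = "density_estimate")
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup |ECDF_a - ECDF_b|` over the pooled sorted unique values
#' (right-continuous step ECDFs, so ties are handled by evaluating only at
#' the distinct pooled values).
#'
#' @param a,b numeric samples, both non-empty.
#' @return the statistic, a fraction in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b))
    stop("input error: both samples must be non-empty", call. = FALSE)
  pts <- sort(unique(c(a, b)))
  fa <- findInterval(pts, sort(a)) / length(a)
  fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Permutation two-sample Kolmogorov-Smirnov test
#'
#' Pools both samples and, for each of `m` permutations, randomly re-splits
#' the pool into groups of the original sizes and recomputes D. The
#' p-value uses the Phipson-Smyth estimator `p = (b + 1) / (m + 1)` with
#' `b` the number of permuted statistics at least as large as the observed
#' one (ties counted as exceedances, conservative), so p can never be zero
#' and its minimum at `m` permutations is `1 / (m + 1)`.
#'
#' @param a,b numeric samples, both non-empty.
#' @param m number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return a `ks_result`: `d_observed`, `m_permutations`, `n_exceed`,
#'   `p_value`, `seed`, `group_sizes`.
#' @export
permutation_ks_test <- function(a, b, m = 10000L, seed = 1L) {
  if (!length(a) || !length(b))
    stop("input error: both samples must be non-empty", call. = FALSE)
  if (!is.numeric(m) || m < 1) stop("parameter error: `m` must be >= 1", call. = FALSE)
  m <- as.integer(m)
  pooled <- c(a, b)
  ord <- order(pooled)
  flags <- c(rep(1L, length(a)), rep(0L, length(b)))[ord]
  res <- with_seed(seed, cpp_perm_ks(pooled[ord], flags, length(a), length(b), m))
  n_exceed <- sum(res$d_perm >= res$d_observed)
  structure(list(d_observed = res$d_observed,
                 m_permutations = m,
                 n_exceed = n_exceed,
                 p_value = (n_exceed + 1) / (m + 1),
                 seed = as.integer(seed),
                 group_sizes = c(length(a), length(b))),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.3g (%d of %d permuted D >= observed; n = %d vs %d)\n",
              x$d_observed, x$p_value, x$n_exceed, x$m_permutations,
              x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Linear model for depot, sex and body-weight effects
#'
#' Ordinary least squares of a per-sample morphometry summary on tissue
#' (categorical), sex (categorical) and body weight (continuous), with
#' t-based p-values per coefficient. Fit on per-sample means (see
#' [sample_summaries()]) rather than per-cell values to avoid
#' pseudo-replication.
#'
#' @param summaries data.frame with one row per sample: columns `tissue`,
#'   `sex`, `body_weight` and the response.
#' @param response `"mean_diameter"` or `"mean_sphericity"`.
#' @return an `effects_model`: coefficient table (estimate, standard error,
#'   t, p), response name, `n_samples`, and the underlying `lm` fit.
#' @export
fit_effects_model <- function(summaries,
                              response = c("mean_diameter", "mean_sphericity")) {
  response <- match.arg(response)
  need <- c("tissue", "sex", "body_weight", response)
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop(sprintf("schema error: missing column `%s`", miss[1]), call. = FALSE)
  for (term in c("tissue", "sex")) {
    lev <- unique(summaries[[term]])
    if (length(lev) < 2L)
      stop(sprintf("model error: term `%s` has a single level", term), call. = FALSE)
  }
  df <- data.frame(y = summaries[[response]],
                   tissue = factor(summaries$tissue),
                   sex = factor(summaries$sex),
                   body_weight = as.numeric(summaries$body_weight))
  fit <- lm(y ~ tissue + sex + body_weight, data = df)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)))
    stop(sprintf("model error: rank-deficient design (term `%s`)",
                 names(coef(fit))[which(is.na(coef(fit)))[1]]), call. = FALSE)
  structure(list(response = response,
                 coefficients = data.frame(term = rownames(cf),
                                           estimate = cf[, 1],
                                           std_error = cf[, 2],
                                           t_value = cf[, 3],
                                           p_value = cf[, 4],
                                           row.names = NULL),
                 n_samples = nrow(df),
                 fit = fit),
            class = "effects_model")
}

#' @export
print.effects_model <- function(x, ...) {
  cat(sprintf("<effects_model> %s ~ tissue + sex + body_weight (n = %d samples)\n",
              x$response, x$n_samples))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Term p-value of an effects model
#'
#' @param model an `effects_model`.
#' @param term coefficient name prefix (`"tissue"`, `"sex"`,
#'   `"body_weight"`).
#' @return the smallest p-value among the matching coefficients.
#' @export
term_p_value <- function(model, term) {
  stopifnot(inherits(model, "effects_model"))
  hit <- startsWith(model$coefficients$term, term)
  if (!any(hit)) stop(sprintf("no term `%s` in model", term), call. = FALSE)
  min(model$coefficients$p_value[hit])
}
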
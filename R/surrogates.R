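# Variogram estimation and variogram-matched spatially autocorrelated
# surrogate maps over the region atlas.

# pair bookkeeping shared by the variogram and the surrogate generator:
# truncated pair list (indices, distances) and equal-count bin assignment
.pair_bins <- function(D, n_bins = 25, truncate = 0.25) {
  m <- nrow(D)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  if (all(d == 0)) stop("all regions coincident", call. = FALSE)
  dmax <- stats::quantile(d, truncate)
  keep <- d <= dmax
  ii <- ut[keep, 1]; jj <- ut[keep, 2]; d <- d[keep]
  o <- order(d)
  ii <- ii[o]; jj <- jj[o]; d <- d[o]
  bin <- ceiling(seq_along(d) / (length(d) / n_bins))
  bin[bin > n_bins] <- n_bins
  list(ii = ii, jj = jj, d = d, bin = bin,
       centers = as.vector(tapply(d, bin, mean)),
       counts = as.vector(table(bin)))
}

.gamma_of <- function(x, pb) {
  g <- 0.5 * (x[pb$ii] - x[pb$jj])^2
  as.vector(rowsum(g, pb$bin)) / pb$counts
}

#' Empirical variogram of a regional map
#'
#' Semivariance `gamma(d) = mean over pairs at separation d of
#' 0.5 (x_i - x_j)^2`, with pairs grouped into equal-count distance bins
#' up to the 25th-percentile truncation distance (the smoothness-relevant
#' range).
#'
#' @param x numeric map over regions.
#' @param D distance matrix from [region_distances()].
#' @param n_bins number of equal-count bins (>= 3).
#' @param truncate distance-quantile truncation (default 0.25).
#' @return `variogram` data frame: `distance` (bin center), `gamma`,
#'   `n_pairs`.
#' @export
empirical_variogram <- function(x, D, n_bins = 25, truncate = 0.25) {
  stopifnot(n_bins >= 3, all(is.finite(x)), length(x) == nrow(D))
  pb <- .pair_bins(D, n_bins, truncate)
  out <- data.frame(distance = pb$centers, gamma = .gamma_of(x, pb),
                    n_pairs = pb$counts)
  class(out) <- c("variogram", "data.frame")
  out
}

#' Generate variogram-matched surrogate maps
#'
#' Per surrogate: the map values are randomly permuted, the permuted map
#' is smoothed with Gaussian distance-decay kernels over a log-spaced
#' bandwidth grid, and for each bandwidth a scale/offset pair (beta,
#' alpha) is fit by least squares so the candidate's variogram matches
#' the target variogram; the bandwidth with minimum variogram SSE is
#' kept, the surrogate being `sqrt(beta) * smoothed + sqrt(alpha) *
#' white noise`. With `resample = TRUE` (default) surrogate values are
#' replaced by the original value multiset via rank mapping, so null
#' distributions preserve the map's histogram.
#'
#' @param x target map over regions.
#' @param D distance matrix.
#' @param n number of surrogates (>= 1).
#' @param seed integer seed (surrogates are deterministic given
#'   `(x, D, seed, n)`).
#' @param resample rank-map surrogate values onto the original multiset.
#' @param n_bandwidths bandwidth-grid size (default 16).
#' @param n_draws noise realizations evaluated per bandwidth (default 2).
#' @param n_bins,truncate variogram settings (see
#'   [empirical_variogram()]).
#' @return matrix n x regions; each row one surrogate map.
#' @export
generate_surrogates <- function(x, D, n = 1000L, seed = 1L,
                                resample = TRUE, n_bandwidths = 16L,
                                n_draws = 2L, n_bins = 25,
                                truncate = 0.25) {
  stopifnot(n >= 1, length(x) == nrow(D))
  m <- length(x)
  pb <- .pair_bins(D, n_bins, truncate)
  g_t <- .gamma_of(x, pb)
  if (all(g_t == 0)) {
    # handled below (degenerate target)
  } else if (n_bins >= 8) {
    # match the loess-smoothed semivariance: individual bins are noisy
    # (tens of pairs each) and chasing them under-smooths the surrogates
    sm <- tryCatch(stats::fitted(stats::loess(g_t ~ pb$centers,
                                              span = 0.75)),
                   error = function(e) g_t)
    g_t <- pmax(sm, 0)
  }
  if (all(g_t == 0)) {
    warning("degenerate variogram (constant map); returning permutations")
    return(with_seed(seed,
      t(replicate(n, x[sample(m)]))))
  }
  # bandwidths spanning sub-neighbour to truncation scales, log-spaced:
  # kernels much wider than the variogram window cannot carry shape
  Doff <- D; diag(Doff) <- Inf
  nn_med <- stats::median(apply(Doff, 1, min))
  hs <- exp(seq(log(nn_med / 4), log(max(pb$d)),
                length.out = n_bandwidths))
  # all kernels stacked row-wise so every bandwidth smooths in one product
  Kbig <- do.call(rbind, lapply(hs, function(h) {
    K <- exp(-D^2 / (2 * h^2))
    K / rowSums(K)
  }))
  gammas_of <- function(M) {           # columns of M -> binned variograms
    G <- 0.5 * (M[pb$ii, , drop = FALSE] - M[pb$jj, , drop = FALSE])^2
    rowsum(G, pb$bin) / pb$counts
  }
  nh <- length(hs)
  nc <- nh * n_draws
  xs <- sort(x)
  out <- matrix(NA_real_, n, m)
  colnames(out) <- colnames(D)
  with_seed(seed, {
    for (s in seq_len(n)) {
      perm <- x[sample(m)]
      Y <- matrix(Kbig %*% perm, m, nh)          # smoothed at every h
      Gs <- gammas_of(Y)
      # per-bandwidth LS fit of g_t ~ beta * g_s + alpha
      beta <- alpha <- numeric(nh)
      for (j in seq_len(nh)) {
        cf <- stats::lm.fit(cbind(Gs[, j], 1), g_t)$coefficients
        beta[j] <- max(cf[1], 0); alpha[j] <- max(cf[2], 0)
      }
      Yc <- sweep(Y, 2, colMeans(Y))
      cand <- sweep(Yc[, rep(seq_len(nh), n_draws), drop = FALSE], 2,
                    rep(sqrt(beta), n_draws), "*") +
        sweep(matrix(stats::rnorm(m * nc), m, nc), 2,
              rep(sqrt(alpha), n_draws), "*") + mean(x)
      if (resample)
        cand <- apply(cand, 2, function(v)
          xs[rank(v, ties.method = "first")])
      # keep the candidate whose realized (post-noise, post-resampling)
      # variogram best matches the target
      sse <- colSums((gammas_of(cand) - g_t)^2)
      out[s, ] <- cand[, which.min(sse)]
    }
  })
  out
}
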
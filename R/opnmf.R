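# Nonnegativity transform, NNDSVD initialization, orthonormal projective
# NMF, and split-half stability rank selection.

#' Nonnegativity transform of a signed deviation matrix
#'
#' opNMF requires a nonnegative input. `shift` subtracts the global
#' minimum (preserving all pairwise contrasts and the additive
#' parts-based geometry; the default), `abs` takes magnitudes, and
#' `split` stacks the positive and negative parts vertically (the region
#' dimension doubles), keeping the sign information in separate rows.
#'
#' @param dev a `deviation_table` (subjects x regions) or a numeric
#'   matrix; it is transposed internally so rows are regions.
#' @param mode `"shift"`, `"abs"` or `"split"`.
#' @return `nonneg_matrix`: regions x subjects matrix (attributes
#'   `transform` and `offset` record the inversion).
#' @export
to_nonnegative <- function(dev, mode = c("shift", "abs", "split")) {
  mode <- match.arg(mode)
  Z <- t(unclass(as.matrix(dev)))
  if (all(Z == 0)) stop("all-zero matrix", call. = FALSE)
  offset <- 0
  X <- switch(mode,
    shift = {
      offset <- min(Z)
      if (offset < 0) Z - offset else Z
    },
    abs = abs(Z),
    split = {
      up <- pmax(Z, 0); dn <- pmax(-Z, 0)
      rn <- rownames(Z) %||% paste0("row", seq_len(nrow(Z)))
      rownames(up) <- paste0(rn, "+")
      rownames(dn) <- paste0(rn, "-")
      rbind(up, dn)
    })
  attr(X, "transform") <- mode
  attr(X, "offset") <- min(offset, 0)
  class(X) <- c("nonneg_matrix", class(X))
  X
}

#' Sparse NNDSVD initialization
#'
#' Nonnegative double singular value decomposition (sparse variant: zeros
#' are left as zeros). Column 1 is `sqrt(s1) |u1|`; for j >= 2 the
#' dominant of the positive/negative section pair of `(u_j, v_j)` is
#' kept.
#'
#' @param X nonnegative matrix (m x n).
#' @param k rank, `2 <= k <= min(m, n)`.
#' @return m x k nonnegative initialization matrix `W0`.
#' @export
nndsvd_init <- function(X, k) {
  X <- unclass(as.matrix(X))
  if (k > min(dim(X))) stop("k exceeds min(dim(X))", call. = FALSE)
  sv <- svd(X, nu = k, nv = k)
  W0 <- matrix(0, nrow(X), k)
  u1 <- sv$u[, 1]
  if (sum(u1) < 0) u1 <- -u1
  W0[, 1] <- sqrt(sv$d[1]) * abs(u1)
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      if (nup > 0) W0[, j] <- sqrt(sv$d[j] * nup * nvp) * up / nup
    } else {
      if (nun > 0) W0[, j] <- sqrt(sv$d[j] * nun * nvn) * un / nun
    }
  }
  W0
}

#' Fit orthonormal projective NMF
#'
#' Approximates `X ~ W W' X` with nonnegative `W` via the multiplicative
#' update `W <- W * (A W) / (W (W' A W))`, `A = X X'` precomputed and
#' `eps = 1e-16` guarding denominators; columns are L2-normalized each
#' iteration. Deterministic given `(X, W0)`. Stops when the relative
#' Frobenius change of `W` falls below `tol` or at `max_iter`.
#'
#' @param X nonnegative matrix, regions x subjects.
#' @param k rank (>= 1).
#' @param W0 initialization; default [nndsvd_init()].
#' @param max_iter iteration cap (default 50000).
#' @param tol relative-change tolerance (default 1e-5).
#' @return `opnmf_fit`: list with `W` (m x k, unit-L2 columns), `H = W'X`
#'   (k x n, nonnegative), `k`, `recon_error` (`||X - W H||_F`),
#'   `n_iter`, `converged`.
#' @export
opnmf_fit <- function(X, k, W0 = NULL, max_iter = 50000L, tol = 1e-5) {
  X <- unclass(as.matrix(X))
  if (k < 1) stop("k must be positive", call. = FALSE)
  if (any(X < 0)) stop("X must be nonnegative", call. = FALSE)
  if (is.null(W0)) W0 <- nndsvd_init(X, k)
  W0[W0 <= 0] <- 1e-12          # multiplicative updates cannot leave 0
  A <- tcrossprod(X)
  res <- opnmf_core(A, W0, as.integer(max_iter), tol, 1e-16)
  W <- res$W
  rownames(W) <- rownames(X)
  H <- crossprod(W, X)
  out <- list(W = W, H = H, k = as.integer(k),
              recon_error = norm(X - W %*% H, "F"),
              n_iter = res$n_iter, converged = res$converged)
  class(out) <- "opnmf_fit"
  out
}

#' @export
print.opnmf_fit <- function(x, ...) {
  cat(sprintf(
    "opNMF fit: %d regions x %d components, recon error %.4g (%d iter%s)\n",
    nrow(x$W), x$k, x$recon_error, x$n_iter,
    if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Split-half stability and reconstruction-error gradient across ranks
#'
#' For each of `n_splits` random halvings of the subjects and each rank
#' in `k_range`, opNMF is fit on both halves; component columns of the
#' two `W` matrices are paired by Hungarian assignment on their
#' cosine-similarity matrix and the split's stability is the mean Pearson
#' correlation of the paired columns. `stability(k)` averages over
#' splits; `gradient(k)` is the mean over splits of
#' `error(k) - error(k - 2)` (undefined for the two smallest ranks),
#' computed on the same split fits.
#'
#' @param X nonnegative matrix, regions x subjects (n >= 8).
#' @param k_range ranks to evaluate (default `2:20`).
#' @param n_splits number of random half-splits (default 100).
#' @param seed integer seed.
#' @param max_iter,tol per-fit convergence settings; half-cohort fits use
#'   a lower cap than a final fit since only relative structure matters.
#' @return `stability_curve` data frame: `k`, `stability`,
#'   `recon_error`, `error_gradient`, attribute `n_splits`.
#' @export
stability_analysis <- function(X, k_range = 2:20, n_splits = 100L,
                               seed = 1L, max_iter = 5000L, tol = 1e-4) {
  X <- unclass(as.matrix(X))
  n <- ncol(X)
  if (n < 8) stop("need at least 8 subjects", call. = FALSE)
  if (min(k_range) < 2) stop("k_range must start at 2 or above",
                             call. = FALSE)
  half <- floor(n / 2)
  if (max(k_range) > half)
    stop("k_range exceeds half-cohort size", call. = FALSE)
  nk <- length(k_range)
  stab <- err <- matrix(NA_real_, n_splits, nk)
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      idx <- sample(n)
      a <- idx[seq_len(half)]
      b <- idx[(half + 1):n]          # larger half takes the odd subject
      Xa <- X[, a, drop = FALSE]; Xb <- X[, b, drop = FALSE]
      for (j in seq_len(nk)) {
        k <- k_range[j]
        fa <- opnmf_fit(Xa, k, max_iter = max_iter, tol = tol)
        fb <- opnmf_fit(Xb, k, max_iter = max_iter, tol = tol)
        mt <- match_components(fa$W, fb$W)
        stab[s, j] <- mean(sapply(seq_len(k), function(i)
          stats::cor(fa$W[, i], fb$W[, mt$pairs[i]])))
        err[s, j] <- (fa$recon_error + fb$recon_error) / 2
      }
    }
  })
  grad <- rep(NA_real_, nk)
  for (j in seq_len(nk)) {
    prev <- match(k_range[j] - 2, k_range)
    if (!is.na(prev)) grad[j] <- mean(err[, j] - err[, prev])
  }
  out <- data.frame(k = k_range,
                    stability = colMeans(stab),
                    recon_error = colMeans(err),
                    error_gradient = grad)
  attr(out, "n_splits") <- n_splits
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' Advisory rank from a stability curve
#'
#' Returns the largest rank before the first sustained stability decline
#' (two consecutive drops exceeding `delta`), together with a
#' gradient-plateau indicator. The choice is advisory: the full curve is
#' always reported and meant to be inspected, mirroring how the rank is
#' chosen visually in practice.
#'
#' @param curve a `stability_curve` (>= 3 ranks).
#' @param delta minimum per-step stability drop counting towards a
#'   sustained decline (default 0.01).
#' @param plateau_tol maximum change between consecutive error gradients
#'   for the gradient to count as plateaued (default: a tenth of the
#'   gradient range).
#' @return list: `k` (advisory rank), `no_elbow` flag, `gradient_plateau_k`
#'   (smallest rank with plateaued gradient, or `NA`), `curve`.
#' @export
select_k <- function(curve, delta = 0.01, plateau_tol = NULL) {
  stopifnot(inherits(curve, "stability_curve"), nrow(curve) >= 3)
  s <- curve$stability; k <- curve$k
  drops <- -diff(s)                   # drop from k[j] to k[j+1]
  sustained <- which(drops[-length(drops)] > delta &
                     drops[-1] > delta)
  g <- curve$error_gradient
  gd <- abs(diff(g))
  if (is.null(plateau_tol))
    plateau_tol <- 0.1 * diff(range(g, na.rm = TRUE))
  plat <- which(!is.na(gd) & gd < plateau_tol)
  gradient_plateau_k <- if (length(plat)) k[min(plat) + 1] else NA_integer_
  if (length(sustained)) {
    list(k = k[sustained[1]], no_elbow = FALSE,
         gradient_plateau_k = gradient_plateau_k, curve = curve)
  } else {
    # monotone / flat curve: no elbow, boundary rank returned
    list(k = k[length(k)], no_elbow = TRUE,
         gradient_plateau_k = gradient_plateau_k, curve = curve)
  }
}

#' Write a factorization result to disk
#'
#' `W` goes to a region x component CSV aligned to the atlas (for surface
#' mapping elsewhere); the full result, including `H`, to JSON.
#'
#' @param fit an `opnmf_fit`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_factorization <- function(fit, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.frame(region_id = rownames(fit$W), fit$W)
    names(df)[-1] <- paste0("component_", seq_len(fit$k))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    write_json_file(list(k = fit$k, W = fit$W, H = fit$H,
                         recon_error = fit$recon_error,
                         n_iter = fit$n_iter,
                         converged = fit$converged), json_path)
  }
  invisible(c(csv_path, json_path))
}
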
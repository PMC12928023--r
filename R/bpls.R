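# Behavioral partial least squares: SVD of the brain-behavior
# cross-correlation matrix, permutation inference on latent variables,
# bootstrap ratios and loading confidence intervals.

# listwise deletion + validation shared by all bPLS entry points
.pls_prepare <- function(brain, behavior, floor = 10) {
  brain <- as.matrix(brain); behavior <- as.matrix(behavior)
  stopifnot(nrow(brain) == nrow(behavior))
  cc <- stats::complete.cases(brain) & stats::complete.cases(behavior)
  brain <- brain[cc, , drop = FALSE]
  behavior <- behavior[cc, , drop = FALSE]
  if (nrow(brain) < floor)
    stop("fewer than ", floor, " complete cases", call. = FALSE)
  list(brain = brain, behavior = behavior, complete = cc)
}

# core decomposition on complete data; sign convention: the largest-|.|
# element of each brain-salience column is made positive
.pls_core <- function(brain, behavior) {
  C <- stats::cor(brain, behavior)          # k x p cross-correlations
  sv <- svd(C)
  L <- min(ncol(brain), ncol(behavior))
  U <- sv$u[, seq_len(L), drop = FALSE]
  V <- sv$v[, seq_len(L), drop = FALSE]
  d <- sv$d[seq_len(L)]
  for (l in seq_len(L)) {
    j <- which.max(abs(U[, l]))
    if (U[j, l] < 0) { U[, l] <- -U[, l]; V[, l] <- -V[, l] }
  }
  list(C = C, u = U, v = V, d = d)
}

#' Fit behavioral PLS
#'
#' Listwise-deletes incomplete rows, z-scores both blocks, forms the
#' cross-correlation matrix `C` (components x behaviors) and decomposes
#' it, `C = U S V'`. Each latent variable (LV) pairs a brain salience
#' column of `U` with a behavior salience column of `V`; its singular
#' value is proportional to the brain-behavior covariance it captures,
#' summarized as covariance explained `s^2 / sum(s^2)`. Behavior loadings
#' are the correlations of each behavior variable with the brain latent
#' score, as typically plotted with bootstrap CIs.
#'
#' @param brain n x k subject component loadings (rows of `H` transposed).
#' @param behavior n x p behavior table (matrix or data frame).
#' @param floor minimum complete-case n (default 10).
#' @return `bpls_fit` object: `u` (k x L brain saliences), `v` (p x L
#'   behavior saliences), `d` singular values, `cov_explained`,
#'   `scores_brain`, `scores_behavior`, `behavior_loadings` (p x L
#'   correlations), `n`, `C`.
#' @export
bpls_fit <- function(brain, behavior, floor = 10) {
  prep <- .pls_prepare(brain, behavior, floor)
  Zb <- zscore_cols(prep$brain, "brain loadings")
  Zy <- zscore_cols(prep$behavior, "behavior")
  core <- .pls_core(prep$brain, prep$behavior)
  scores_brain <- Zb %*% core$u
  scores_behavior <- Zy %*% core$v
  out <- list(u = core$u, v = core$v, d = core$d,
              cov_explained = core$d^2 / sum(core$d^2),
              scores_brain = scores_brain,
              scores_behavior = scores_behavior,
              behavior_loadings = stats::cor(Zy, scores_brain),
              n = nrow(prep$brain), C = core$C,
              complete = prep$complete,
              brain = prep$brain, behavior = prep$behavior)
  class(out) <- "bpls_fit"
  out
}

#' @export
print.bpls_fit <- function(x, ...) {
  cat(sprintf("bPLS fit: n = %d, %d LVs; covariance explained: %s\n",
              x$n, length(x$d),
              paste(sprintf("%.1f%%", 100 * x$cov_explained),
                    collapse = ", ")))
  invisible(x)
}

#' Permutation test for latent variables
#'
#' Rows of the brain block are shuffled `n_perm` times; the decomposition
#' is recomputed and the singular value at each LV position is compared
#' with the observed one. P-values use the add-one (smoothed) estimator
#' `(1 + #\{s_perm >= s_obs\}) / (n_perm + 1)`.
#'
#' @param fit a [bpls_fit()] result.
#' @param n_perm number of permutations (default 10000, >= 100).
#' @param seed integer seed.
#' @param alpha significance threshold reported alongside (default 0.05).
#' @return data frame: `lv`, `singular_value`, `cov_explained`,
#'   `p_value`, `significant`.
#' @export
pls_permutation <- function(fit, n_perm = 10000L, seed = 1L,
                            alpha = 0.05) {
  stopifnot(inherits(fit, "bpls_fit"), n_perm >= 100)
  L <- length(fit$d)
  count <- integer(L)
  with_seed(seed, {
    n <- nrow(fit$brain)
    for (b in seq_len(n_perm)) {
      sp <- .pls_core(fit$brain[sample(n), , drop = FALSE],
                      fit$behavior)$d
      count <- count + (sp >= fit$d)
    }
  })
  p <- (1 + count) / (n_perm + 1)
  data.frame(lv = seq_len(L), singular_value = fit$d,
             cov_explained = fit$cov_explained, p_value = p,
             significant = p < alpha)
}

#' Bootstrap ratios and loading confidence intervals
#'
#' Subjects are resampled with replacement (paired brain/behavior rows)
#' and the decomposition refit; each resample's LVs are aligned to the
#' original solution by greedy correlation matching of the brain
#' saliences (with sign flips). The bootstrap ratio (BSR) of a variable
#' is its original salience divided by the SD of its bootstrap saliences;
#' `|BSR| > 1.96` flags significance at two-sided p = 0.05. Behavior
#' loading CIs are bootstrap percentiles (2.5/97.5%).
#'
#' @param fit a [bpls_fit()] result.
#' @param n_boot number of resamples (default 10000, >= 100).
#' @param seed integer seed.
#' @param threshold BSR significance threshold (default 1.96).
#' @return `pls_bootstrap` list: `bsr_brain` (k x L), `bsr_behavior`
#'   (p x L), `loading_ci_lower`/`upper` (p x L), significance flags,
#'   `n_boot`, `n_redrawn`.
#' @export
pls_bootstrap <- function(fit, n_boot = 10000L, seed = 1L,
                          threshold = 1.96) {
  stopifnot(inherits(fit, "bpls_fit"), n_boot >= 100)
  k <- nrow(fit$u); p <- nrow(fit$v); L <- length(fit$d)
  n <- nrow(fit$brain)
  boot_u <- array(NA_real_, c(k, L, n_boot))
  boot_v <- array(NA_real_, c(p, L, n_boot))
  boot_load <- array(NA_real_, c(p, L, n_boot))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample(n, replace = TRUE)
        br <- fit$brain[idx, , drop = FALSE]
        bh <- fit$behavior[idx, , drop = FALSE]
        if (all(apply(br, 2, stats::sd) > 0) &&
            all(apply(bh, 2, stats::sd) > 0)) break
        n_redrawn <- n_redrawn + 1L
      }
      core <- .pls_core(br, bh)
      # greedy alignment of resample LVs to the original by |corr| of
      # brain saliences
      avail <- seq_len(L)
      for (l in seq_len(L)) {
        cors <- vapply(avail, function(j)
          stats::cor(fit$u[, l], core$u[, j]), 0)
        pick <- avail[which.max(abs(cors))]
        sgn <- sign(cors[which.max(abs(cors))])
        if (sgn == 0) sgn <- 1
        boot_u[, l, b] <- sgn * core$u[, pick]
        boot_v[, l, b] <- sgn * core$v[, pick]
        boot_load[, l, b] <- stats::cor(scale(bh), scale(br) %*%
                                          (sgn * core$u[, pick]))
        avail <- setdiff(avail, pick)
      }
    }
  })
  if (n_redrawn > 0.01 * n_boot)
    warning("more than 1% of bootstrap resamples redrawn ",
            "(zero-variance columns)")
  sd_u <- apply(boot_u, c(1, 2), stats::sd)
  sd_v <- apply(boot_v, c(1, 2), stats::sd)
  bsr_brain <- fit$u / sd_u
  bsr_behavior <- fit$v / sd_v
  bsr_brain[sd_u == 0] <- NA
  bsr_behavior[sd_v == 0] <- NA
  out <- list(
    bsr_brain = bsr_brain,
    bsr_behavior = bsr_behavior,
    loading_ci_lower = apply(boot_load, c(1, 2), stats::quantile,
                             probs = 0.025, na.rm = TRUE),
    loading_ci_upper = apply(boot_load, c(1, 2), stats::quantile,
                             probs = 0.975, na.rm = TRUE),
    sig_brain = abs(bsr_brain) > threshold,
    sig_behavior = abs(bsr_behavior) > threshold,
    threshold = threshold, n_boot = n_boot, n_redrawn = n_redrawn)
  class(out) <- "pls_bootstrap"
  out
}

#' Behavioral PLS on named variable subsets
#'
#' Runs an independent fit (with listwise deletion per subset, so
#' complete-case n differs by subset) for each named group of behavior
#' columns, e.g. clinical versus cognitive variables.
#'
#' @param brain n x k loadings.
#' @param behavior n x p behavior table.
#' @param groups named list of character vectors (column names) or column
#'   indices.
#' @param floor minimum complete-case n per subset.
#' @return named list of [bpls_fit()] results (each records its `n`).
#' @export
pls_subsets <- function(brain, behavior, groups, floor = 10) {
  stopifnot(length(groups) >= 1)
  behavior <- as.data.frame(behavior)
  lapply(groups, function(g) {
    if (length(g) == 0) stop("empty variable subset", call. = FALSE)
    bpls_fit(brain, behavior[, g, drop = FALSE], floor = floor)
  })
}

#' Export bPLS results as tidy CSV-ready tables
#' @param fit a [bpls_fit()]; `boot` an optional [pls_bootstrap()].
#' @param boot optional bootstrap result to merge.
#' @return data frame with one row per (variable, lv): saliences,
#'   loadings, CIs, BSRs.
#' @export
pls_report <- function(fit, boot = NULL) {
  L <- length(fit$d)
  p <- nrow(fit$v)
  behav_names <- rownames(fit$v) %||% colnames(fit$behavior) %||%
    paste0("beh_", seq_len(p))
  out <- do.call(rbind, lapply(seq_len(L), function(l) {
    data.frame(lv = l, variable = behav_names,
               salience = fit$v[, l],
               loading = fit$behavior_loadings[, l],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(boot)) {
    out$ci_lower <- as.vector(boot$loading_ci_lower)
    out$ci_upper <- as.vector(boot$loading_ci_upper)
    out$bsr <- as.vector(boot$bsr_behavior)
    out$significant <- as.vector(boot$sig_behavior)
  }
  rownames(out) <- NULL
  out
}
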
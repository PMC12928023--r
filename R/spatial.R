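# Spatial association of component maps with molecular predictor sets:
# multilinear fit, dominance analysis, variogram-matched spatial nulls,
# distance-dependent cross-validation, and term-map decoding.

#' Multilinear spatial regression of a component map on predictor maps
#'
#' OLS of the standardized map on the standardized predictors with
#' intercept; `adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - q - 1)`.
#'
#' @param map numeric component map over regions (one column of `W`).
#' @param preds regions x q predictor matrix (standardized internally).
#' @param cond_max condition-number threshold for collinearity (1e10).
#' @return list: `r2`, `adj_r2`, `coef` (standardized), `fitted`,
#'   `residuals`, `n`, `q`.
#' @export
multilinear_fit <- function(map, preds, cond_max = 1e10) {
  preds <- as.matrix(preds)
  n <- length(map); q <- ncol(preds)
  stopifnot(nrow(preds) == n)
  if (n < q + 2) stop("need at least q + 2 regions", call. = FALSE)
  Zy <- drop(scale(map))
  Zx <- zscore_cols(preds, "predictors")
  kap <- kappa(crossprod(Zx), exact = TRUE)
  if (kap > cond_max) {
    cors <- stats::cor(Zx)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("collinear predictors (condition number ", format(kap, digits = 3),
         "): ", paste(colnames(preds)[worst], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Zx), Zy)
  r2 <- 1 - sum(fit$residuals^2) / sum((Zy - mean(Zy))^2)
  list(r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - q - 1),
       coef = fit$coefficients, fitted = fit$fitted.values,
       residuals = fit$residuals, n = n, q = q)
}

#' Dominance analysis of a multilinear spatial regression
#'
#' General dominance: each predictor's incremental R^2 when added to
#' every subset of the remaining predictors, averaged first within
#' subset-size strata and then across sizes. The dominances sum to the
#' full-model R^2 (the fundamental identity, asserted on every run);
#' percent contributions are dominance / R^2. The headline fit is also
#' reported as adjusted R^2. Exact enumeration (2^q - 1 subset models,
#' solved from a precomputed cross-product matrix) up to `exact_max`
#' predictors; beyond that, stratified subset sampling.
#'
#' @param map component map over regions.
#' @param preds regions x q predictor matrix.
#' @param exact_max largest q for exact enumeration (default 20).
#' @param n_samples subsets sampled per (predictor, size) stratum in
#'   sampling mode (default 200).
#' @param seed seed for sampling mode.
#' @return `dominance_result`: `r2`, `adj_r2`, `dominance` (named, sums
#'   to `r2`), `percent` (sums to 100), `method`.
#' @export
dominance <- function(map, preds, exact_max = 20L, n_samples = 200L,
                      seed = 1L) {
  preds <- as.matrix(preds)
  q <- ncol(preds)
  if (q == 0) stop("no predictors", call. = FALSE)
  labels <- colnames(preds) %||% paste0("x", seq_len(q))
  fit <- multilinear_fit(map, preds)
  Zy <- drop(scale(map)); Zx <- zscore_cols(preds)
  Cxx <- stats::cor(Zx)
  b <- drop(stats::cor(Zx, Zy))
  if (q <= exact_max) {
    res <- dominance_core(Cxx, b)
    dom <- drop(res$dominance)
    method <- "exact"
  } else {
    dom <- .dominance_sampled(Cxx, b, n_samples, seed)
    method <- "sampled"
  }
  names(dom) <- labels
  stopifnot(abs(sum(dom) - fit$r2) < 1e-6 || method == "sampled")
  out <- list(r2 = fit$r2, adj_r2 = fit$adj_r2, dominance = dom,
              percent = 100 * dom / fit$r2, method = method)
  class(out) <- "dominance_result"
  out
}

# stratified subset sampling for q > exact_max: for each predictor and
# each subset size, average the increment over sampled subsets
.dominance_sampled <- function(Cxx, b, n_samples, seed) {
  q <- length(b)
  r2_of <- function(idx) {
    if (!length(idx)) return(0)
    bs <- b[idx]
    drop(crossprod(bs, solve(Cxx[idx, idx, drop = FALSE], bs)))
  }
  with_seed(seed, {
    vapply(seq_len(q), function(j) {
      others <- setdiff(seq_len(q), j)
      size_means <- vapply(0:(q - 1), function(s) {
        total <- choose(q - 1, s)
        reps <- min(n_samples, total)
        inc <- vapply(seq_len(reps), function(r) {
          S <- if (s == 0) integer(0) else sample(others, s)
          r2_of(c(S, j)) - r2_of(S)
        }, 0)
        mean(inc)
      }, 0)
      mean(size_means)
    }, 0)
  })
}

#' Spatial-null significance of map-predictor fits
#'
#' The observed adjusted R^2 of each component map regressed on the
#' predictors is compared with the adjusted R^2 of variogram-matched
#' surrogates of the map ([generate_surrogates()]) regressed on the same
#' predictors: `p = (1 + #\{R2_surr >= R2_obs\}) / (n_surr + 1)`,
#' Benjamini-Hochberg FDR across the component family.
#'
#' @param maps regions x n_components matrix (or a single map vector).
#' @param preds regions x q predictor matrix.
#' @param D distance matrix for the surrogate generator.
#' @param n_surr surrogates per component (default 1000, >= 100).
#' @param seed integer seed.
#' @param alpha FDR significance level (default 0.05).
#' @return data frame: `component`, `adj_r2`, `p_value`, `q_value`,
#'   `significant`.
#' @export
spatial_null_test <- function(maps, preds, D, n_surr = 1000L, seed = 1L,
                              alpha = 0.05) {
  maps <- as.matrix(maps)
  if (length(unique(round(D[upper.tri(D)], 9))) < 3)
    stop("fewer than 3 distinct distances", call. = FALSE)
  stopifnot(n_surr >= 100)
  nc <- ncol(maps)
  obs <- p <- numeric(nc)
  for (cmp in seq_len(nc)) {
    obs[cmp] <- multilinear_fit(maps[, cmp], preds)$adj_r2
    surr <- generate_surrogates(maps[, cmp], D, n = n_surr,
                                seed = spawn_seed(seed,
                                                  paste0("comp", cmp)))
    r2s <- apply(surr, 1, function(s) multilinear_fit(s, preds)$adj_r2)
    p[cmp] <- (1 + sum(r2s >= obs[cmp])) / (n_surr + 1)
  }
  qv <- stats::p.adjust(p, method = "BH")
  data.frame(component = seq_len(nc), adj_r2 = obs, p_value = p,
             q_value = qv, significant = qv < alpha)
}

#' Distance-dependent cross-validation of a spatial model
#'
#' Each region serves once as source: the model is trained on the
#' nearest `ceil(train_fraction * m)` regions (by Euclidean centroid
#' distance, source included) and evaluated as the Pearson correlation
#' between predicted and empirical map values on the held-out regions.
#'
#' @param map component map over regions.
#' @param preds regions x q predictor matrix.
#' @param D distance matrix.
#' @param train_fraction fraction of regions in the training fold
#'   (default 0.25).
#' @return list: `fold_r` (per-source test correlations), `mean`,
#'   `quartiles`, `n_train`, `skipped` (folds with too few training
#'   regions).
#' @export
distance_dependent_cv <- function(map, preds, D, train_fraction = 0.25) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  preds <- as.matrix(preds)
  m <- length(map); q <- ncol(preds)
  n_train <- ceiling(train_fraction * m)
  fold_r <- rep(NA_real_, m)
  skipped <- 0L
  Zx <- zscore_cols(preds); Zy <- drop(scale(map))
  for (src in seq_len(m)) {
    train <- order(D[src, ])[seq_len(n_train)]   # includes src (d = 0)
    if (n_train < q + 2) { skipped <- skipped + 1L; next }
    test <- setdiff(seq_len(m), train)
    fit <- stats::lm.fit(cbind(1, Zx[train, , drop = FALSE]), Zy[train])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, Zx[test, , drop = FALSE]) %*% cf)
    fold_r[src] <- stats::cor(pred, Zy[test])
  }
  if (skipped > 0)
    warning(skipped, " fold(s) skipped: training fold smaller than q + 2")
  ok <- fold_r[!is.na(fold_r)]
  list(fold_r = fold_r, mean = mean(ok),
       quartiles = stats::quantile(ok, c(0.25, 0.5, 0.75)),
       n_train = n_train, skipped = skipped)
}

#' Decode a component map against meta-analytic term maps
#'
#' Pearson correlation between the component map and each term map, with
#' an association z-statistic (Fisher transform) thresholded at
#' `z_threshold` (default 3.1) and an explicit noise-term exclusion
#' list applied to the retained set.
#'
#' @param map component map over regions.
#' @param term_maps regions x terms matrix, rows aligned to the atlas
#'   (rownames checked against `names(map)` when both are present).
#' @param z_threshold retention threshold on the association z (3.1).
#' @param exclude character vector of noise terms to drop from the
#'   retained list.
#' @return list: `correlations` (data frame term/r/z/retained),
#'   `retained` (character), `n_retained`.
#' @export
decode_terms <- function(map, term_maps, z_threshold = 3.1,
                         exclude = character()) {
  term_maps <- as.matrix(term_maps)
  if (length(map) != nrow(term_maps))
    stop("term maps not aligned to the component map", call. = FALSE)
  if (!is.null(names(map)) && !is.null(rownames(term_maps)) &&
      !identical(names(map), rownames(term_maps)))
    stop("term maps not aligned to the component map", call. = FALSE)
  m <- length(map)
  r <- drop(stats::cor(map, term_maps))
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(m - 3)
  terms <- colnames(term_maps) %||% paste0("term_", seq_along(r))
  pass <- z > z_threshold
  retained <- setdiff(terms[pass], exclude)
  df <- data.frame(term = terms, r = r, z = z,
                   retained = terms %in% retained,
                   stringsAsFactors = FALSE)
  list(correlations = df, retained = retained,
       n_retained = length(retained))
}
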
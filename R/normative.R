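# Site harmonization, fractional-polynomial normative growth models, and
# deviation z-scoring.

.fp_grid <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' The fractional-polynomial power grid and FP2 pairs
#'
#' The standard Royston-Altman exponent set \{-2, -1, -0.5, 0, 0.5, 1, 2,
#' 3\}; power 0 denotes log. FP2 pairs allow repeats, a repeated power p
#' contributing `x^p` and `x^p log x`.
#'
#' @return `fp_power_pairs()` returns a 36 x 2 matrix of all FP2 pairs
#'   (p1 <= p2); `fp_powers()` the 8-element grid.
#' @export
fp_powers <- function() .fp_grid

#' @rdname fp_powers
#' @export
fp_power_pairs <- function() {
  g <- .fp_grid
  out <- do.call(rbind, lapply(seq_along(g), function(i)
    cbind(g[i], g[i:length(g)])))
  colnames(out) <- c("p1", "p2")
  out
}

#' Fractional-polynomial age basis
#'
#' Ages are divided by 10 before exponentiation for numerical
#' conditioning (this rescales coefficients, not predictions).
#'
#' @param age numeric vector of ages, years (> 0).
#' @param powers length-1 (FP1) or length-2 (FP2) vector from the grid.
#' @return matrix with one column per basis term.
#' @export
fp_basis <- function(age, powers) {
  x <- age / 10
  if (any(x <= 0)) stop("ages must be positive", call. = FALSE)
  tm <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1) {
    b <- cbind(tm(powers))
  } else if (powers[1] != powers[2]) {
    b <- cbind(tm(powers[1]), tm(powers[2]))
  } else {
    b <- cbind(tm(powers[1]), tm(powers[1]) * log(x))
  }
  colnames(b) <- paste0("fp", seq_len(ncol(b)))
  b
}

# design used to preserve biology during harmonization: flexible age
# basis + sex. Global-size covariates (mean CT, TIV) are deliberately NOT
# preserved here: they are themselves measured and carry the site effect,
# so conditioning on them would reabsorb the effect being removed. They
# enter the normative models afterwards.
.preserve_design <- function(demo) {
  cbind(fp_basis(demo$age, c(0.5, 2)),
        sex = as.numeric(demo$sex == "male"))
}

#' Empirical-Bayes site harmonization (ComBat-style)
#'
#' Location/scale harmonization of multi-site reference data with
#' parametric empirical-Bayes shrinkage of per-site, per-region effects,
#' estimated after regressing out a preserved biological design
#' (fractional-polynomial age basis + sex + mean-CT / TIV covariate) so
#' age, sex and global-size effects are retained. Single-site input is
#' returned unchanged with identity parameters.
#'
#' @param morph a `morphometry_table` (see [as_morphometry()]).
#' @param demo matching [as_demographics()] rows (same subject order).
#' @param atlas the [region_atlas()].
#' @return list: `harmonized` (morphometry table), `model` (class
#'   `harmonization_model`: per-site `gamma_star` location and
#'   `delta_star` scale per region, pooled `sigma`, `sites`).
#' @export
harmonize <- function(morph, demo, atlas) {
  stopifnot(nrow(morph) == nrow(demo))
  Y <- morphometry_matrix(morph)
  sites <- unique(demo$site)
  if (length(sites) == 1) {
    model <- list(sites = sites,
                  gamma_star = matrix(0, 1, ncol(Y),
                                      dimnames = list(sites, colnames(Y))),
                  delta_star = matrix(1, 1, ncol(Y),
                                      dimnames = list(sites, colnames(Y))),
                  sigma = rep(NA_real_, ncol(Y)))
    class(model) <- "harmonization_model"
    return(list(harmonized = morph, model = model))
  }
  tab <- table(demo$site)
  if (any(tab < 2))
    stop("each site needs at least 2 subjects", call. = FALSE)
  n <- nrow(Y); m <- ncol(Y)
  batch <- factor(demo$site, levels = sites)
  B <- stats::model.matrix(~ 0 + batch)            # n x n_sites
  is_ct <- atlas$structure_class == "cortical_thickness"
  n_i <- as.numeric(table(batch))

  gamma_hat <- delta_hat2 <- matrix(NA_real_, length(sites), m)
  Z <- matrix(NA_real_, n, m)
  sigma <- numeric(m)
  stand_mean <- matrix(NA_real_, n, m)
  X <- .preserve_design(demo)
  for (r in seq_len(m)) {
    fit <- stats::lm.fit(cbind(B, X), Y[, r])
    beta <- fit$coefficients
    if (anyNA(beta)) beta[is.na(beta)] <- 0
    gam <- beta[seq_along(sites)]
    alpha <- sum(n_i / n * gam)                    # weighted grand mean
    sm <- alpha + drop(X %*% beta[-seq_along(sites)])
    sigma[r] <- sqrt(sum(fit$residuals^2) / n)
    if (sigma[r] == 0) sigma[r] <- 1
    Z[, r] <- (Y[, r] - sm) / sigma[r]
    stand_mean[, r] <- sm
    for (i in seq_along(sites)) {
      zi <- Z[batch == sites[i], r]
      gamma_hat[i, r] <- mean(zi)
      delta_hat2[i, r] <- stats::var(zi)
    }
  }
  # a region constant within a site has no usable scale information
  raw_const <- t(vapply(sites, function(s)
    apply(Y[batch == s, , drop = FALSE], 2, stats::var) == 0,
    logical(m)))
  const <- delta_hat2 == 0 | !is.finite(delta_hat2) | raw_const
  if (any(const)) {
    warning("constant region within a site; scale clamped to 1")
    delta_hat2[const] <- 1
  }

  # parametric EB shrinkage (normal prior on location, inverse-gamma on
  # scale), iterated to convergence per site
  gamma_star <- delta_star <- matrix(NA_real_, length(sites), m,
                                     dimnames = list(sites, colnames(Y)))
  for (i in seq_along(sites)) {
    g <- gamma_hat[i, ]; d2 <- delta_hat2[i, ]
    g_bar <- mean(g); t2 <- stats::var(g)
    md <- mean(d2); s2d <- stats::var(d2)
    a_prior <- (2 * s2d + md^2) / s2d
    b_prior <- (md * s2d + md^3) / s2d
    ni <- n_i[i]
    zi <- Z[batch == sites[i], , drop = FALSE]
    g_new <- g; d_new <- d2
    for (it in 1:100) {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * ni * g + d_new * g_bar) / (t2 * ni + d_new)
      ss <- colSums((zi - matrix(g_new, ni, m, byrow = TRUE))^2)
      d_new <- (0.5 * ss + b_prior) / (ni / 2 + a_prior - 1)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-6) break
    }
    gamma_star[i, ] <- g_new
    delta_star[i, ] <- pmax(sqrt(d_new), 1e-8)
  }

  Yh <- Y
  for (i in seq_along(sites)) {
    idx <- batch == sites[i]
    Zadj <- sweep(sweep(Z[idx, , drop = FALSE], 2, gamma_star[i, ], "-"),
                  2, delta_star[i, ], "/")
    Yh[idx, ] <- stand_mean[idx, , drop = FALSE] +
      sweep(Zadj, 2, sigma, "*")
  }
  out <- morph
  out[, colnames(Yh)] <- Yh
  ct <- atlas_regions(atlas, "cortical_thickness")
  if (length(ct)) out$mean_ct <- rowMeans(Yh[, ct, drop = FALSE])
  model <- list(sites = sites, gamma_star = gamma_star,
                delta_star = delta_star, sigma = sigma)
  class(model) <- "harmonization_model"
  list(harmonized = out, model = model)
}

# exhaustive FP1 + FP2 search for one (region, sex) cell
.fit_fp_one <- function(y, age, covariate, criterion = "BIC") {
  n <- length(y)
  cand <- c(lapply(.fp_grid, function(p) p),
            lapply(seq_len(nrow(fp_power_pairs())), function(i)
              fp_power_pairs()[i, ]))
  best <- NULL
  for (pw in cand) {
    X <- cbind(1, fp_basis(age, pw), covariate = covariate)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    dropped <- anyNA(cf)
    if (dropped) cf[is.na(cf)] <- 0     # collinear terms dropped from fit
    rss <- sum(fit$residuals^2)
    p_eff <- fit$rank
    ic <- if (criterion == "AIC")
      n * log(rss / n) + 2 * (p_eff + 1) else
      n * log(rss / n) + (p_eff + 1) * log(n)
    if (is.null(best) || ic < best$ic) {
      best <- list(powers = unname(pw), ic = ic, rss = rss,
                   coef = cf, rank = p_eff,
                   dropped = dropped,
                   rmse = sqrt(rss / (n - p_eff)))
    }
  }
  best
}

#' Fit sex- and region-specific fractional-polynomial normative models
#'
#' For each region and sex, an exhaustive search over FP1 (8 powers) and
#' FP2 (36 power pairs) age bases, with the class covariate (mean CT for
#' thickness regions, TIV for volume regions), selects the model with
#' minimum BIC; coefficients by ordinary least squares. The stored RMSE is
#' the residual root-mean-squared error (df-adjusted) of the selected
#' model on the reference fit.
#'
#' @param morph harmonized reference `morphometry_table`.
#' @param demo matching demographics.
#' @param atlas the [region_atlas()].
#' @param min_per_sex minimum subjects per sex (default 20).
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return `normative_model_set`: nested list `models[[region]][[sex]]`
#'   with `powers`, `coef`, `rmse`, plus `age_range` and atlas metadata.
#' @export
fit_normative <- function(morph, demo, atlas, min_per_sex = 20,
                          criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(morph) == nrow(demo))
  if (stats::var(demo$age) == 0)
    stop("degenerate age distribution (zero variance)", call. = FALSE)
  tab <- table(demo$sex)
  if (length(tab) < 2 || any(tab < min_per_sex))
    stop("both sexes must be represented with >= ", min_per_sex,
         " subjects", call. = FALSE)
  Y <- morphometry_matrix(morph)
  is_ct <- atlas$structure_class == "cortical_thickness"
  models <- vector("list", ncol(Y))
  names(models) <- colnames(Y)
  warned <- FALSE
  for (r in seq_len(ncol(Y))) {
    covariate <- if (is_ct[r]) morph$mean_ct else morph$tiv
    per_sex <- list()
    for (s in c("male", "female")) {
      idx <- demo$sex == s
      f <- .fit_fp_one(Y[idx, r], demo$age[idx], covariate[idx], criterion)
      if (f$dropped && !warned) {
        warning("rank-deficient design; collinear terms dropped")
        warned <- TRUE
      }
      per_sex[[s]] <- list(powers = f$powers, coef = f$coef,
                           rmse = f$rmse)
    }
    models[[r]] <- per_sex
  }
  out <- list(models = models,
              region_ids = colnames(Y),
              is_ct = is_ct,
              age_range = range(demo$age),
              criterion = criterion)
  class(out) <- "normative_model_set"
  out
}

.predict_one <- function(mod, age, covariate) {
  X <- cbind(1, fp_basis(age, mod$powers), covariate = covariate)
  keep <- names(mod$coef)
  cf <- mod$coef
  cf[is.na(cf)] <- 0
  drop(X[, seq_along(cf), drop = FALSE] %*% cf)
}

#' Deviation z-scores against a normative model set
#'
#' `z = (observed - predicted) / RMSE` per subject x region, using the
#' region- and sex-specific model. Subjects with ages outside the training
#' range are flagged in the `extrapolated` attribute.
#'
#' @param models a `normative_model_set` from [fit_normative()].
#' @param morph target `morphometry_table`.
#' @param demo matching demographics (sex levels must be seen in
#'   training).
#' @return `deviation_table`: numeric matrix subjects x regions of
#'   dimensionless z-scores.
#' @export
deviation_scores <- function(models, morph, demo) {
  stopifnot(inherits(models, "normative_model_set"),
            nrow(morph) == nrow(demo))
  if (!all(demo$sex %in% c("male", "female")))
    stop("sex level unseen in training", call. = FALSE)
  Y <- morphometry_matrix(morph)
  Z <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (r in seq_len(ncol(Y))) {
    covariate <- if (models$is_ct[r]) morph$mean_ct else morph$tiv
    for (s in c("male", "female")) {
      idx <- demo$sex == s
      if (!any(idx)) next
      mod <- models$models[[r]][[s]]
      pred <- .predict_one(mod, demo$age[idx], covariate[idx])
      Z[idx, r] <- (Y[idx, r] - pred) / mod$rmse
    }
  }
  if (!all(is.finite(Z))) stop("non-finite deviation scores", call. = FALSE)
  attr(Z, "extrapolated") <- demo$age < models$age_range[1] |
    demo$age > models$age_range[2]
  class(Z) <- c("deviation_table", class(Z))
  Z
}

#' Evaluate normative-model transfer on held-out controls
#'
#' Per-region mean absolute error, RMSE and the fraction of controls with
#' `|z| > 1.96` (the nominal 5% extreme-deviation rate); regions whose
#' extreme rate exceeds `flag_rate` are flagged.
#'
#' @param models a `normative_model_set`.
#' @param morph control `morphometry_table` (disjoint from training).
#' @param demo matching demographics.
#' @param flag_rate extreme-rate threshold for flagging (default 0.15).
#' @return data frame: `region`, `mae`, `rmse`, `extreme_rate`, `flagged`.
#' @export
evaluate_controls <- function(models, morph, demo, flag_rate = 0.15) {
  if (nrow(morph) == 0) stop("empty control set", call. = FALSE)
  Z <- deviation_scores(models, morph, demo)
  Y <- morphometry_matrix(morph)
  res <- sapply(seq_len(ncol(Y)), function(r) {
    rmse_mod <- sapply(c("male", "female"), function(s)
      models$models[[r]][[s]]$rmse)
    zr <- Z[, r]
    err <- zr * rmse_mod[ifelse(demo$sex == "male", 1, 2)]
    c(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
      extreme_rate = mean(abs(zr) > 1.96))
  })
  out <- data.frame(region = colnames(Y), t(res),
                    stringsAsFactors = FALSE)
  out$flagged <- out$extreme_rate > flag_rate
  out
}

#' Serialize / restore a normative model set as JSON
#'
#' The JSON artifact (powers, coefficients, RMSE per region and sex, age
#' range) is sufficient to reproduce deviation scores exactly.
#'
#' @param models a `normative_model_set`.
#' @param path file path.
#' @return `read_normative` returns the model set; `write_normative`
#'   returns `path` invisibly.
#' @export
write_normative <- function(models, path) {
  payload <- list(region_ids = models$region_ids,
                  is_ct = models$is_ct,
                  age_range = models$age_range,
                  criterion = models$criterion,
                  models = models$models)
  write_json_file(payload, path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(p$models, function(rm) lapply(rm, function(sm) {
    cf <- unlist(sm$coef)
    list(powers = unlist(sm$powers), coef = cf, rmse = sm$rmse)
  }))
  out <- list(models = models, region_ids = p$region_ids,
              is_ct = p$is_ct, age_range = p$age_range,
              criterion = p$criterion)
  class(out) <- "normative_model_set"
  out
}
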
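# Harmonization, fractional-polynomial normative models, deviation scores.

test_that("single-site harmonization is the identity", {
  fx <- two_site_fixture(n = 60)
  one <- fx$demo$site == "A"
  h <- harmonize(fx$morph[one, ], fx$demo[one, ], fx$atlas)
  expect_identical(morphometry_matrix(h$harmonized),
                   morphometry_matrix(fx$morph[one, ]))
  expect_equal(unname(h$model$gamma_star[1, ]), rep(0, 8))
  expect_equal(unname(h$model$delta_star[1, ]), rep(1, 8))
})

test_that("planted site effects are removed while biology is preserved", {
  fx <- two_site_fixture(n = 400, shift = 0.3, scale = 1.4)
  h <- harmonize(fx$morph, fx$demo, fx$atlas)
  Yh <- morphometry_matrix(h$harmonized)
  # per-region site-difference t statistics on age/sex-residualized data
  ts <- vapply(1:8, function(r) {
    rs <- resid(lm(Yh[, r] ~ fp_basis(fx$demo$age, c(0.5, 2)) +
                     fx$demo$sex))
    unname(t.test(rs[fx$demo$site == "A"],
                  rs[fx$demo$site == "B"])$statistic)
  }, 0)
  expect_true(all(abs(ts) < 2))
  # planted age slope recovered within 5%
  sl <- vapply(1:8, function(r)
    unname(coef(lm(Yh[, r] ~ I(fx$demo$age / 10) + fx$demo$sex))[2]), 0)
  expect_true(all(abs(sl - fx$slope) / fx$slope < 0.05))
  # residual variance matched across sites (planted scale 1.4 removed)
  vr <- vapply(1:8, function(r) {
    rs <- resid(lm(Yh[, r] ~ fp_basis(fx$demo$age, c(0.5, 2)) +
                     fx$demo$sex))
    var(rs[fx$demo$site == "B"]) / var(rs[fx$demo$site == "A"])
  }, 0)
  expect_true(all(vr > 0.7 & vr < 1.4))
  # within-site subject ranking preserved per region
  Y0 <- morphometry_matrix(fx$morph)
  for (r in c(1, 5)) for (s in c("A", "B")) {
    idx <- fx$demo$site == s
    expect_gt(cor(Y0[idx, r], Yh[idx, r], method = "spearman"), 0.95)
  }
})

test_that("harmonization agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  fx <- two_site_fixture(n = 240)
  h <- harmonize(fx$morph, fx$demo, fx$atlas)
  mod <- cbind(1, fp_basis(fx$demo$age, c(0.5, 2)),
               as.numeric(fx$demo$sex == "male"))
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(morphometry_matrix(fx$morph)),
                batch = fx$demo$site, mod = mod)))
  expect_equal(morphometry_matrix(h$harmonized), ref, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("harmonization error and degenerate paths", {
  fx <- two_site_fixture(n = 60)
  demo <- fx$demo
  demo$site[demo$site == "B"] <- "A"
  demo$site[1] <- "B"                     # site with a single subject
  expect_error(harmonize(fx$morph, demo, fx$atlas), "at least 2")
  # constant region within a site: scale clamped with a warning
  morph <- fx$morph
  morph[fx$demo$site == "B", 3] <- 2.5
  expect_warning(harmonize(morph, fx$demo, fx$atlas), "clamped")
})

test_that("normative fit selects parsimonious models and validates input", {
  set.seed(21)
  n <- 300
  age <- runif(n, 3, 18)
  cov <- rnorm(n, 0, 0.05)
  # linear truth: FP1 with power 1 never loses to FP2 by BIC
  hits <- replicate(20, {
    y <- 1 + 0.5 * (age / 10) + 0.8 * cov + rnorm(n, 0, 0.05)
    f <- morphodev:::.fit_fp_one(y, age, cov)
    lin <- sum(lm.fit(cbind(1, fp_basis(age, 1), cov), y)$residuals^2)
    bic_lin <- n * log(lin / n) + 4 * log(n)
    expect_lte(f$ic, bic_lin + 1e-9)     # selected never worse than linear
    length(f$powers) == 1 && f$powers == 1
  })
  expect_gt(mean(hits), 0.7)
  fx <- two_site_fixture(n = 100)
  demo <- fx$demo; demo$age <- rep(10, 100)
  expect_error(fit_normative(fx$morph, demo, fx$atlas), "degenerate age")
  expect_error(fit_normative(fx$morph[1:25, ], fx$demo[1:25, ], fx$atlas),
               "sexes")
})

test_that("the generative age-curve is recovered even when the power labels are ambiguous", {
  # fractional-polynomial power pairs are near-collinear over ages 3-18:
  # the fitted CURVE pins down the truth far more tightly than the power
  # labels do, and the true pair is the modal selection
  set.seed(22)
  n <- 400
  picks <- character(60); cerr <- numeric(60)
  for (i in 1:60) {
    age <- runif(n, 3, 18); x <- age / 10
    b1 <- runif(1, 0.05, 0.2); b2 <- runif(1, -0.13, -0.07)
    f <- b1 * x^0.5 + b2 * x^2
    cov <- rnorm(n, 0, 0.06)
    y <- 2.6 + f + 0.8 * cov + rnorm(n, 0, 0.05 * diff(range(f)))
    fit <- morphodev:::.fit_fp_one(y, age, cov)
    picks[i] <- paste(sort(fit$powers), collapse = ",")
    ag <- seq(3, 18, length.out = 50); xg <- ag / 10
    pred <- drop(cbind(1, fp_basis(ag, fit$powers), 0) %*% fit$coef)
    truth <- 2.6 + b1 * xg^0.5 + b2 * xg^2
    cerr[i] <- sqrt(mean((pred - truth)^2)) / diff(range(truth))
  }
  expect_equal(names(sort(table(picks), decreasing = TRUE))[1], "0.5,2")
  expect_lt(max(cerr), 0.02)    # fitted curve within 2% of the truth
})

test_that("reference-fit residuals are orthogonal to the design", {
  fx <- two_site_fixture(n = 200)
  h <- harmonize(fx$morph, fx$demo, fx$atlas)
  mods <- fit_normative(h$harmonized, fx$demo, fx$atlas)
  Y <- morphometry_matrix(h$harmonized)
  for (r in c(1, 4, 8)) for (s in c("male", "female")) {
    idx <- fx$demo$sex == s
    mod <- mods$models[[r]][[s]]
    covariate <- if (mods$is_ct[r]) h$harmonized$mean_ct else
      h$harmonized$tiv
    X <- cbind(1, fp_basis(fx$demo$age[idx], mod$powers),
               covariate[idx])
    res <- Y[idx, r] - drop(X %*% mod$coef)
    # normalized projections of residuals on each design column
    expect_lt(max(abs(crossprod(X, res)) / colSums(X^2)^0.5 /
                    sqrt(sum(res^2))), 1e-8)
  }
})

test_that("deviation scores satisfy closed-form cases and calibration", {
  fx <- two_site_fixture(n = 300)
  h <- harmonize(fx$morph, fx$demo, fx$atlas)
  mods <- fit_normative(h$harmonized, fx$demo, fx$atlas)
  # applied back to the reference: mean ~ 0, SD ~ 1 per region
  z <- deviation_scores(mods, h$harmonized, fx$demo)
  expect_true(all(abs(colMeans(z)) < 0.05))
  expect_true(all(apply(z, 2, sd) > 0.95 & apply(z, 2, sd) < 1.05))
  # observed = predicted gives z = 0; one-RMSE residual gives z = 1
  pred <- morphometry_matrix(h$harmonized) - unclass(z) *
    matrix(vapply(seq_len(8), function(r)
      ifelse(fx$demo$sex == "male",
             mods$models[[r]]$male$rmse,
             mods$models[[r]]$female$rmse), numeric(300)), 300)
  df <- data.frame(subject_id = fx$demo$subject_id, pred,
                   tiv = fx$morph$tiv)
  names(df)[2:9] <- fx$atlas$region_id
  morph0 <- as_morphometry(df, fx$atlas)
  morph0$mean_ct <- h$harmonized$mean_ct   # covariate held fixed
  z0 <- deviation_scores(mods, morph0, fx$demo)
  expect_equal(max(abs(z0)), 0, tolerance = 1e-8)
  df1 <- df
  for (r in seq_len(8))
    df1[[r + 1]] <- df[[r + 1]] +
      ifelse(fx$demo$sex == "male",
             mods$models[[r]]$male$rmse, mods$models[[r]]$female$rmse)
  morph1 <- as_morphometry(df1, fx$atlas)
  morph1$mean_ct <- h$harmonized$mean_ct
  z1 <- deviation_scores(mods, morph1, fx$demo)
  expect_equal(unclass(z1), matrix(1, 300, 8), tolerance = 1e-8,
               ignore_attr = TRUE)
  demo_bad <- fx$demo; demo_bad$sex[1] <- "other"
  expect_error(deviation_scores(mods, fx$morph, demo_bad), "sex")
})

test_that("deviation scoring is invariant to re-uniting a region's measure", {
  fx <- two_site_fixture(n = 150)
  mods <- fit_normative(fx$morph, fx$demo, fx$atlas)
  z <- deviation_scores(mods, fx$morph, fx$demo)
  # rescale a subcortical region mm^3 -> cm^3-like units (x 1e-3); its
  # covariate (TIV) is a separate column, so scoring must be unchanged
  morph2 <- fx$morph
  sv <- atlas_regions(fx$atlas, "subcortical_volume")[1]
  morph2[[sv]] <- morph2[[sv]] * 1e-3
  mods2 <- fit_normative(morph2, fx$demo, fx$atlas)
  z2 <- deviation_scores(mods2, morph2, fx$demo)
  expect_equal(unclass(z2)[, sv], unclass(z)[, sv], tolerance = 1e-10)
})

test_that("control evaluation flags planted shifts and validates input", {
  fx <- two_site_fixture(n = 360)
  test <- seq(3, 360, by = 3)            # held out from both sites
  train <- setdiff(seq_len(360), test)
  mods <- fit_normative(fx$morph[train, ], fx$demo[train, ], fx$atlas)
  ev <- evaluate_controls(mods, fx$morph[test, ], fx$demo[test, ])
  expect_equal(nrow(ev), 8)
  # in-distribution controls: pooled extreme rate near the nominal 5%
  expect_lt(abs(mean(ev$extreme_rate) - 0.05), 0.03)
  # shift one region by +1 RMSE: its extreme rate jumps and is flagged
  morph_s <- fx$morph[test, ]
  r1 <- fx$atlas$region_id[1]
  rm1 <- mean(c(mods$models[[r1]]$male$rmse, mods$models[[r1]]$female$rmse))
  morph_s[[r1]] <- morph_s[[r1]] + rm1
  ev_s <- evaluate_controls(mods, morph_s, fx$demo[test, ])
  expect_gt(ev_s$extreme_rate[1], 0.15)
  expect_true(ev_s$flagged[1])
  expect_error(evaluate_controls(mods, fx$morph[integer(0), ],
                                 fx$demo[integer(0), ]), "empty")
})

test_that("normative models round-trip through JSON exactly", {
  fx <- two_site_fixture(n = 120)
  mods <- fit_normative(fx$morph, fx$demo, fx$atlas)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative(mods, path)
  back <- read_normative(path)
  z1 <- deviation_scores(mods, fx$morph, fx$demo)
  z2 <- deviation_scores(back, fx$morph, fx$demo)
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-12)
})
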
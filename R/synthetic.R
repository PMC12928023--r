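#' Simulation configuration for synthetic cohorts
#'
#' Defines the study conditions emulated by the generator: a two-site
#' reference cohort of typically developing children (203 + 254 subjects,
#' ages 3-18), a patient cohort (187 subjects, ages 4-18) carrying planted
#' nonnegative deviation components, and a matched control group (108).
#' The planted patient deviations are negative (regional thinning /
#' volume loss) in units of the per-region residual SD, so that pipeline
#' deviation z-scores recover them directly.
#'
#' @param n_reference total reference-cohort size (split across two sites).
#' @param site_split named integer vector of per-site reference counts.
#' @param n_patients number of patients.
#' @param n_controls number of scanner-matched healthy controls.
#' @param age_range_reference,age_range_patients age ranges in years.
#' @param k_true number of planted deviation components.
#' @param component_sparsity fraction of regions carrying each component.
#' @param deviation_effect mean planted loading magnitude, in residual-SD
#'   (RMSE) units; 0 plants nothing.
#' @param noise_sd residual-scale multiplier (1 = realistic measurement
#'   noise; smaller values shrink the residual SD of every region).
#' @param fp_powers age-curve fractional-polynomial powers planted in every
#'   region (length-2 numeric from the standard grid), or `"random"` to
#'   draw a pair per region.
#' @param behavior_weights p x k_true coupling matrix for
#'   [simulate_behavior()]; `NULL` uses the default (10 behavioral
#'   variables, variable 1 coupled to component 1, variable 3 weakly to
#'   component 3).
#' @param behavior_noise_sd behavioral noise SD.
#' @param missing_rate per-cell probability of missing behavior entries.
#' @param mnar if `TRUE`, missingness probability increases for
#'   low-scoring entries (noncompliance-style) instead of being completely
#'   at random.
#' @param seed integer; fixes all randomness end-to-end.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_reference = 457L,
                              site_split = c(CKG = 203L, PEK = 254L),
                              n_patients = 187L,
                              n_controls = 108L,
                              age_range_reference = c(3, 18),
                              age_range_patients = c(4, 18),
                              k_true = 8L,
                              component_sparsity = 0.12,
                              deviation_effect = 1,
                              noise_sd = 1,
                              fp_powers = c(0.5, 2),
                              behavior_weights = NULL,
                              behavior_noise_sd = 0.5,
                              missing_rate = 0.15,
                              mnar = FALSE,
                              seed = 1L) {
  stopifnot(n_reference >= 1, n_patients >= 1, n_controls >= 0,
            sum(site_split) == n_reference,
            component_sparsity > 0, component_sparsity <= 1,
            k_true >= 1, noise_sd > 0,
            missing_rate >= 0, missing_rate <= 1)
  cfg <- list(n_reference = as.integer(n_reference),
              site_split = site_split,
              n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              age_range_reference = age_range_reference,
              age_range_patients = age_range_patients,
              k_true = as.integer(k_true),
              component_sparsity = component_sparsity,
              deviation_effect = deviation_effect,
              noise_sd = noise_sd,
              fp_powers = fp_powers,
              behavior_weights = behavior_weights,
              behavior_noise_sd = behavior_noise_sd,
              missing_rate = missing_rate,
              mnar = mnar,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Fixed per-region generative parameters, drawn deterministically from the
# running RNG stream. CT baselines in mm, SV baselines in mm^3.
.region_params <- function(atlas, cfg) {
  m <- nrow(atlas)
  is_ct <- atlas$structure_class == "cortical_thickness"
  base_sv <- c(thalamus = 7500, caudate = 3800, putamen = 5200,
               pallidum = 1700, hippocampus = 4200, amygdala = 1700,
               accumbens = 600)
  struct <- sub("^[LR]_", "", atlas$region_id)
  baseline <- ifelse(is_ct, stats::runif(m, 2.3, 3.0), base_sv[struct])
  baseline <- baseline * stats::runif(m, 0.97, 1.03)
  # base_sigma is the realistic per-region residual scale; the planted
  # deviations are expressed in these fixed units so that lowering
  # noise_sd raises the deviation signal-to-noise ratio
  base_sigma <- ifelse(is_ct, 0.12, 0.06 * baseline)
  sigma <- cfg$noise_sd * base_sigma
  if (identical(cfg$fp_powers, "random")) {
    grid <- fp_power_pairs()
    idx <- sample(nrow(grid), m, replace = TRUE)
    powers <- grid[idx, , drop = FALSE]
  } else {
    powers <- matrix(rep(sort(cfg$fp_powers), each = m), m, 2)
  }
  # age-curve coefficients on the (age/10)-scaled basis; CT thins with
  # age, SV follows a rise-then-flatten growth curve
  b1 <- ifelse(is_ct, stats::runif(m, 0.05, 0.20),
               baseline * stats::runif(m, 0.10, 0.25))
  b2 <- ifelse(is_ct, stats::runif(m, -0.13, -0.07),
               baseline * stats::runif(m, -0.06, -0.02))
  sex_off <- ifelse(is_ct, stats::runif(m, -0.03, 0.03), 0.04 * baseline)
  tiv_beta <- ifelse(is_ct, 0, 0.10 * baseline / 1e5)
  list(baseline = baseline, sigma = sigma, base_sigma = base_sigma,
       powers = powers, b1 = b1, b2 = b2, sex_off = sex_off,
       tiv_beta = tiv_beta, is_ct = is_ct)
}

.fp_eval <- function(age, p) {
  x <- age / 10
  if (p == 0) log(x) else x^p
}

# measurement model for one group of subjects (no site effect, no planted
# deviations); returns list(measures matrix, tiv, mean-CT global factor)
.simulate_measures <- function(rp, age, sex, atlas) {
  n <- length(age); m <- nrow(atlas)
  male <- as.numeric(sex == "male")
  tiv <- 1.45e6 + 6e4 * male + 2.5e4 * (age / 10) + stats::rnorm(n, 0, 9e4)
  gfac <- stats::rnorm(n, 0, 0.06)      # subject-level global CT factor, mm
  meas <- matrix(0, n, m, dimnames = list(NULL, atlas$region_id))
  for (r in seq_len(m)) {
    f <- rp$b1[r] * .fp_eval(age, rp$powers[r, 1]) +
         rp$b2[r] * .fp_eval(age, rp$powers[r, 2])
    mu <- rp$baseline[r] + f + rp$sex_off[r] * male +
      rp$tiv_beta[r] * (tiv - 1.45e6)
    if (rp$is_ct[r]) mu <- mu + gfac
    meas[, r] <- mu
  }
  list(mu = meas, tiv = tiv)
}

.add_noise <- function(mu, rp, shift = 0, scale = 1) {
  n <- nrow(mu)
  eps <- matrix(stats::rnorm(length(mu)), n, ncol(mu))
  sweep(mu, 2, rp$sigma * shift, "+") +
    sweep(eps, 2, rp$sigma * scale, "*")
}

#' Simulate reference, patient and control cohorts with ground truth
#'
#' The reference cohort carries planted additive and multiplicative site
#' effects (so harmonization is identifiable); patients and controls come
#' from a third, unshifted site. Patient measures are additionally
#' perturbed by `-(W_true H_true)` scaled per region by the residual SD,
#' so the planted deviations are negative (thinning / volume loss) and
#' appear directly in downstream deviation z-scores.
#'
#' @param cfg a [simulation_config()].
#' @param atlas a [region_atlas()].
#' @return list with `reference`, `patients`, `controls` (each a list of
#'   `morphometry` and `demographics`), and `ground_truth` (class
#'   `ground_truth`: `W_true` regions x k with unit-L2 columns, `H_true`
#'   k x n_patients >= 0, `z_plant`, `site_effects`, `fp_powers_true`,
#'   `sigma`).
#' @export
simulate_cohorts <- function(cfg, atlas) {
  if (cfg$k_true > nrow(atlas))
    stop("k_true exceeds the number of regions", call. = FALSE)
  with_seed(cfg$seed, {
    m <- nrow(atlas)
    rp <- .region_params(atlas, cfg)
    site_effects <- data.frame(site = c(names(cfg$site_split), "HOSP"),
                               shift = c(-0.15, 0.12, 0),
                               scale = c(0.95, 1.10, 1))

    make_demo <- function(n, prefix, sites, ages, group) {
      data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
                 age = stats::runif(n, ages[1], ages[2]),
                 sex = sample(c("male", "female"), n, replace = TRUE),
                 site = sites, group = group, stringsAsFactors = FALSE)
    }

    ref_demo <- make_demo(cfg$n_reference, "REF",
                          rep(names(cfg$site_split), cfg$site_split),
                          cfg$age_range_reference, "reference")
    ref_sig <- .simulate_measures(rp, ref_demo$age, ref_demo$sex, atlas)
    ref_meas <- ref_sig$mu
    for (s in names(cfg$site_split)) {
      idx <- ref_demo$site == s
      se <- site_effects[site_effects$site == s, ]
      ref_meas[idx, ] <- .add_noise(ref_sig$mu[idx, , drop = FALSE], rp,
                                    shift = se$shift, scale = se$scale)
    }

    pat_demo <- make_demo(cfg$n_patients, "PAT", "HOSP",
                          cfg$age_range_patients, "patient")
    pat_demo$duration_illness <- round(stats::rlnorm(cfg$n_patients,
                                                     log(14), 0.9), 1)
    pat_demo$duration_medicine <- round(stats::rlnorm(cfg$n_patients,
                                                      log(13), 0.8), 1)
    pat_demo$dose <- round(stats::rlnorm(cfg$n_patients, log(0.6), 0.7), 2)
    pat_demo$seizure_frequency <- round(stats::rlnorm(cfg$n_patients,
                                                      log(2.5), 1.1), 1)
    # per-variable missingness mirroring the reported complete-case counts
    for (v in c("duration_illness", "seizure_frequency"))
      pat_demo[[v]][stats::runif(cfg$n_patients) < 0.107] <- NA
    for (v in c("duration_medicine", "dose"))
      pat_demo[[v]][stats::runif(cfg$n_patients) < 0.45] <- NA

    pat_sig <- .simulate_measures(rp, pat_demo$age, pat_demo$sex, atlas)
    pat_meas <- .add_noise(pat_sig$mu, rp)

    # planted nonnegative components: sparse mutually disjoint supports
    # where they fit, unit-L2 columns
    k <- cfg$k_true
    supp_size <- max(2L, round(cfg$component_sparsity * m))
    W_true <- matrix(0, m, k)
    if (k * supp_size <= m) {
      perm <- sample(m)
      for (c in seq_len(k)) {
        idx <- perm[((c - 1) * supp_size + 1):(c * supp_size)]
        W_true[idx, c] <- stats::runif(supp_size, 0.5, 1.5)
      }
    } else {
      for (c in seq_len(k))
        W_true[sample(m, supp_size), c] <- stats::runif(supp_size, 0.5, 1.5)
    }
    W_true <- sweep(W_true, 2, sqrt(colSums(W_true^2)), "/")
    H_true <- matrix(cfg$deviation_effect *
                       abs(stats::rnorm(k * cfg$n_patients)),
                     k, cfg$n_patients)
    z_plant <- -(W_true %*% H_true)           # negative = thinning/atrophy
    pat_meas <- pat_meas +
      t(z_plant) * rep(rp$base_sigma, each = cfg$n_patients)

    hc_demo <- make_demo(cfg$n_controls, "CTL", "HOSP",
                         cfg$age_range_patients, "control")
    hc_sig <- .simulate_measures(rp, hc_demo$age, hc_demo$sex, atlas)
    hc_meas <- .add_noise(hc_sig$mu, rp)

    wrap <- function(meas, tiv, demo) {
      df <- data.frame(subject_id = demo$subject_id,
                       stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(meas))
      df$tiv <- tiv
      as_morphometry(df, atlas)
    }

    gt <- list(W_true = W_true, H_true = H_true, z_plant = z_plant,
               site_effects = site_effects,
               fp_powers_true = rp$powers, sigma = rp$sigma,
               baseline = rp$baseline)
    class(gt) <- "ground_truth"

    list(reference = list(morphometry = wrap(ref_meas, ref_sig$tiv,
                                             ref_demo),
                          demographics = as_demographics(ref_demo)),
         patients = list(morphometry = wrap(pat_meas, pat_sig$tiv,
                                            pat_demo),
                         demographics = as_demographics(pat_demo)),
         controls = list(morphometry = wrap(hc_meas, hc_sig$tiv, hc_demo),
                         demographics = as_demographics(hc_demo)),
         ground_truth = gt)
  })
}

.default_behavior_names <- c(
  "age", "sex", "duration_illness", "duration_medicine", "dose",
  "seizure_frequency", "iq", "fs_comprehension", "fs_control",
  "fs_attention")

#' Simulate a behavior table coupled to planted component loadings
#'
#' Each behavioral variable is a weighted sum of the planted subject
#' loadings plus Gaussian noise; entries then go missing at
#' `cfg$missing_rate` (MCAR by default; set `cfg$mnar` for
#' noncompliance-style missingness concentrated in low scorers).
#'
#' @param gt `ground_truth` from [simulate_cohorts()].
#' @param cfg a [simulation_config()]; `cfg$behavior_weights` is a p x
#'   k_true matrix (default: 10 variables, variable 1 coupled to component
#'   1 with weight 1, variable 3 to component 3 with weight 0.6).
#' @return data frame `subject_id` + p behavior columns; attribute
#'   `saliences` holds the planted coupling matrix.
#' @export
simulate_behavior <- function(gt, cfg) {
  k <- nrow(gt$H_true); n <- ncol(gt$H_true)
  W <- cfg$behavior_weights
  if (is.null(W)) {
    W <- matrix(0, 10, k)
    W[1, 1] <- 1
    if (k >= 3) W[3, 3] <- 0.6
    rownames(W) <- .default_behavior_names
  }
  W <- as.matrix(W)
  if (nrow(W) < 1) stop("at least one behavioral variable required",
                        call. = FALSE)
  if (ncol(W) != k) stop("behavior_weights must have k_true columns",
                         call. = FALSE)
  with_seed(spawn_seed(cfg$seed, "behavior"), {
    p <- nrow(W)
    Y <- t(W %*% gt$H_true) +
      matrix(stats::rnorm(n * p, 0, cfg$behavior_noise_sd), n, p)
    if (cfg$missing_rate > 0) {
      if (cfg$mnar) {
        for (j in seq_len(p)) {
          pr <- pmin(1, 2 * cfg$missing_rate * (1 - rank(Y[, j]) / n))
          Y[stats::runif(n) < pr, j] <- NA
        }
      } else {
        Y[matrix(stats::runif(n * p) < cfg$missing_rate, n, p)] <- NA
      }
    }
    nm <- rownames(W) %||% paste0("beh_", seq_len(p))
    out <- data.frame(subject_id = sprintf("PAT%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    out[nm] <- as.data.frame(Y)
    attr(out, "saliences") <- W
    out
  })
}

.receptor_labels <- c("D1", "D2", "DAT", "5HT1a", "5HT1b", "5HT2a",
                      "5HT4", "5HT6", "5HTT", "NET", "NMDA", "mGluR5",
                      "GABAa", "a4b2", "M1", "VAChT", "H3", "MOR", "CB1")
.mito_labels <- c("CI", "CII", "CIV", "MitoD", "TRC", "MRC")

#' Simulate spatially autocorrelated molecular predictor maps
#'
#' Each map is a Gaussian random field over the region centroids with
#' exponential covariance `exp(-d / length_scale)`, standardized per
#' column. With `q = 19` the columns take the receptor/transporter labels
#' (D1 ... CB1); with `q = 6` the mitochondrial feature labels (CI ...
#' MRC). Optionally a target map is built as a stated linear combination
#' of a predictor subset plus spatially correlated noise, with the
#' coupling recorded as ground truth.
#'
#' @param atlas a [region_atlas()].
#' @param q number of predictor maps (>= 1).
#' @param length_scale autocorrelation length, mm (> 0).
#' @param seed integer seed.
#' @param target_subset optional indices of predictors forming the target.
#' @param target_weights weights for `target_subset` (default all 1).
#' @param target_noise SD of the smooth noise added to the target.
#' @return list: `maps` (regions x q matrix, standardized, labelled),
#'   `target` (or `NULL`), `coupling` ground truth.
#' @export
simulate_molecular_maps <- function(atlas, q, length_scale = 30, seed = 1L,
                                    target_subset = NULL,
                                    target_weights = NULL,
                                    target_noise = 0.3) {
  stopifnot(q >= 1, length_scale > 0)
  D <- region_distances(atlas)
  K <- exp(-D / length_scale)
  L <- tryCatch(chol(K + 1e-8 * diag(nrow(K))),
                error = function(e)
                  stop("covariance not positive definite after jitter",
                       call. = FALSE))
  with_seed(seed, {
    m <- nrow(K)
    maps <- crossprod(L, matrix(stats::rnorm(m * (q + 1)), m, q + 1))
    smooth_noise <- maps[, q + 1]
    maps <- scale(maps[, seq_len(q), drop = FALSE])
    colnames(maps) <- if (q == 19) .receptor_labels else
      if (q == 6) .mito_labels else paste0("mol_", seq_len(q))
    rownames(maps) <- atlas$region_id
    target <- NULL; coupling <- NULL
    if (!is.null(target_subset)) {
      w <- target_weights %||% rep(1, length(target_subset))
      target <- drop(maps[, target_subset, drop = FALSE] %*% w) +
        target_noise * drop(scale(smooth_noise))
      target <- drop(scale(target))
      names(target) <- atlas$region_id
      coupling <- list(subset = target_subset, weights = w,
                       noise = target_noise)
    }
    list(maps = maps, target = target, coupling = coupling)
  })
}
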
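# Orchestration: simulate -> harmonize -> normative -> deviations ->
# opNMF -> bPLS -> molecular association, from a single structured config
# with one master seed.

#' Pipeline configuration
#'
#' Collects every module parameter reachable from one structured object;
#' round-trips through YAML unchanged. The master `seed` deterministically
#' spawns per-stage seeds (stable hashing of stage names) so stages can
#' be rerun in isolation.
#'
#' @param simulation a [simulation_config()] (or a list of overrides for
#'   one).
#' @param k_range ranks for the stability analysis.
#' @param n_splits stability half-splits.
#' @param transform nonnegativity transform mode (see
#'   [to_nonnegative()]).
#' @param k rank of the final factorization; `NULL` uses the advisory
#'   rank from [select_k()].
#' @param n_perm,n_boot bPLS permutations / bootstrap resamples.
#' @param n_surr surrogates per component for the spatial null.
#' @param q_molecular number of molecular predictor maps.
#' @param length_scale molecular-map autocorrelation length, mm.
#' @param train_fraction distance-dependent CV training fraction.
#' @param bsr_threshold bootstrap-ratio significance threshold.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            k_range = 2:20, n_splits = 100L,
                            transform = "shift", k = NULL,
                            n_perm = 10000L, n_boot = 10000L,
                            n_surr = 1000L, q_molecular = 19L,
                            length_scale = 30, train_fraction = 0.25,
                            bsr_threshold = 1.96, seed = 1L) {
  if (!inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, as.list(simulation))
  cfg <- list(simulation = simulation, k_range = k_range,
              n_splits = as.integer(n_splits), transform = transform,
              k = k, n_perm = as.integer(n_perm),
              n_boot = as.integer(n_boot), n_surr = as.integer(n_surr),
              q_molecular = as.integer(q_molecular),
              length_scale = length_scale,
              train_fraction = train_fraction,
              bsr_threshold = bsr_threshold, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a [pipeline_config()]; `path` file path.
#' @param path file path.
#' @return `read_pipeline_config` returns the config; the writer returns
#'   `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$simulation <- unclass(plain$simulation)
  # named vectors serialize as YAML maps so the names survive the trip
  plain$simulation$site_split <- as.list(plain$simulation$site_split)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  if (!is.null(sim$site_split)) sim$site_split <- unlist(sim$site_split)
  raw$simulation <- do.call(simulation_config, sim)
  raw$k_range <- as.integer(unlist(raw$k_range))
  do.call(pipeline_config, raw)
}

.stage_log <- function(log, stage, t0, notes = NULL) {
  c(log, list(list(stage = stage,
                   seconds = round(as.numeric(Sys.time()) - t0, 2),
                   notes = notes)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing per-stage JSON/CSV artifacts, a
#' provenance log (seed, parameters, package version) and a summary
#' report under `outdir`. Identical config + seed reproduces every
#' output. A stage error aborts with the stage name; artifacts of
#' completed stages persist.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate","normative","decompose","pls","molecular")` to run
#'   (later stages recompute what they need from the config; default
#'   all).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "normative", "decompose",
                                    "pls", "molecular")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  res <- list()
  run_stage <- function(name, fun) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log <<- .stage_log(log, name, t0)
    out
  }

  atlas <- make_atlas(spawn_seed(config$seed, "atlas"))
  write_atlas(atlas, file.path(outdir, "atlas.json"))

  sim_cfg <- config$simulation
  sim_cfg$seed <- spawn_seed(config$seed, "simulate")
  res$cohorts <- run_stage("simulate", function() {
    co <- simulate_cohorts(sim_cfg, atlas)
    write_morphometry(co$reference$morphometry,
                      file.path(outdir, "reference_morphometry.csv"))
    write_morphometry(co$patients$morphometry,
                      file.path(outdir, "patient_morphometry.csv"))
    utils::write.csv(co$reference$demographics,
                     file.path(outdir, "reference_demographics.csv"),
                     row.names = FALSE)
    utils::write.csv(co$patients$demographics,
                     file.path(outdir, "patient_demographics.csv"),
                     row.names = FALSE)
    co
  })
  co <- res$cohorts

  if (!any(c("normative", "decompose", "pls", "molecular") %in% stages))
    return(.finish_pipeline(res, log, config, outdir))

  res$normative <- run_stage("normative", function() {
    h <- harmonize(co$reference$morphometry, co$reference$demographics,
                   atlas)
    models <- fit_normative(h$harmonized, co$reference$demographics,
                            atlas)
    write_normative(models, file.path(outdir, "normative_models.json"))
    dev <- deviation_scores(models, co$patients$morphometry,
                            co$patients$demographics)
    utils::write.csv(data.frame(subject_id = rownames(dev),
                                unclass(dev)),
                     file.path(outdir, "deviation_scores.csv"),
                     row.names = FALSE)
    ctl <- evaluate_controls(models, co$controls$morphometry,
                             co$controls$demographics)
    utils::write.csv(ctl, file.path(outdir, "control_evaluation.csv"),
                     row.names = FALSE)
    list(harmonized = h, models = models, deviations = dev,
         control_eval = ctl)
  })

  if (!any(c("decompose", "pls", "molecular") %in% stages))
    return(.finish_pipeline(res, log, config, outdir))

  res$decompose <- run_stage("decompose", function() {
    X <- to_nonnegative(res$normative$deviations, config$transform)
    curve <- adv <- NULL
    if (is.null(config$k)) {   # rank fixed in the config: skip the search
      curve <- stability_analysis(X, k_range = config$k_range,
                                  n_splits = config$n_splits,
                                  seed = spawn_seed(config$seed,
                                                    "stability"))
      utils::write.csv(curve, file.path(outdir, "stability_curve.csv"),
                       row.names = FALSE)
      adv <- select_k(curve)
    }
    k <- config$k %||% adv$k
    fit <- opnmf_fit(X, k)
    write_factorization(fit,
                        csv_path = file.path(outdir, "components_W.csv"),
                        json_path = file.path(outdir,
                                              "factorization.json"))
    list(X = X, curve = curve, advisory = adv, k = k, fit = fit)
  })

  if ("pls" %in% stages) {
    res$pls <- run_stage("pls", function() {
      behav <- simulate_behavior(co$ground_truth, sim_cfg)
      brain <- t(res$decompose$fit$H)
      fit <- bpls_fit(brain, behav[, -1])
      perm <- pls_permutation(fit, n_perm = config$n_perm,
                              seed = spawn_seed(config$seed, "perm"))
      boot <- pls_bootstrap(fit, n_boot = config$n_boot,
                            seed = spawn_seed(config$seed, "boot"),
                            threshold = config$bsr_threshold)
      utils::write.csv(pls_report(fit, boot),
                       file.path(outdir, "pls_loadings.csv"),
                       row.names = FALSE)
      utils::write.csv(perm, file.path(outdir, "pls_permutation.csv"),
                       row.names = FALSE)
      list(behavior = behav, fit = fit, permutation = perm,
           bootstrap = boot)
    })
  }

  if ("molecular" %in% stages) {
    res$molecular <- run_stage("molecular", function() {
      mol <- simulate_molecular_maps(atlas, q = config$q_molecular,
                                     length_scale = config$length_scale,
                                     seed = spawn_seed(config$seed,
                                                       "molecular"))
      W <- res$decompose$fit$W
      D <- region_distances(atlas)
      null_test <- spatial_null_test(W, mol$maps, D,
                                     n_surr = config$n_surr,
                                     seed = spawn_seed(config$seed,
                                                       "surrogates"))
      doms <- lapply(seq_len(ncol(W)), function(cmp)
        dominance(W[, cmp], mol$maps))
      cv <- lapply(seq_len(ncol(W)), function(cmp)
        distance_dependent_cv(W[, cmp], mol$maps, D,
                              config$train_fraction))
      tidy <- do.call(rbind, lapply(seq_len(ncol(W)), function(cmp)
        data.frame(component = cmp,
                   predictor = names(doms[[cmp]]$dominance),
                   dominance = doms[[cmp]]$dominance,
                   percent = doms[[cmp]]$percent,
                   adj_r2 = doms[[cmp]]$adj_r2,
                   p_value = null_test$p_value[cmp],
                   q_value = null_test$q_value[cmp],
                   row.names = NULL)))
      utils::write.csv(tidy, file.path(outdir, "molecular_dominance.csv"),
                       row.names = FALSE)
      utils::write.csv(null_test,
                       file.path(outdir, "molecular_null_test.csv"),
                       row.names = FALSE)
      list(maps = mol, null_test = null_test, dominance = doms, cv = cv)
    })
  }

  .finish_pipeline(res, log, config, outdir)
}

.finish_pipeline <- function(res, log, config, outdir) {
  prov <- list(
    package_version = as.character(utils::packageVersion("morphodev")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    parameters = list(k_range = config$k_range,
                      n_splits = config$n_splits,
                      transform = config$transform,
                      n_perm = config$n_perm, n_boot = config$n_boot,
                      n_surr = config$n_surr,
                      q_molecular = config$q_molecular,
                      length_scale = config$length_scale,
                      train_fraction = config$train_fraction),
    stages = log)
  write_json_file(prov, file.path(outdir, "provenance.json"))
  summary <- list(
    n_reference = config$simulation$n_reference,
    n_patients = config$simulation$n_patients,
    advisory_k = if (!is.null(res$decompose))
      res$decompose$advisory$k else NULL,
    k_used = res$decompose$k %||% NULL,
    lv1_p = if (!is.null(res$pls)) res$pls$permutation$p_value[1] else
      NULL,
    lv1_cov_explained = if (!is.null(res$pls))
      res$pls$fit$cov_explained[1] else NULL,
    files = list(
      deviations = "deviation_scores.csv",
      stability = "stability_curve.csv",
      components = "components_W.csv",
      pls = "pls_loadings.csv",
      molecular = "molecular_dominance.csv"))
  write_json_file(summary, file.path(outdir, "summary.json"))
  invisible(res)
}
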
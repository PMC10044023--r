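#' Pipeline configuration
#'
#' Bundles everything an end-to-end run needs. The cohort source is either
#' a [cohort_spec()] (synthetic source) or a CSV path in the event-record
#' dialect of [read_pk_dataset()]. One master seed drives every stochastic
#' stage through logged, stage-labelled sub-seeds.
#'
#' @param cohort A [cohort_spec()]; ignored when `dataset_path` is given.
#' @param dataset_path Optional path to an event-record CSV.
#' @param seed Master integer seed.
#' @param init Initial [pop_params()] for estimation.
#' @param n_bootstrap Bootstrap replicates.
#' @param vpc_sims VPC simulation replicates.
#' @param pta_replicates Monte Carlo PTA replicates.
#' @param mic MIC grid (mg/L).
#' @param out_dir Optional directory for CSV artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), dataset_path = NULL,
                            seed = 1L, init = pop_params(),
                            n_bootstrap = 1000, vpc_sims = 1000,
                            pta_replicates = 1000,
                            mic = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                            out_dir = NULL) {
  if (is.null(dataset_path)) stopifnot(inherits(cohort, "cohort_spec"))
  check_number(seed, "seed")
  for (nm in c("n_bootstrap", "vpc_sims", "pta_replicates")) {
    check_number(get(nm), nm, lower = 1)
  }
  structure(list(cohort = cohort, dataset_path = dataset_path, seed = seed,
                 init = init, n_bootstrap = n_bootstrap,
                 vpc_sims = vpc_sims, pta_replicates = pta_replicates,
                 mic = mic, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `seed`, `dataset_path`, `n_bootstrap`,
#' `vpc_sims`, `pta_replicates`, `mic`, `out_dir`, and an optional `cohort`
#' mapping whose entries override [cohort_spec()] defaults; group sizes go
#' under `sizes` (YAML reserves bare `n` as a boolean).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec_args <- list()
  if (!is.null(cfg$cohort)) {
    spec_args <- cfg$cohort
    if (!is.null(spec_args$sizes)) {
      spec_args$n <- unlist(spec_args$sizes)
      spec_args$sizes <- NULL
    }
  }
  spec <- do.call(cohort_spec, spec_args)
  args <- cfg[intersect(names(cfg), c("dataset_path", "seed", "n_bootstrap",
                                      "vpc_sims", "pta_replicates", "mic",
                                      "out_dir"))]
  do.call(pipeline_config, c(list(cohort = spec), args))
}

#' Run the full analysis pipeline
#'
#' Orders the stages of a complete population-PK / target-attainment
#' analysis: data acquisition and cleaning, base-model fit, stepwise
#' covariate analysis, bootstrap, prediction-corrected VPC, empirical Bayes
#' estimation, PK/PD target tables, exposure comparison, shift-vs-exact
#' comparison (synthetic source only) and the Monte Carlo PTA simulation.
#' Any stage failure halts the run with the stage name; artifacts computed
#' up to that point are returned/persisted.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list of stage artifacts plus a `manifest`
#'   recording the config hash and every stage seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list()
  artifacts <- list()
  persist <- function() {
    if (!is.null(config$out_dir)) write_artifacts(artifacts, config$out_dir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }
  sub_seed <- function(name) {
    seeds[[name]] <<- derive_seed(config$seed, name)
    seeds[[name]]
  }

  artifacts$dataset <- stage("dataset_io", {
    if (!is.null(config$dataset_path)) {
      read_pk_dataset(config$dataset_path) |> clean_dataset(quiet = TRUE)
    } else {
      cohort <- sample_cohort(config$cohort, sub_seed("cohort"))
      artifacts$truth <- cohort$truth
      clean_dataset(cohort$data, quiet = TRUE)
    }
  })
  artifacts$base_fit <- stage("fit", {
    fit_popk(artifacts$dataset, popk_model(), init = config$init)
  })
  artifacts$covariates <- stage("covariates", {
    covariate_step(artifacts$dataset, artifacts$base_fit)
  })
  final_fit <- artifacts$covariates$final_fit
  artifacts$final_fit <- final_fit

  artifacts$bootstrap <- stage("bootstrap", {
    bootstrap_popk(artifacts$dataset, final_fit$model,
                   n_replicates = config$n_bootstrap,
                   seed = sub_seed("bootstrap"), init = config$init)
  })
  artifacts$vpc <- stage("vpc", {
    pc_vpc(artifacts$dataset, final_fit, n_sim = config$vpc_sims,
           seed = sub_seed("vpc"))
  })
  artifacts$gof <- stage("gof", gof_tables(artifacts$dataset, final_fit))
  artifacts$ebe <- stage("empirical_bayes",
                         empirical_bayes(artifacts$dataset, final_fit))

  artifacts$pta_observed <- stage("target_attainment", {
    params <- artifacts$ebe
    if (!is.null(artifacts$truth)) {
      params <- params |>
        left_join(artifacts$truth |>
                    select("id", "misdosed", "short_course"), by = "id")
    }
    subj <- subject_profiles(artifacts$dataset, params)
    list(
      primary = pta_table(subj, config$mic, pkpd_target(0, 24, 0.5)),
      full_0_24 = pta_table(subj, config$mic, pkpd_target(0, 24, 1)),
      half_24_48 = pta_table(subj, config$mic, pkpd_target(24, 48, 0.5)),
      subjects = subj
    )
  })
  artifacts$exposure <- stage("exposure", {
    exposure_summary(artifacts$pta_observed$subjects)
  })
  artifacts$pta_simulation <- stage("pta_simulation", {
    simulate_pta(artifacts$dataset, fit_pop_params(final_fit),
                 n_replicates = config$pta_replicates, mic = config$mic,
                 seed = sub_seed("pta"))
  })

  artifacts$manifest <- tibble(
    key = c("config_hash", paste0("seed.", names(seeds)), "master_seed"),
    value = c(rlang::hash(config[setdiff(names(config), "out_dir")]),
              as.character(unlist(seeds)), as.character(config$seed))
  )
  persist_all <- function() {
    if (!is.null(config$out_dir)) write_artifacts(artifacts, config$out_dir)
  }
  persist_all()
  structure(artifacts, class = "pipeline_result")
}

# Flat-file persistence of the tabular artifacts (figures are byproducts;
# the numbers are the interface).
write_artifacts <- function(artifacts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }
  if (!is.null(artifacts$dataset)) write_pk_dataset(artifacts$dataset,
                                                    file.path(out_dir, "dataset.csv"))
  if (!is.null(artifacts$truth)) wr(artifacts$truth, "truth")
  if (!is.null(artifacts$base_fit)) wr(tidy(artifacts$base_fit), "base_fit")
  if (!is.null(artifacts$final_fit)) wr(tidy(artifacts$final_fit), "final_fit")
  if (!is.null(artifacts$covariates)) wr(artifacts$covariates$report, "covariate_step")
  if (!is.null(artifacts$bootstrap)) wr(artifacts$bootstrap$summary, "bootstrap")
  if (!is.null(artifacts$vpc)) wr(artifacts$vpc$bins, "vpc_bins")
  if (!is.null(artifacts$gof)) wr(artifacts$gof$obs, "gof_obs")
  if (!is.null(artifacts$ebe)) wr(artifacts$ebe, "ebe")
  if (!is.null(artifacts$pta_observed)) {
    wr(artifacts$pta_observed$primary, "pta_primary")
    wr(artifacts$pta_observed$full_0_24, "pta_full_0_24")
    wr(artifacts$pta_observed$half_24_48, "pta_half_24_48")
  }
  if (!is.null(artifacts$exposure)) {
    wr(artifacts$exposure$by_group, "exposure_by_group")
    wr(artifacts$exposure$tests, "exposure_tests")
  }
  if (!is.null(artifacts$pta_simulation)) {
    wr(artifacts$pta_simulation$pooled, "pta_simulation_pooled")
    wr(artifacts$pta_simulation$replicate_summary, "pta_simulation_spread")
  }
  if (!is.null(artifacts$manifest)) wr(artifacts$manifest, "manifest")
  invisible(out_dir)
}
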
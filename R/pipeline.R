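#' End-to-end SV association pipeline configuration
#'
#' Bundles every stage parameter: the simulation (or input files), the
#' caller thresholds, the outcomes to test, and the permutation budget. All
#' randomness downstream flows from the single `seed` passed to
#' [run_pipeline()]; stage-local streams are derived deterministically.
#'
#' @param sim A [sim_config()] to simulate inputs from, or `NULL` when
#'   `coverage`/`clinical` tibbles are supplied directly.
#' @param coverage,clinical Input tibbles when not simulating (long coverage
#'   with a `cohort` column; clinical table).
#' @param discovery_cohort Cohort label used for SV discovery; other cohorts
#'   are genotyped against its catalog by projection. Defaults to the first
#'   cohort.
#' @param outcomes Binary outcomes to test (subset of `response`, `pfs12`,
#'   `irae`); OS is tested whenever the clinical table has events.
#' @param depth_min,breadth_min Species-presence thresholds
#'   ([normalize_coverage()]).
#' @param del_ratio,del_band,var_thresh,merge_r Caller thresholds
#'   ([detect_sv_regions()]).
#' @param min_samples Present-sample floor for discovery (`NULL` = 10% of
#'   the discovery cohort).
#' @param min_frac Profile filter threshold ([filter_sv_profile()]).
#' @param min_n_binary,min_events_binary,min_n_surv Association filters.
#' @param n_perm Permutations for any PERMANOVA stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, coverage = NULL, clinical = NULL,
                            discovery_cohort = NULL,
                            outcomes = c("response", "pfs12", "irae"),
                            depth_min = 1, breadth_min = 0.10,
                            del_ratio = 0.25, del_band = c(0.25, 0.75),
                            var_thresh = 0.75, merge_r = 0.95,
                            min_samples = NULL, min_frac = 0.05,
                            min_n_binary = 10, min_events_binary = 3,
                            min_n_surv = 20, n_perm = 999) {
  if (is.null(sim) && (is.null(coverage) || is.null(clinical))) {
    abort("provide either a sim_config or coverage + clinical tables")
  }
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  structure(list(
    sim = sim, coverage = coverage, clinical = clinical,
    discovery_cohort = discovery_cohort, outcomes = outcomes,
    depth_min = depth_min, breadth_min = breadth_min,
    del_ratio = del_ratio, del_band = del_band, var_thresh = var_thresh,
    merge_r = merge_r, min_samples = min_samples, min_frac = min_frac,
    min_n_binary = min_n_binary, min_events_binary = min_events_binary,
    min_n_surv = min_n_surv, n_perm = n_perm
  ), class = "pipeline_config")
}

#' Run the SV association pipeline end to end
#'
#' Simulate (or take) multi-cohort coverage and clinical tables; call SVs on
#' the discovery cohort; project the catalog onto every cohort; filter the
#' profile; run per-cohort logistic associations for each binary outcome and
#' Cox for OS; pool cohorts with DerSimonian-Laird meta-analysis; and label
#' replicated candidates. Identical config + seed gives an identical result
#' bundle.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer root seed.
#' @return A list bundle: `catalog`, `profile`, `associations` (per-cohort
#'   records), `meta` (pooled results with decisions), `presence`, and a
#'   `log` tibble of per-stage messages.
#' @export
run_pipeline <- function(config, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  say <- function(stage, msg) {
    log[[length(log) + 1]] <<- tibble(stage = stage, message = msg)
  }

  if (!is.null(config$sim)) {
    sim <- simulate_cohorts(config$sim, seed = derive_seed(seed, "simulate"))
    coverage <- sim$coverage
    clinical <- sim$clinical
    say("simulate", sprintf("simulated %d cohorts, %d samples",
                            config$sim$n_cohorts, nrow(clinical)))
  } else {
    sim <- NULL
    coverage <- config$coverage
    clinical <- config$clinical
  }
  assert_columns(coverage, c("cohort", "species_id", "sample_id",
                             "bin_index", "depth"), "coverage")
  cohorts <- sort(unique(coverage$cohort))
  discovery <- config$discovery_cohort %||% cohorts[1]
  if (!discovery %in% cohorts) abort("discovery cohort not present in coverage")

  norm <- lapply(cohorts, function(co) {
    normalize_coverage(coverage[coverage$cohort == co, ],
                       depth_min = config$depth_min,
                       breadth_min = config$breadth_min)
  })
  names(norm) <- cohorts

  catalog <- detect_sv_regions(
    norm[[discovery]], min_samples = config$min_samples,
    del_ratio = config$del_ratio, del_band = config$del_band,
    var_thresh = config$var_thresh, merge_r = config$merge_r
  )
  say("call-sv", sprintf("discovery %s: %d regions (%d dSV, %d vSV)",
                         discovery, nrow(catalog),
                         sum(catalog$sv_class == "dSV"),
                         sum(catalog$sv_class == "vSV")))
  if (nrow(catalog) == 0) {
    return(list(catalog = catalog, profile = NULL, associations = NULL,
                meta = NULL, sim = sim, log = bind_rows(log)))
  }

  profile <- bind_rows(lapply(cohorts, function(co) {
    p <- suppressWarnings(project_sv(catalog, norm[[co]]))
    p$cohort <- co
    p
  }))
  class(profile) <- c("sv_profile", class(profile))
  profile <- filter_sv_profile(profile, min_frac = config$min_frac)
  say("project-sv", sprintf("profile: %d regions x %d samples; %d dropped",
                            length(unique(profile$region_id)),
                            length(unique(profile$sample_id)),
                            length(attr(profile, "dropped"))))

  assoc <- list()
  for (oc in config$outcomes) {
    if (all(is.na(clinical[[oc]]))) next
    assoc[[oc]] <- sv_binary_assoc(profile, clinical, oc,
                                   min_n = config$min_n_binary,
                                   min_events = config$min_events_binary)
  }
  if (any(clinical$os_event == 1, na.rm = TRUE)) {
    assoc[["os"]] <- sv_survival_assoc(profile, clinical,
                                       min_n = config$min_n_surv)
  }
  associations <- bind_rows(assoc)
  say("assoc", sprintf("%d testable records of %d",
                       sum(!is.na(associations$p)), nrow(associations)))

  meta <- meta_analyze(associations)
  say("meta", sprintf("%d pooled results; %d replicated candidates",
                      nrow(meta),
                      sum(meta$decision == "replicated-candidate")))

  list(catalog = catalog, profile = profile, associations = associations,
       meta = meta, sim = sim,
       presence = lapply(norm, sv_presence), log = bind_rows(log))
}
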
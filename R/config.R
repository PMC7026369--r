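#' Default run configuration
#'
#' A run configuration bundles every parameter object of the pipeline.
#' All sub-seeds are derived deterministically from `master_seed`, so a
#' run is fully reproducible from the configuration document alone.
#'
#' @param experiment `"EXP1"` or `"EXP2"`.
#' @param n_participants Simulated sample size.
#' @param master_seed Master integer seed.
#' @param taxonomy,retrieval,decision,feature,variability Parameter
#'   objects; defaults are the package defaults.
#' @param allow_partial_counterbalance Permit EXP1 participant counts
#'   that are not multiples of 24 (the condition orderings then cycle).
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = "EXP1",
                       n_participants = if (experiment == "EXP1") 24L else 32L,
                       master_seed = 1L,
                       taxonomy = taxonomy_config(),
                       retrieval = retrieval_params(),
                       decision = decision_params(),
                       feature = feature_params(),
                       variability = participant_variability(),
                       allow_partial_counterbalance = FALSE) {
  stopifnot(experiment %in% c("EXP1", "EXP2"), n_participants >= 1)
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 master_seed = as.integer(master_seed),
                 taxonomy = taxonomy, retrieval = retrieval,
                 decision = decision, feature = feature,
                 variability = variability,
                 allow_partial_counterbalance =
                   isTRUE(allow_partial_counterbalance)),
            class = "run_config")
}

# apply user-supplied values over a constructor's defaults, rejecting
# unknown keys so config typos fail loudly
merge_params <- function(constructor, values, what) {
  if (is.null(values)) return(constructor())
  known <- names(formals(constructor))
  bad <- setdiff(names(values), known)
  if (length(bad))
    stop("unknown ", what, " field(s): ", paste(bad, collapse = ", "))
  do.call(constructor, values)
}

#' Read and validate a run configuration from JSON
#'
#' Unknown keys anywhere in the document are rejected; omitted keys take
#' the package defaults.
#'
#' @param path Path to a JSON document.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  top <- c("experiment", "n_participants", "master_seed", "taxonomy",
           "retrieval", "decision", "feature", "variability")
  bad <- setdiff(names(doc), top)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(doc$feature$overlap_false_by_type))
    doc$feature$overlap_false_by_type <-
      unlist(doc$feature$overlap_false_by_type)
  run_config(
    experiment = if (is.null(doc$experiment)) "EXP1" else doc$experiment,
    n_participants = if (is.null(doc$n_participants)) {
      if (identical(doc$experiment, "EXP2")) 32L else 24L
    } else doc$n_participants,
    master_seed = if (is.null(doc$master_seed)) 1L else doc$master_seed,
    taxonomy = merge_params(taxonomy_config, as.list(doc$taxonomy),
                            "taxonomy"),
    retrieval = merge_params(retrieval_params, as.list(doc$retrieval),
                             "retrieval"),
    decision = merge_params(decision_params, as.list(doc$decision),
                            "decision"),
    feature = merge_params(feature_params, as.list(doc$feature), "feature"),
    variability = merge_params(participant_variability,
                               as.list(doc$variability), "variability"))
}

#' Run the full simulation pipeline from a configuration
#'
#' Generates the taxonomy, builds the stimulus set and design, and
#' simulates every trial. Child seeds for each stage are derived from the
#' master seed.
#'
#' @param config A [run_config()].
#' @return A list: `taxonomy`, `stimset`, `design`, `trials`.
#' @export
run_pipeline <- function(config = run_config()) {
  tax_cfg <- config$taxonomy
  tax_cfg$seed <- derive_seed(config$master_seed, "taxonomy")
  taxonomy <- generate_taxonomy(tax_cfg)
  stimset <- build_stimulus_set(taxonomy, config$experiment,
                                seed = derive_seed(config$master_seed,
                                                   "stimuli"))
  design <- make_experiment_design(config$experiment, config$n_participants,
                                   stimset,
                                   seed = derive_seed(config$master_seed,
                                                      "design"),
                                   allow_any =
                                     config$allow_partial_counterbalance)
  trials <- run_experiment(design, taxonomy, config$retrieval,
                           config$decision, config$feature,
                           config$variability, seed = config$master_seed)
  list(taxonomy = taxonomy, stimset = stimset, design = design,
       trials = trials)
}
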
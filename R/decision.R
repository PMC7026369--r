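#' Decision-stage parameters
#'
#' Stage 2 applies production rules to retrieved label tuples. Each
#' application costs a constant `eval_time`: by construction the
#' evaluation stage is unaffected by associative strength and hence by
#' typicality, which is the model's central additive-factors commitment.
#'
#' @param eval_time Duration, ms, of one path-evaluation application.
#' @param base_time Encoding plus motor time, ms, added to every trial.
#' @param guess_true_rate Probability of guessing TRUE when retrieval
#'   exhausts with only ambiguous evidence (0 disables guessing; retrieval
#'   exhaustion then yields FALSE).
#' @return A list of class `decision_params`.
#' @export
decision_params <- function(eval_time = 150, base_time = 700,
                            guess_true_rate = 0) {
  stopifnot(eval_time >= 0, base_time >= 0,
            guess_true_rate >= 0, guess_true_rate <= 1)
  structure(list(eval_time = eval_time, base_time = base_time,
                 guess_true_rate = guess_true_rate),
            class = "decision_params")
}

#' Feature-comparison model parameters
#'
#' The rival account: independent counters sample features one at a time;
#' a sample matches with the stimulus type's overlap probability. TRUE is
#' declared at `c_true` accumulated matches (`c_true_shifted` under a
#' criterion shift), FALSE at `c_false` mismatches. Typical exemplars
#' overlap the category more, so matches accrue faster and raising the
#' true criterion amplifies the typicality effect.
#'
#' @param n_features Nominal feature-pool size (bookkeeping only; sampling
#'   is Bernoulli per draw).
#' @param overlap_typical,overlap_atypical Match probability for
#'   typical/atypical true items; `overlap_typical > overlap_atypical`.
#' @param overlap_false_by_type Named vector of match probabilities for
#'   false stimulus types.
#' @param c_true,c_false,c_true_shifted Counter criteria (counts >= 1;
#'   `c_true_shifted >= c_true`).
#' @param sample_time Duration, ms, of one feature sample.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(n_features = 50L,
                           overlap_typical = 0.9,
                           overlap_atypical = 0.7,
                           overlap_false_by_type = c(
                             anomalous_false = 0.10,
                             cross_category_false = 0.40,
                             coordinate_false = 0.75,
                             reversed_false = 0.75,
                             cat_derived_anom = 0.10,
                             coord_derived_anom = 0.10,
                             similar_coord = 0.80,
                             less_similar_coord = 0.70),
                           c_true = 4L, c_false = 12L,
                           c_true_shifted = 8L,
                           sample_time = 200) {
  if (c_true < 1L || c_false < 1L || c_true_shifted < 1L)
    stop("counter criteria must be >= 1")
  stopifnot(overlap_typical > overlap_atypical,
            c_true_shifted >= c_true, sample_time > 0)
  structure(list(n_features = as.integer(n_features),
                 overlap_typical = overlap_typical,
                 overlap_atypical = overlap_atypical,
                 overlap_false_by_type = overlap_false_by_type,
                 c_true = as.integer(c_true),
                 c_false = as.integer(c_false),
                 c_true_shifted = as.integer(c_true_shifted),
                 sample_time = sample_time),
            class = "feature_params")
}

#' Construct a single category-verification stimulus
#'
#' @param subject,predicate Stimulus terms.
#' @param stimulus_type One of the true/false stimulus types; truth is
#'   implied (only `typical_true`/`atypical_true` are true).
#' @param condition Block condition: `"ANOMALOUS"`, `"COORDINATE"`,
#'   `"CROSS_CATEGORY"` or `"REVERSED"`.
#' @return A list of class `trial_stimulus`.
#' @export
trial_stimulus <- function(subject, predicate, stimulus_type, condition) {
  types <- c("typical_true", "atypical_true", "anomalous_false",
             "coordinate_false", "cross_category_false", "reversed_false",
             "cat_derived_anom", "coord_derived_anom", "similar_coord",
             "less_similar_coord")
  stopifnot(stimulus_type %in% types,
            condition %in% c("ANOMALOUS", "COORDINATE", "CROSS_CATEGORY",
                             "REVERSED"))
  structure(list(subject = subject, predicate = predicate,
                 stimulus_type = stimulus_type,
                 truth = stimulus_type %in% c("typical_true", "atypical_true"),
                 condition = condition),
            class = "trial_stimulus")
}

trial_result <- function(response, truth, stage1, stage2, base_time,
                         mechanism, n_evaluations = 0L) {
  rt <- base_time + stage1 + stage2
  list(response = response, correct = identical(response, truth),
       rt = rt, stage1 = stage1, stage2 = stage2,
       mechanism = mechanism, n_evaluations = n_evaluations)
}

#' Network-model decision for one trial
#'
#' In the Anomalous condition any connecting path suffices: TRUE if stage-1
#' retrieval finds a path, FALSE on exhaustion, with no evaluation stage.
#' In the Coordinate and Reversed conditions each retrieved path's label
#' tuple is classified (mirrored first when the predicate-origin search
#' won): a set-superset class answers TRUE, a coordinate or superset-set
#' class answers FALSE, and an ambiguous class resumes retrieval for the
#' next path. Every classification adds a constant `eval_time` to stage 2.
#' Exhaustion with no decisive path yields FALSE (or a TRUE guess at
#' `guess_true_rate`).
#'
#' @param net A [semantic_network()].
#' @param stimulus A [trial_stimulus()] with condition `"ANOMALOUS"`,
#'   `"COORDINATE"` or `"REVERSED"`.
#' @param rparams,dparams [retrieval_params()] and [decision_params()].
#' @param adj Optional prebuilt adjacency index.
#' @param cache Optional environment memoising traversal orders.
#' @return A trial result list: `response` (logical), `correct`, `rt`,
#'   `stage1`, `stage2` (ms), `mechanism = "NETWORK"`.
#' @export
decide_network <- function(net, stimulus, rparams = retrieval_params(),
                           dparams = decision_params(),
                           adj = NULL, cache = NULL) {
  cond <- stimulus$condition
  if (cond == "CROSS_CATEGORY")
    stop("CROSS_CATEGORY trials use the feature fallback; see verify_trial()")
  race <- race_paths(net, stimulus$subject, stimulus$predicate, rparams,
                     adj = adj, cache = cache)
  exhaust_latency <- max(race$exhaust) + rparams$exhaustion_overhead
  if (cond == "ANOMALOUS") {
    if (length(race$events)) {
      ev <- race$events[[1L]]
      return(trial_result(TRUE, stimulus$truth, ev$time, 0,
                          dparams$base_time, "NETWORK"))
    }
    return(trial_result(FALSE, stimulus$truth, exhaust_latency, 0,
                        dparams$base_time, "NETWORK"))
  }
  # COORDINATE / REVERSED: path evaluation over retrieved tuples
  n_eval <- 0L
  for (ev in race$events) {
    n_eval <- n_eval + 1L
    tup <- path_tuple(ev$path)
    if (ev$origin == "PREDICATE") tup <- mirror_tuple(tup$first, tup$second)
    cls <- classify_tuple(tup$first, tup$second)
    if (cls == "AMBIGUOUS") next
    response <- cls == "SET_SUPERSET"
    return(trial_result(response, stimulus$truth, ev$time,
                        n_eval * dparams$eval_time, dparams$base_time,
                        "NETWORK", n_eval))
  }
  response <- dparams$guess_true_rate > 0 &&
    stats::runif(1) < dparams$guess_true_rate
  trial_result(response, stimulus$truth, exhaust_latency,
               n_eval * dparams$eval_time, dparams$base_time,
               "NETWORK", n_eval)
}

# Vectorised counter race: n independent trials, each sampling Bernoulli
# matches at probability p until c_true matches (-> TRUE) or c_false
# mismatches (-> FALSE). Returns responses and samples drawn.
feature_race <- function(n, p, c_true, c_false) {
  max_draws <- c_true + c_false - 1L
  matches <- integer(n)
  response <- logical(n)
  nsamp <- integer(n)
  done <- logical(n)
  for (j in seq_len(max_draws)) {
    active <- which(!done)
    if (!length(active)) break
    hit <- stats::runif(length(active)) < p
    matches[active] <- matches[active] + hit
    now_true <- active[matches[active] >= c_true]
    now_false <- active[(j - matches[active]) >= c_false]
    response[now_true] <- TRUE
    nsamp[c(now_true, now_false)] <- j
    done[c(now_true, now_false)] <- TRUE
  }
  list(response = response, samples = nsamp)
}

#' Feature-comparison decision for one trial
#'
#' @param stimulus A [trial_stimulus()].
#' @param fparams A [feature_params()]; the stimulus type must have a
#'   defined overlap probability.
#' @param shifted Use the raised true criterion (`c_true_shifted`), the
#'   criterion-shift account of semantically similar false contexts.
#' @param dparams A [decision_params()] (supplies `base_time`).
#' @return A trial result list with `mechanism = "FEATURE"`; `stage1` is
#'   samples-drawn times `sample_time`, `stage2` is 0.
#' @export
feature_verify <- function(stimulus, fparams = feature_params(),
                           shifted = FALSE, dparams = decision_params()) {
  p <- switch(stimulus$stimulus_type,
              typical_true = fparams$overlap_typical,
              atypical_true = fparams$overlap_atypical,
              fparams$overlap_false_by_type[[stimulus$stimulus_type]])
  if (is.null(p) || is.na(p))
    stop("no overlap probability defined for stimulus type ",
         stimulus$stimulus_type)
  ct <- if (shifted) fparams$c_true_shifted else fparams$c_true
  race <- feature_race(1L, p, ct, fparams$c_false)
  trial_result(race$response, stimulus$truth,
               race$samples * fparams$sample_time, 0,
               dparams$base_time, "FEATURE")
}

#' Run one verification trial under the condition's decision policy
#'
#' Routes Anomalous, Coordinate and Reversed trials to the network model
#' and Cross-Category trials to the feature-comparison model with the
#' shifted criterion (the similarity-judgment fallback: in a
#' cross-category context every retrievable associative chain is
#' ambiguous, so the network cannot discriminate true from false).
#'
#' @inheritParams decide_network
#' @param fparams A [feature_params()].
#' @return A unified trial result list.
#' @export
verify_trial <- function(net, stimulus, rparams = retrieval_params(),
                         dparams = decision_params(),
                         fparams = feature_params(),
                         adj = NULL, cache = NULL) {
  if (stimulus$condition == "CROSS_CATEGORY")
    feature_verify(stimulus, fparams, shifted = TRUE, dparams = dparams)
  else
    decide_network(net, stimulus, rparams, dparams, adj = adj, cache = cache)
}
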
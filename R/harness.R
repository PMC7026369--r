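#' Between-participant variability parameters
#'
#' Trial components are scaled by a participant-specific log-normal
#' factor (mean 1) and shifted by a normal offset, giving simulated
#' between-subject standard deviations of realistic size for t statistics
#' and confidence intervals.
#'
#' @param scale_sdlog Log-SD of the multiplicative RT scale.
#' @param offset_sd SD, ms, of the additive offset.
#' @return A list of class `participant_variability`.
#' @export
participant_variability <- function(scale_sdlog = 0.15, offset_sd = 0) {
  stopifnot(scale_sdlog >= 0, offset_sd >= 0)
  structure(list(scale_sdlog = scale_sdlog, offset_sd = offset_sd),
            class = "participant_variability")
}

# deterministic child seed from a master seed and a stream name,
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(master, stream) {
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer(max(1, h))
}

#' Simulate every trial of an experiment design
#'
#' Runs each design row through [verify_trial()] with the block's
#' condition policy. Each participant draws an RT scale (and offset) and
#' owns an independent RNG stream derived from the master seed, so adding
#' participants never perturbs earlier ones. Practice trials are
#' simulated and flagged; summaries exclude them.
#'
#' @param design A [make_experiment_design()] data frame.
#' @param taxonomy The [generate_taxonomy()] result the design was built
#'   from.
#' @param rparams,dparams,fparams Model parameter objects.
#' @param variability A [participant_variability()].
#' @param seed Master integer seed.
#' @return A trial table: one row per trial with columns `participant`,
#'   `condition`, `block`, `trial`, `practice`, `subject`, `predicate`,
#'   `stimulus_type`, `truth`, `response`, `correct`, `rt_ms`,
#'   `stage1_ms`, `stage2_ms`, `mechanism`.
#' @export
run_experiment <- function(design, taxonomy,
                           rparams = retrieval_params(),
                           dparams = decision_params(),
                           fparams = feature_params(),
                           variability = participant_variability(),
                           seed = 1L) {
  net <- taxonomy$network
  missing <- setdiff(unique(c(design$subject, design$predicate)), net$words)
  if (length(missing))
    stop("design references words absent from the network: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  adj <- network_adjacency(net)
  cache <- new.env(parent = emptyenv())
  n <- nrow(design)
  response <- logical(n)
  correct <- logical(n)
  rt <- numeric(n)
  s1 <- numeric(n)
  s2 <- numeric(n)
  mech <- character(n)
  for (pid in unique(design$participant)) {
    set.seed(derive_seed(seed, sprintf("participant_%06d", pid)))
    scale <- stats::rlnorm(1L, meanlog = -variability$scale_sdlog^2 / 2,
                           sdlog = variability$scale_sdlog)
    offset <- if (variability$offset_sd > 0)
      stats::rnorm(1L, 0, variability$offset_sd) else 0
    idx <- which(design$participant == pid)
    for (i in idx) {
      stim <- trial_stimulus(design$subject[i], design$predicate[i],
                             design$stimulus_type[i], design$condition[i])
      res <- verify_trial(net, stim, rparams, dparams, fparams,
                          adj = adj, cache = cache)
      response[i] <- res$response
      correct[i] <- res$correct
      s1[i] <- scale * res$stage1
      s2[i] <- scale * res$stage2
      rt[i] <- scale * res$rt + offset
      mech[i] <- res$mechanism
    }
  }
  cbind(design[, c("participant", "condition", "block", "trial", "practice",
                   "subject", "predicate", "stimulus_type", "truth")],
        data.frame(response = response, correct = correct, rt_ms = rt,
                   stage1_ms = s1, stage2_ms = s2, mechanism = mech,
                   stringsAsFactors = FALSE))
}

#' Trim slow outliers per participant and condition
#'
#' Single pass: within each (participant, condition) cell, rows with
#' `rt_ms` above the cell mean plus `k` standard deviations are dropped.
#' Cells with fewer than two rows, or zero variance, pass through
#' untouched.
#'
#' @param trials A trial table.
#' @param k Trimming criterion in SD units.
#' @return A list: `trials` (trimmed table), `n_trimmed`, `fraction`.
#' @export
trim_outliers <- function(trials, k = 2.5) {
  stopifnot(k > 0)
  cell <- interaction(trials$participant, trials$condition, drop = TRUE)
  keep <- rep(TRUE, nrow(trials))
  for (cl in levels(cell)) {
    i <- which(cell == cl)
    if (length(i) < 2L) next
    m <- mean(trials$rt_ms[i])
    s <- stats::sd(trials$rt_ms[i])
    if (!is.finite(s) || s == 0) next
    keep[i] <- trials$rt_ms[i] <= m + k * s
  }
  list(trials = trials[keep, , drop = FALSE],
       n_trimmed = sum(!keep),
       fraction = sum(!keep) / nrow(trials))
}

#' Per-participant typicality effect in one condition
#'
#' The typicality effect is the mean correct atypical-true RT minus the
#' mean correct typical-true RT, per participant. Incorrect trials and
#' practice trials are excluded; a participant with an empty cell is
#' dropped with a warning.
#'
#' @param trials A trial table.
#' @param condition Condition name.
#' @return A list of class `typicality_effect`: `effects` (data frame
#'   `participant`, `effect`), `mean`, `ci95`, `n`, `condition`.
#' @export
typicality_effect <- function(trials, condition) {
  tt <- trials[!trials$practice & trials$condition == condition &
                 trials$truth & trials$correct, , drop = FALSE]
  if (!nrow(tt)) stop("no correct true trials in condition ", condition)
  effects <- lapply(split(tt, tt$participant), function(d) {
    typ <- d$rt_ms[d$stimulus_type == "typical_true"]
    atyp <- d$rt_ms[d$stimulus_type == "atypical_true"]
    if (!length(typ) || !length(atyp)) return(NULL)
    mean(atyp) - mean(typ)
  })
  dropped <- names(effects)[vapply(effects, is.null, logical(1))]
  if (length(dropped))
    warning("participant(s) without correct trials in both cells dropped: ",
            paste(dropped, collapse = ", "))
  effects <- effects[!vapply(effects, is.null, logical(1))]
  eff <- data.frame(participant = as.integer(names(effects)),
                    effect = unlist(effects, use.names = FALSE))
  eff <- eff[order(eff$participant), , drop = FALSE]
  n <- nrow(eff)
  m <- mean(eff$effect)
  se <- stats::sd(eff$effect) / sqrt(n)
  ci <- m + stats::qt(c(0.025, 0.975), df = n - 1L) * se
  structure(list(effects = eff, mean = m, ci95 = ci, n = n,
                 condition = condition),
            class = "typicality_effect")
}

#' @export
print.typicality_effect <- function(x, ...) {
  cat(sprintf("Typicality effect, %s: %.0f ms (95%% CI %.0f - %.0f), n = %d\n",
              x$condition, x$mean, x$ci95[1L], x$ci95[2L], x$n))
  invisible(x)
}

#' Proportion correct by condition and stimulus type
#'
#' @param trials A trial table.
#' @return A data frame `condition`, `stimulus_type`, `n`, `prop_correct`.
#' @export
accuracy_summary <- function(trials) {
  tt <- trials[!trials$practice, , drop = FALSE]
  agg <- stats::aggregate(tt$correct,
                          by = list(condition = tt$condition,
                                    stimulus_type = tt$stimulus_type),
                          FUN = function(v) c(n = length(v), p = mean(v)))
  data.frame(condition = agg$condition, stimulus_type = agg$stimulus_type,
             n = as.integer(agg$x[, "n"]), prop_correct = agg$x[, "p"],
             stringsAsFactors = FALSE)
}

#' Generate a lightweight synthetic trial table
#'
#' A harness-level generative model for calibration studies: cell means
#' are `base_rt` plus the typicality effect for atypical cells, plus an
#' injected condition-by-typicality interaction in non-baseline
#' conditions; trials are gamma-distributed around the cell mean with SD
#' `trial_sd`, and each participant applies a log-normal RT scale. All
#' trials are marked correct true trials, so the table feeds directly
#' into [typicality_effect()] and [contrast_table()].
#'
#' @param n_participants Participants.
#' @param conditions Condition names; the first is the baseline.
#' @param n_per_cell Trials per participant x condition x typicality cell.
#' @param base_rt Typical-cell mean RT, ms.
#' @param typicality_ms True typicality effect, ms.
#' @param interaction_ms Added to atypical cells of non-baseline
#'   conditions (0 simulates the null of an invariant typicality effect).
#' @param trial_sd Within-cell trial SD, ms.
#' @param scale_sdlog Participant log-normal scale SD.
#' @param seed Optional integer seed.
#' @return A trial table.
#' @export
simulate_trial_table <- function(n_participants = 24L,
                                 conditions = c("ANOMALOUS", "COORDINATE"),
                                 n_per_cell = 20L, base_rt = 1000,
                                 typicality_ms = 300, interaction_ms = 0,
                                 trial_sd = 350, scale_sdlog = 0.15,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (p in seq_len(n_participants)) {
    scale <- stats::rlnorm(1L, -scale_sdlog^2 / 2, scale_sdlog)
    for (ci in seq_along(conditions)) {
      for (typ in c("typical_true", "atypical_true")) {
        mu <- base_rt +
          (typ == "atypical_true") * (typicality_ms +
                                        if (ci > 1L) interaction_ms else 0)
        mu <- scale * mu
        shape <- (mu / trial_sd)^2
        rt <- stats::rgamma(n_per_cell, shape = shape, rate = shape / mu)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, condition = conditions[ci], block = ci,
          trial = seq_len(n_per_cell), practice = FALSE,
          subject = "s", predicate = "p", stimulus_type = typ,
          truth = TRUE, response = TRUE, correct = TRUE, rt_ms = rt,
          stage1_ms = rt, stage2_ms = 0, mechanism = "SYNTH",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
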
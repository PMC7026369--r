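#' One-sample t test on paired differences
#'
#' @param differences Numeric vector of per-participant differences.
#' @return A list `t`, `df`.
#' @export
paired_t <- function(differences) {
  n <- length(differences)
  if (n < 2L) stop("need at least 2 differences")
  s <- stats::sd(differences)
  if (s == 0) stop("zero variance in the differences")
  list(t = mean(differences) / (s / sqrt(n)), df = n - 1L)
}

#' Cohen's d from a repeated-measures t
#'
#' The repeated-measures convention `d = t / sqrt(n)`.
#'
#' @param t t statistic.
#' @param n Number of paired observations.
#' @return d.
#' @export
cohens_d_from_t <- function(t, n) {
  if (n < 2L) stop("need n >= 2")
  t / sqrt(n)
}

#' Unit-information Bayes factor BF01 for a one-sample t
#'
#' The null-over-alternative Bayes factor under a normal unit-information
#' prior with scale `r` on the standardized effect size. With `v = n - 1`:
#'
#' \deqn{BF_{01} = \frac{(1 + t^2/v)^{-(v+1)/2}}
#'   {(1 + n r^2)^{-1/2}\,\bigl(1 + t^2 / (v (1 + n r^2))\bigr)^{-(v+1)/2}}}
#'
#' At `t = 0` this reduces to `sqrt(1 + n r^2)`. BF10 is the reciprocal.
#'
#' @param t Observed t statistic.
#' @param n Number of paired observations.
#' @param r Prior scale on the standardized effect (1 for a large expected
#'   effect, 0.5 as a conservative small-effect choice).
#' @return BF01 (> 0).
#' @examples
#' bf01_unit_information(-0.49, 24, 1)   # 4.44
#' bf01_unit_information(4.88, 24, 1)    # 0.0016
#' @export
bf01_unit_information <- function(t, n, r = 1) {
  if (n < 2L) stop("need n >= 2")
  stopifnot(r > 0)
  v <- n - 1
  g <- 1 + n * r^2
  ((1 + t^2 / v)^(-(v + 1) / 2)) /
    (g^(-0.5) * (1 + t^2 / (v * g))^(-(v + 1) / 2))
}

#' Power of a paired t test via the noncentral t distribution
#'
#' Exact power for a one-sample t on n paired differences with
#' standardized effect `d` (noncentrality `d * sqrt(n)`, df `n - 1`).
#' Two-sided by default; at `d = 0` the two-sided power equals `alpha`.
#'
#' @param d Standardized effect size.
#' @param n Number of pairs.
#' @param alpha Type I error rate.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return Power in (0, 1).
#' @examples
#' power_paired_t(0.2, 24, alpha = 0.2)  # 0.39
#' @export
power_paired_t <- function(d, n, alpha = 0.2, two_sided = TRUE) {
  if (n < 2L) stop("need n >= 2")
  stopifnot(alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (two_sided) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Convert a 1-df F to a signed t
#'
#' @param f F statistic with 1 numerator df.
#' @param sign Direction of the effect (+1 or -1).
#' @return t.
#' @export
f_to_t <- function(f, sign = 1) {
  stopifnot(f >= 0, sign %in% c(-1, 1))
  sign * sqrt(f)
}

contrast_row <- function(label, base_eff, cond_eff, r_scales) {
  d <- cond_eff - base_eff
  n <- length(d)
  tt <- paired_t(d)
  se_eff <- stats::sd(cond_eff) / sqrt(n)
  se_d <- stats::sd(d) / sqrt(n)
  q <- stats::qt(0.975, n - 1L)
  row <- data.frame(label = label,
                    effect_ms = mean(cond_eff),
                    effect_lo = mean(cond_eff) - q * se_eff,
                    effect_hi = mean(cond_eff) + q * se_eff,
                    delta_ms = mean(d),
                    delta_lo = mean(d) - q * se_d,
                    delta_hi = mean(d) + q * se_d,
                    n = n, t = tt$t,
                    d = cohens_d_from_t(tt$t, n),
                    stringsAsFactors = FALSE)
  for (r in r_scales)
    row[[paste0("bf01_r", sub("\\.", "", format(r)))]] <-
      bf01_unit_information(tt$t, n, r)
  row
}

#' Typicality-effect contrast table against a baseline condition
#'
#' For every non-baseline condition, forms per-participant paired
#' differences of typicality effects (condition minus baseline) and
#' reports the effect and its 95% CI, the difference and its CI, the
#' repeated-measures t, Cohen's d (`t / sqrt(n)`) and the
#' unit-information BF01 at each prior scale.
#'
#' @param x Either a trial table (output of [run_experiment()] or
#'   [simulate_trial_table()]) or a data frame of per-participant effects
#'   with columns `participant`, `condition`, `effect`.
#' @param baseline Baseline condition name.
#' @param r_scales Prior scales for the Bayes factors.
#' @return A data frame of class `contrast_table`, one row per
#'   non-baseline condition, plus a baseline attribute row description.
#' @export
contrast_table <- function(x, baseline = "ANOMALOUS", r_scales = c(1, 0.5)) {
  eff <- if (all(c("participant", "condition", "effect") %in% names(x)) &&
               !"rt_ms" %in% names(x)) {
    x
  } else {
    conds <- unique(x$condition)
    do.call(rbind, lapply(conds, function(cc) {
      te <- typicality_effect(x, cc)
      data.frame(participant = te$effects$participant, condition = cc,
                 effect = te$effects$effect, stringsAsFactors = FALSE)
    }))
  }
  if (!baseline %in% eff$condition)
    stop("baseline condition ", baseline, " not present")
  base <- eff[eff$condition == baseline, ]
  base <- base[order(base$participant), ]
  rows <- lapply(setdiff(unique(eff$condition), baseline), function(cc) {
    cnd <- eff[eff$condition == cc, ]
    cnd <- cnd[order(cnd$participant), ]
    if (!identical(cnd$participant, base$participant))
      stop("participant sets differ between ", cc, " and ", baseline)
    contrast_row(cc, base$effect, cnd$effect, r_scales)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  attr(out, "baseline_effect") <- mean(base$effect)
  class(out) <- c("contrast_table", class(out))
  out
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("Typicality-effect contrasts vs %s (baseline effect %.0f ms)\n",
              attr(x, "baseline"), attr(x, "baseline_effect")))
  df <- as.data.frame(x)
  df$effect_ms <- sprintf("%.0f (%.0f - %.0f)", df$effect_ms, df$effect_lo,
                          df$effect_hi)
  df$delta_ms <- sprintf("%.0f (%.0f - %.0f)", df$delta_ms, df$delta_lo,
                         df$delta_hi)
  keep <- c("label", "effect_ms", "delta_ms", "n", "t", "d",
            grep("^bf01", names(df), value = TRUE))
  df <- df[, keep]
  df$t <- sprintf("%.2f", df$t)
  df$d <- sprintf("%.2f", df$d)
  for (cc in grep("^bf01", names(df), value = TRUE))
    df[[cc]] <- signif(df[[cc]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pool per-participant effect pairs across studies
#'
#' Concatenates the per-participant (condition minus baseline) typicality
#' effect differences of several studies and computes one combined
#' contrast row.
#'
#' @param studies A list; each element is either a numeric vector of
#'   per-participant differences or a two-column data frame/matrix whose
#'   first column is the baseline effect and second the condition effect.
#' @param label Row label.
#' @param r_scales Prior scales for the Bayes factors.
#' @return A one-row `contrast_table`.
#' @export
pool_combined <- function(studies, label = "combined", r_scales = c(1, 0.5)) {
  if (length(studies) < 2L) stop("need at least 2 studies to pool")
  pairs <- lapply(studies, function(s) {
    if (is.numeric(s) && is.null(dim(s))) cbind(0, s)
    else as.matrix(s[, 1:2])
  })
  m <- do.call(rbind, pairs)
  out <- contrast_row(label, m[, 1L], m[, 2L], r_scales)
  attr(out, "baseline") <- "per-study baseline"
  attr(out, "baseline_effect") <- mean(m[, 1L])
  class(out) <- c("contrast_table", class(out))
  out
}

#' Standardize per-participant effects and bin them
#'
#' Effects are z-scored against their own mean and SD, then counted into
#' bins of `width` standard deviations; all values at or above `pool_at`
#' are pooled into the top bin.
#'
#' @param effects Numeric vector of per-participant effects.
#' @param width Bin width in SD units.
#' @param pool_at Pooling threshold in SD units.
#' @return A list of class `binned_distribution`: `counts` (named by bin
#'   lower edge), `width`, `pool_at`, `n`.
#' @export
standardize_and_bin <- function(effects, width = 0.25, pool_at = 2.25) {
  s <- stats::sd(effects)
  if (!is.finite(s) || s == 0) stop("effects have zero standard deviation")
  z <- (effects - mean(effects)) / s
  lo <- floor(min(z) / width) * width
  edges <- seq(lo, pool_at, by = width)
  bin <- pmin(floor((z - lo) / width + 1e-9), length(edges) - 1L) + 1L
  counts <- tabulate(bin, nbins = length(edges))
  names(counts) <- format(edges, trim = TRUE)
  structure(list(counts = counts, width = width, pool_at = pool_at,
                 n = length(z)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat("Binned standardized distribution (width", x$width,
      "SD, pooled at", x$pool_at, "SD), n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' @export
plot.binned_distribution <- function(x, ...) {
  edges <- as.numeric(names(x$counts))
  graphics::plot(edges + x$width / 2, x$counts, type = "b",
                 xlab = "typicality effect (SD units)", ylab = "count", ...)
  invisible(x)
}

#' Chi-square comparison of two binned distributions
#'
#' Aligns the two distributions on the union of their bins, drops bins
#' with zero combined count, and runs a standard two-sample chi-square on
#' the 2 x B count table (df = retained bins - 1).
#'
#' @param dist_a,dist_b [standardize_and_bin()] results with the same
#'   width and pooling threshold.
#' @return A list `statistic`, `df`, `p.value`.
#' @export
chi_square_binned <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "binned_distribution"),
            inherits(dist_b, "binned_distribution"))
  if (dist_a$width != dist_b$width || dist_a$pool_at != dist_b$pool_at)
    stop("distributions use different binnings")
  w <- dist_a$width
  key <- function(d) as.integer(round(as.numeric(names(d$counts)) / w))
  all_bins <- sort(unique(c(key(dist_a), key(dist_b))))
  get <- function(d) {
    v <- rep(0L, length(all_bins))
    v[match(key(d), all_bins)] <- d$counts
    v
  }
  m <- rbind(get(dist_a), get(dist_b))
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L) stop("fewer than 2 retained bins")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}
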
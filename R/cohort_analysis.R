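## Patient-level statistics: AEI-survival correlation, dichotomized
## Kaplan-Meier with log-rank and median-survival comparison, pre- vs
## on-therapy t-tests, and the immunogenicity covariate panel.
##
## Kaplan-Meier and the Mantel-Cox log-rank are implemented directly (the
## contracts pin the exact tie and variance handling); the survival
## package is used only as an independent oracle in the test suite.

#' Spearman correlation with Gaussian-approximation p-value
#'
#' `r` is the Pearson correlation of average ranks (ties allowed); the
#' two-sided p-value comes from the classical large-sample normal
#' approximation `z = r * sqrt(n - 1)`. A t-approximation
#' (`t = r * sqrt((n-2)/(1-r^2))`, df `n-2`) is available behind a flag.
#'
#' @param x,y Paired numeric vectors, at least 4 complete observations.
#' @param approximation `"gaussian"` (default) or `"t"`.
#' @return `list(r =, p =, n =, method =)`.
#' @export
spearman_gaussian <- function(x, y, approximation = c("gaussian", "t")) {
  approximation <- match.arg(approximation)
  if (length(x) != length(y)) abort_format("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort_format("need >= 4 complete observations, got %d", n)
  if (sd(x) == 0 || sd(y) == 0)
    abort_format("correlation undefined for a constant vector")
  r <- stats::cor(rank(x), rank(y))
  p <- if (approximation == "gaussian") {
    2 * pnorm(-abs(r) * sqrt(n - 1))
  } else {
    if (abs(r) >= 1) 0
    else 2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2)
  }
  list(r = r, p = p, n = n, method = approximation)
}

#' Split records into low/high AEI groups at a cutoff
#'
#' Records exactly at the cutoff go to the side named by
#' `equal_to_cutoff` (default `"high"`; the dichotomy must be total even
#' though the defining wording — above vs below 50 — excludes equality).
#'
#' @param records `data.frame` with an `aei` column.
#' @param cutoff AEI cutoff (default 50).
#' @param equal_to_cutoff `"high"` or `"low"`.
#' @return `list(low =, high =, cutoff =, equal_to_cutoff =)`.
#' @export
dichotomize_aei <- function(records, cutoff = 50,
                            equal_to_cutoff = c("high", "low")) {
  equal_to_cutoff <- match.arg(equal_to_cutoff)
  records <- as.data.table(records)
  if (nrow(records) == 0L) abort_format("no records to dichotomize")
  stopifnot_cols(records, "aei", "cohort records")
  if (!is_number(cutoff) || cutoff <= 0) abort_format("cutoff must be > 0")
  hi <- if (equal_to_cutoff == "high") records$aei >= cutoff
        else records$aei > cutoff
  list(low = records[!hi], high = records[hi],
       cutoff = cutoff, equal_to_cutoff = equal_to_cutoff)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` steps down by factor `(1 - d_i/n_i)` at each distinct event
#' time; censored observations leave the risk set without a step.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = death, 0 = censored). Default: all
#'   events (the no-censoring special case).
#' @return A `km_curve`: `data.table` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` at each distinct observed time.
#' @export
kaplan_meier <- function(times, events = rep(1L, length(times))) {
  if (length(times) != length(events))
    abort_format("times and events must be paired")
  if (any(!is.finite(times)) || any(times < 0))
    abort_format("times must be finite and >= 0")
  if (any(!events %in% c(0L, 1L)))
    abort_format("events must be 0 or 1")
  ut <- sort(unique(times))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_t <- times == ut[i]
    n_risk[i] <- sum(times >= ut[i])
    n_event[i] <- sum(at_t & events == 1L)
    n_censor[i] <- sum(at_t & events == 0L)
    if (n_event[i] > 0L) s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  structure(data.table(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_curve", "data.table", "data.frame"))
}

#' Survival probability from a KM curve at arbitrary times
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate (right-continuous step function).
#' @return Numeric vector of `S(t)`.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$survival[max(idx)]
  }, numeric(1L))
}

#' Median survival time from a KM curve
#'
#' Smallest observed time with `S(t) <= 0.5`; `NA` (not reached) when the
#' curve never drops to 0.5.
#'
#' @param curve A `km_curve`.
#' @return Time, or `NA_real_` if not reached.
#' @export
median_survival <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (length(idx) == 0L) return(NA_real_)
  as.numeric(curve$time[min(idx)])
}

#' Mantel-Cox log-rank test for two groups
#'
#' Accumulates observed and hypergeometric expected/variance over the
#' pooled distinct event times:
#' `E_a = sum d_t * n_at / n_t`,
#' `V = sum d_t (n_t - d_t) n_at n_bt / (n_t^2 (n_t - 1))`,
#' `chisq = (O_a - E_a)^2 / V`, p from chi-square with 1 df.
#'
#' @param times_a,events_a,times_b,events_b Follow-up times and event
#'   flags per group (each group must contain at least one event).
#' @return `list(chisq =, p =, df = 1, observed =, expected =)`.
#' @export
logrank_test <- function(times_a, events_a = rep(1L, length(times_a)),
                         times_b, events_b = rep(1L, length(times_b))) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    abort_format("both groups must be non-empty")
  if (sum(events_a == 1L) == 0L && sum(events_b == 1L) == 0L)
    abort_format("log-rank requires at least one event")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  ev_times <- sort(unique(times[events == 1L]))
  O_a <- E_a <- V <- 0
  for (t in ev_times) {
    n_t <- sum(times >= t)
    n_at <- sum(times >= t & grp_a)
    n_bt <- n_t - n_at
    d_t <- sum(times == t & events == 1L)
    d_at <- sum(times == t & events == 1L & grp_a)
    O_a <- O_a + d_at
    E_a <- E_a + d_t * n_at / n_t
    if (n_t > 1L)
      V <- V + d_t * (n_t - d_t) * n_at * n_bt / (n_t^2 * (n_t - 1))
  }
  chisq <- if (V > 0) (O_a - E_a)^2 / V else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L, observed = O_a, expected = E_a, variance = V)
}

#' Compare AEI between therapy phases
#'
#' Two-sided Welch t-test on the unpaired group AEIs and a paired t-test
#' on within-patient differences (patients present in both phases).
#' Zero-variance degenerate cases are resolved by rule: zero paired
#' variance with zero mean difference gives p = 1; zero variance with a
#' nonzero difference gives p = 0. Same rule for the unpaired test when
#' both groups are constant.
#'
#' @param pre_records,on_records `data.frame`s with `patient_id` and
#'   `aei`.
#' @return `list(unpaired_p, paired_p, mean_pre, mean_on, sd_pre, sd_on,
#'   mean_paired_diff, n_pairs)`.
#' @export
phase_comparison <- function(pre_records, on_records) {
  pre <- as.data.table(pre_records)
  on <- as.data.table(on_records)
  stopifnot_cols(pre, c("patient_id", "aei"), "pre-phase records")
  stopifnot_cols(on, c("patient_id", "aei"), "on-phase records")
  x <- pre$aei; y <- on$aei

  unpaired_p <- if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) 1 else 0
  } else {
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }

  common <- intersect(pre$patient_id, on$patient_id)
  if (length(common) < 2L)
    abort_format("paired test needs >= 2 patients present in both phases")
  d <- on[match(common, patient_id), aei] - pre[match(common, patient_id), aei]
  paired_p <- if (sd(d) == 0) {
    if (mean(d) == 0) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  list(unpaired_p = unpaired_p, paired_p = paired_p,
       mean_pre = mean(x), mean_on = mean(y),
       sd_pre = sd(x), sd_on = sd(y),
       mean_paired_diff = mean(d), n_pairs = length(common))
}

#' Covariate panel: AEI correlations and low/high group contrasts
#'
#' For each immunogenicity covariate (mutation, neoantigen and neopeptide
#' loads, cytolytic score): panel A gives the Spearman r against AEI with
#' the Gaussian-approximation p (pairwise-complete); panel B gives
#' mean +/- SD in the low- and high-AEI groups with a two-sided Welch
#' t-test p. Rows with fewer than 4 complete pairs (A) or fewer than 2
#' values in a group (B) are flagged `insufficient_data`.
#'
#' @param records Cohort `data.frame` with `aei` plus covariate columns.
#' @param covariates Covariate column names (default the Table-1 panel).
#' @param cutoff,equal_to_cutoff Dichotomization parameters.
#' @param alpha Significance level for the `significant` labels.
#' @return `list(correlations =, group_contrast =)`, two `data.table`s.
#' @export
covariate_panel <- function(records,
                            covariates = c("mutation_load",
                                           "neoantigen_load",
                                           "neopeptide_load",
                                           "cytolytic_score"),
                            cutoff = 50, equal_to_cutoff = "high",
                            alpha = 0.05) {
  records <- as.data.table(records)
  stopifnot_cols(records, c("aei", covariates), "cohort records")
  split <- dichotomize_aei(records, cutoff, equal_to_cutoff)

  corr <- rbindlist(lapply(covariates, function(cv) {
    v <- records[[cv]]
    ok <- is.finite(records$aei) & is.finite(v)
    if (sum(ok) < 4L || sd(v[ok]) == 0)
      return(data.table(covariate = cv, n = sum(ok), spearman_r = NA_real_,
                        p = NA_real_, significant = NA,
                        note = "insufficient_data"))
    sp <- spearman_gaussian(records$aei[ok], v[ok])
    data.table(covariate = cv, n = sp$n, spearman_r = sp$r, p = sp$p,
               significant = sp$p < alpha, note = "")
  }))

  contrast <- rbindlist(lapply(covariates, function(cv) {
    lo <- split$low[[cv]]; lo <- lo[is.finite(lo)]
    hi <- split$high[[cv]]; hi <- hi[is.finite(hi)]
    row <- data.table(covariate = cv,
                      n_low = length(lo), n_high = length(hi),
                      mean_low = if (length(lo)) mean(lo) else NA_real_,
                      sd_low = if (length(lo) > 1L) sd(lo) else NA_real_,
                      mean_high = if (length(hi)) mean(hi) else NA_real_,
                      sd_high = if (length(hi) > 1L) sd(hi) else NA_real_,
                      p = NA_real_, significant = NA, note = "")
    if (length(lo) < 2L || length(hi) < 2L ||
        (sd(lo) == 0 && sd(hi) == 0)) {
      row$note <- "insufficient_data"
    } else {
      row$p <- stats::t.test(lo, hi, var.equal = FALSE)$p.value
      row$significant <- row$p < alpha
    }
    row
  }))
  list(correlations = corr, group_contrast = contrast)
}

#' Full cohort analysis report
#'
#' Runs the pre-therapy AEI vs survival correlation, the dichotomized
#' Kaplan-Meier / log-rank / median-survival comparison, ADAR-mRNA
#' correlations, the phase comparison, and the covariate panel.
#'
#' @param cohort Cohort `data.table` (one row per patient and phase; see
#'   [read_cohort_csv()]) with an `aei` column.
#' @param cutoff,equal_to_cutoff,alpha Analysis parameters (defaults 50,
#'   `"high"`, 0.05).
#' @return `list` with elements `aei_survival_pre`, `aei_survival_on`,
#'   `adar_aei`, `adar_survival`, `dichotomy`, `km_low`, `km_high`,
#'   `logrank`, `median_low`, `median_high`, `phase`, `covariate_panel`,
#'   `params`.
#' @export
cohort_report <- function(cohort, cutoff = 50, equal_to_cutoff = "high",
                          alpha = 0.05) {
  cohort <- as.data.table(cohort)
  stopifnot_cols(cohort, c(cohort_required_cols, "aei"), "cohort table")
  pre <- cohort[phase == "pre"]
  on_ <- cohort[phase == "on"]
  if (nrow(pre) == 0L) abort_format("cohort has no pre-therapy records")

  res <- list(params = list(cutoff = cutoff,
                            equal_to_cutoff = equal_to_cutoff,
                            alpha = alpha))
  res$aei_survival_pre <- spearman_gaussian(pre$aei, pre$survival_weeks)
  res$aei_survival_on <- if (nrow(on_) >= 4L)
    spearman_gaussian(on_$aei, on_$survival_weeks) else NULL

  if ("adar_expr" %in% names(pre) && sum(is.finite(pre$adar_expr)) >= 4L) {
    ok <- is.finite(pre$adar_expr)
    res$adar_aei <- spearman_gaussian(pre$adar_expr[ok], pre$aei[ok])
    res$adar_survival <- spearman_gaussian(pre$adar_expr[ok],
                                           pre$survival_weeks[ok])
  }

  split <- dichotomize_aei(pre, cutoff, equal_to_cutoff)
  res$dichotomy <- list(n_low = nrow(split$low), n_high = nrow(split$high))
  if (nrow(split$low) && nrow(split$high)) {
    res$km_low <- kaplan_meier(split$low$survival_weeks, split$low$event)
    res$km_high <- kaplan_meier(split$high$survival_weeks, split$high$event)
    res$logrank <- logrank_test(split$low$survival_weeks, split$low$event,
                                split$high$survival_weeks, split$high$event)
    res$median_low <- median_survival(res$km_low)
    res$median_high <- median_survival(res$km_high)
  }
  if (nrow(on_) >= 2L &&
      length(intersect(pre$patient_id, on_$patient_id)) >= 2L)
    res$phase <- phase_comparison(pre, on_)
  cov_avail <- intersect(c("mutation_load", "neoantigen_load",
                           "neopeptide_load", "cytolytic_score"),
                         names(pre))
  if (length(cov_avail))
    res$covariate_panel <- covariate_panel(pre, cov_avail, cutoff,
                                           equal_to_cutoff, alpha)
  res
}
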
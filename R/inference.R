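#' Binomial proportion estimate with confidence interval
#'
#' Point estimate `k/n` with a Wilson score interval (default) or an
#' exact Clopper-Pearson interval, both computed from their closed forms
#' (beta-quantile form for Clopper-Pearson).
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param conf Confidence level (default 0.95).
#' @return A list with `point`, `lower`, `upper`, `method`, `conf`, `k`,
#'   `n`.
#' @examples
#' estimate_proportion(63, 100)
#' estimate_proportion(0, 100, method = "clopper_pearson")
#' @export
estimate_proportion <- function(k, n, method = c("wilson", "clopper_pearson"),
                                conf = 0.95) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a positive whole number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n ||
      k != floor(k))
    stop("'k' must be a whole number with 0 <= k <= n", call. = FALSE)
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1)
    stop("'conf' must be in (0, 1)", call. = FALSE)
  p_hat <- k / n
  alpha <- 1 - conf
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  } else {
    lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  }
  list(point = p_hat, lower = lower, upper = upper,
       method = method, conf = conf, k = k, n = n)
}

#' Germination success
#'
#' Fraction of single-spore-sorted wells that produced a germling by day
#' 2, after which no new germling appears. The denominator is the number
#' of spores sorted (one per well).
#'
#' @param wells_sorted Wells (spores) sorted, > 0.
#' @param germinated_day2 Cumulative germling count on day 2
#'   (0 <= germinated_day2 <= wells_sorted).
#' @return `germinated_day2 / wells_sorted`.
#' @examples
#' germination_success(288, 18)  # 0.0625
#' @export
germination_success <- function(wells_sorted, germinated_day2) {
  if (!is.numeric(wells_sorted) || anyNA(wells_sorted) || any(wells_sorted <= 0))
    stop("'wells_sorted' must be positive", call. = FALSE)
  if (!is.numeric(germinated_day2) || anyNA(germinated_day2) ||
      any(germinated_day2 < 0) || any(germinated_day2 > wells_sorted))
    stop("'germinated_day2' must satisfy 0 <= day2 <= wells_sorted",
         call. = FALSE)
  germinated_day2 / wells_sorted
}

#' Delayed-germination fraction
#'
#' Fraction of germlings first detected on day 2 rather than day 1,
#' relative to all germlings detected by day 2 (day-2 count = 100%).
#' When no germling appeared at all (`day2 = 0`) the quantity is
#' undefined and `NA` is returned with attribute `"undefined"` set, never
#' a silent 0.
#'
#' @param day1 Germlings detected on day 1.
#' @param day2 Cumulative germlings detected by day 2 (`day1 <= day2`).
#' @return `(day2 - day1) / day2`, vectorised; `NA` where `day2 = 0`.
#' @examples
#' delayed_fraction(40, 50)  # 0.2
#' @export
delayed_fraction <- function(day1, day2) {
  if (!is.numeric(day1) || !is.numeric(day2) || anyNA(day1) || anyNA(day2) ||
      any(day1 < 0) || any(day2 < day1))
    stop("need 0 <= day1 <= day2", call. = FALSE)
  out <- ifelse(day2 == 0, NA_real_, (day2 - day1) / day2)
  structure(out, undefined = day2 == 0)
}

#' Per-line, per-round fitness table
#'
#' Derives, for every measurement row, the measured positive fraction,
#' the germination success of each arm, the delayed-germination
#' fractions, and the fitness index (positive fraction x positive-arm
#' germination success, via [fitness_index()]). Rows with a missing arm
#' (zero wells sorted or `NA` counts) get `NA` in the affected columns
#' and are flagged in `incomplete`.
#'
#' @param measurements A data frame in the round-measurement schema (see
#'   [read_measurement_table()]).
#' @return A data frame with columns `line_id`, `round`,
#'   `positive_fraction`, `germination_pos`, `germination_neg`,
#'   `fitness_index`, `delayed_pos`, `delayed_neg`, `incomplete`.
#' @export
fitness_table <- function(measurements) {
  m <- validate_measurements(measurements)
  pos_frac <- ifelse(m$facs_analyzed > 0,
                     m$facs_positive / m$facs_analyzed, NA_real_)
  germ_pos <- ifelse(!is.na(m$wells_sorted_pos) & m$wells_sorted_pos > 0,
                     m$germinated_day2_pos / m$wells_sorted_pos, NA_real_)
  germ_neg <- ifelse(!is.na(m$wells_sorted_neg) & m$wells_sorted_neg > 0,
                     m$germinated_day2_neg / m$wells_sorted_neg, NA_real_)
  fit <- ifelse(is.na(pos_frac) | is.na(germ_pos), NA_real_,
                fitness_index(ifelse(is.na(pos_frac), 0, pos_frac),
                              ifelse(is.na(germ_pos), 0, germ_pos)))
  del_pos <- ifelse(!is.na(m$germinated_day2_pos) & m$germinated_day2_pos > 0,
                    (m$germinated_day2_pos - m$germinated_day1_pos) /
                      m$germinated_day2_pos, NA_real_)
  del_neg <- ifelse(!is.na(m$germinated_day2_neg) & m$germinated_day2_neg > 0,
                    (m$germinated_day2_neg - m$germinated_day1_neg) /
                      m$germinated_day2_neg, NA_real_)
  data.frame(
    line_id = m$line_id, round = m$round,
    positive_fraction = pos_frac,
    germination_pos = germ_pos, germination_neg = germ_neg,
    fitness_index = fit,
    delayed_pos = del_pos, delayed_neg = del_neg,
    incomplete = is.na(pos_frac) | is.na(germ_pos)
  )
}

#' Estimate transmission parameters from a round-0 measurement
#'
#' Builds a [transmission_params()] object from the observable starting
#' point of a propagation-without-selection assay: `g` from the
#' positive-arm germination plate, `e` from the negative-arm plate (or
#' the long-term fallback average when that arm is absent), and `p0` from
#' the FACS positive fraction — the measured round-0 positive fraction
#' doubles as the transmission fidelity, mirroring how the model is
#' parameterised from data. Wilson 95% intervals for each parameter are
#' attached as attribute `"intervals"`.
#'
#' @param round0 A one-row data frame in the round-measurement schema.
#' @param fallback_e Germination of negative spores used when the
#'   negative arm is missing (default 0.69, the long-term experimental
#'   average).
#' @param conf Confidence level for the intervals.
#' @return A [transmission_params()] object with attributes `"intervals"`
#'   (named list of [estimate_proportion()] results; `e`'s entry is
#'   `NULL` when the fallback was used) and `"e_fallback"` (logical).
#' @export
estimate_transmission_params <- function(round0, fallback_e = 0.69,
                                         conf = 0.95) {
  m <- validate_measurements(round0)
  if (nrow(m) != 1L)
    stop("'round0' must contain exactly one measurement row", call. = FALSE)
  if (is.na(m$wells_sorted_pos) || m$wells_sorted_pos == 0)
    stop("positive germination arm absent (wells_sorted_pos is 0 or NA); ",
         "cannot estimate g", call. = FALSE)
  if (is.na(m$facs_analyzed) || m$facs_analyzed == 0)
    stop("FACS measurement absent; cannot estimate p0", call. = FALSE)
  est_g <- estimate_proportion(m$germinated_day2_pos, m$wells_sorted_pos,
                               conf = conf)
  est_p0 <- estimate_proportion(m$facs_positive, m$facs_analyzed, conf = conf)
  e_fallback <- is.na(m$wells_sorted_neg) || m$wells_sorted_neg == 0
  est_e <- if (e_fallback) NULL
           else estimate_proportion(m$germinated_day2_neg, m$wells_sorted_neg,
                                    conf = conf)
  params <- transmission_params(
    g = est_g$point,
    e = if (e_fallback) fallback_e else est_e$point,
    p0 = est_p0$point
  )
  attr(params, "intervals") <- list(g = est_g, e = est_e, p0 = est_p0)
  attr(params, "e_fallback") <- e_fallback
  params
}

#' Model-fit error on the log scale
#'
#' Root-mean-square error of `log10(p)` between an observed and a
#' predicted positive-fraction trajectory, over rounds present in both.
#' Censored observations (below the detection limit, i.e. zero positives
#' detected) are excluded, as are non-positive values that have no
#' logarithm.
#'
#' @param observed,predicted Data frames with columns `round` and `p`
#'   ([iterate_trajectory()] output qualifies); `observed` may carry a
#'   logical `below_det` column marking censored rounds.
#' @return RMSE of `log10 p` (a pure number of decades).
#' @examples
#' model_fit_error(data.frame(round = 1, p = 1e-3),
#'                 data.frame(round = 1, p = 1e-4))  # 1
#' @export
model_fit_error <- function(observed, predicted) {
  for (d in list(observed, predicted))
    if (!is.data.frame(d) || !all(c("round", "p") %in% names(d)))
      stop("trajectories need columns 'round' and 'p'", call. = FALSE)
  if (!all(observed$round %in% predicted$round))
    stop("observed rounds missing from the predicted trajectory: ",
         paste(setdiff(observed$round, predicted$round), collapse = ", "),
         call. = FALSE)
  obs <- observed
  if ("below_det" %in% names(obs)) obs <- obs[!obs$below_det, , drop = FALSE]
  pred_p <- predicted$p[match(obs$round, predicted$round)]
  keep <- obs$p > 0 & pred_p > 0
  if (!any(keep))
    stop("no comparable rounds (all observations censored or non-positive)",
         call. = FALSE)
  sqrt(mean((log10(obs$p[keep]) - log10(pred_p[keep]))^2))
}

#' Filter mutations that swept
#'
#' Reporting filter for allele-frequency trajectories: keep mutations
#' that are absent from the ancestral sample and whose frequency reaches
#' at least `min_freq` (inclusive, "at least 50%") in some round.
#'
#' @param table Data frame with columns `mutation_id`, `round`,
#'   `frequency` (in `[0, 1]`), `present_in_ancestor` (logical).
#' @param min_freq Frequency threshold (default 0.5).
#' @return Character vector of mutation ids (possibly empty), in order of
#'   first appearance.
#' @export
filter_sweeping_mutations <- function(table, min_freq = 0.5) {
  req <- c("mutation_id", "round", "frequency", "present_in_ancestor")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop("allele table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(table) == 0L) return(character(0))
  if (any(table$frequency < 0 | table$frequency > 1, na.rm = TRUE))
    stop("frequencies must be in [0, 1]", call. = FALSE)
  tab <- table[!table$present_in_ancestor, , drop = FALSE]
  if (nrow(tab) == 0L) return(character(0))
  peak <- tapply(tab$frequency, tab$mutation_id, max, na.rm = TRUE)
  ids <- names(peak)[peak >= min_freq]
  ids[order(match(ids, tab$mutation_id))]
}

#' Correlation between a sweep and the fitness index
#'
#' Spearman rank correlation between a mutation's per-round allele
#' frequency and the per-round fitness index, quantifying whether a
#' sweep's rise coincides with the fitness increase of its line.
#'
#' @param freqs Per-round allele frequencies.
#' @param fitness Per-round fitness indices (same length, >= 3).
#' @return Spearman's rho in `[-1, 1]`; `NA` with attribute
#'   `"undefined" = TRUE` when either series is constant.
#' @export
sweep_fitness_correlation <- function(freqs, fitness) {
  if (length(freqs) != length(fitness))
    stop("series must have equal length", call. = FALSE)
  if (length(freqs) < 3L)
    stop("need at least 3 rounds", call. = FALSE)
  if (anyNA(freqs) || anyNA(fitness))
    stop("series must not contain NA", call. = FALSE)
  if (length(unique(freqs)) == 1L || length(unique(fitness)) == 1L)
    return(structure(NA_real_, undefined = TRUE))
  # Spearman = Pearson on mid-ranks
  r1 <- rank(freqs); r2 <- rank(fitness)
  structure(stats::cor(r1, r2), undefined = FALSE)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value, computed from the formulas:
#' \deqn{t = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}},\qquad
#'   \nu = \frac{(s_x^2/n_x + s_y^2/n_y)^2}
#'              {\frac{(s_x^2/n_x)^2}{n_x - 1} + \frac{(s_y^2/n_y)^2}{n_y - 1}}}
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return A list with `t`, `df`, `p` (two-sided). When both samples have
#'   zero variance the statistic is undefined: `t` and `p` are `NA` and
#'   `undefined` is `TRUE`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_t_test <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y))
    stop("'x' and 'y' must be numeric without NA", call. = FALSE)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, undefined = TRUE))
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       undefined = FALSE)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (standard convention). For `n <= exact_when_n_le` non-zero
#' differences, the p-value is exact: the null distribution of the
#' positive-rank sum `W` is built by convolution over all `2^n` sign
#' assignments (ties handled through mid-ranks). Beyond that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x First sample of each pair, or the vector of differences when
#'   `y` is `NULL`.
#' @param y Optional second sample (paired with `x`).
#' @param exact_when_n_le Largest `n` for which the exact null
#'   distribution is enumerated (default 25).
#' @return A list with `W` (positive-rank sum), `n` (non-zero pairs), `p`
#'   (two-sided), `exact` (logical). When every difference is zero the
#'   test is undefined: `W` and `p` are `NA` and `undefined` is `TRUE`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # W = 6, p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_when_n_le = 25) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("'x' and 'y' must be paired",
                                     call. = FALSE)
    x - y
  }
  if (!is.numeric(d) || anyNA(d)) stop("differences must be numeric without NA",
                                       call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = NA_real_, n = 0L, p = NA_real_, exact = NA,
                undefined = TRUE))
  r <- rank(abs(d))  # mid-ranks for ties
  W <- sum(r[d > 0])
  if (n <= exact_when_n_le) {
    p <- signed_rank_exact_p(r, W)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(W = W, n = n, p = p, exact = exact, undefined = FALSE)
}

# Exact two-sided p for the signed-rank statistic with mid-ranks r and
# observed positive-rank sum W. Convolution over the doubled ranks (mid-
# ranks are multiples of 1/2) gives the exact null distribution without
# enumerating all 2^n sign vectors.
signed_rank_exact_p <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2W = s
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  w2 <- round(2 * W)
  n_assign <- sum(counts)           # = 2^n
  lo <- sum(counts[seq_len(w2 + 1L)])          # P(2W <= w2)
  hi <- sum(counts[(w2 + 1L):(total + 1L)])    # P(2W >= w2)
  min(1, 2 * min(lo, hi) / n_assign)
}
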
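#' A finite pool of spores
#'
#' Discrete counterpart of the positive fraction: integer counts of
#' bacteria-positive and bacteria-negative spores in a simulated
#' population. Counts are stored as doubles because simulated pools
#' routinely exceed `.Machine$integer.max` (a plate of 100,000 germlings
#' at 10,000 spores each is 1e9 spores), but must be non-negative whole
#' numbers.
#'
#' @param n_pos Count of bacteria-positive spores.
#' @param n_neg Count of bacteria-negative spores.
#' @return An object of class `"spore_pool"` with fields `n_pos`, `n_neg`.
#' @examples
#' spore_pool(300, 0)
#' @export
spore_pool <- function(n_pos, n_neg) {
  for (nm in c("n_pos", "n_neg")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v))
      stop(sprintf("'%s' must be a single non-negative whole number", nm),
           call. = FALSE)
  }
  structure(list(n_pos = as.numeric(n_pos), n_neg = as.numeric(n_neg)),
            class = "spore_pool")
}

#' @export
print.spore_pool <- function(x, ...) {
  tot <- x$n_pos + x$n_neg
  frac <- if (tot > 0) x$n_pos / tot else NA_real_
  cat(sprintf("Spore pool: %s positive / %s total (fraction %.4g)\n",
              format(x$n_pos, big.mark = ","), format(tot, big.mark = ","),
              frac))
  invisible(x)
}

pool_total <- function(pool) pool$n_pos + pool$n_neg

pool_fraction <- function(pool) {
  tot <- pool_total(pool)
  if (tot == 0) 0 else pool$n_pos / tot
}

#' Simulation design configuration
#'
#' Describes one serial-passage design: how many spores are plated per
#' round, how many are analysed per flow-cytometry measurement, the spore
#' yield per germling, and whether positive selection (bulk sorting of
#' bacteria-positive spores) is applied between rounds.
#'
#' @param n_plated Spores plated per round (default 100,000, the standard
#'   plating density of the selection experiment).
#' @param n_analyzed Spores analysed per FACS measurement (default
#'   1,000,000; 100,000-1,000,000 were analysed depending on the size of
#'   the positive fraction).
#' @param spores_per_germling Spore yield S per germling (default 10,000;
#'   not reported in the experiment, assumed equal for positive and
#'   negative germlings).
#' @param selection_mode `"positive_sort"` (plate only sorted positive
#'   spores, the adaptive-evolution design) or `"none"` (plate an unsorted
#'   sample, the stability assay).
#' @param sort_purity Fraction of sorted "positive" spores that truly
#'   carry bacteria (default 1: gates validated microscopically).
#' @param delayed_fraction_pos,delayed_fraction_neg Probability that a
#'   germinating positive/negative spore is first seen on day 2 rather
#'   than day 1 of the germination assay.
#' @param load_effect Optional function mapping per-spore bacterial load
#'   to germination probability; when supplied, positive-spore
#'   germination is load-dependent (see [generate_facs_intensities()] for
#'   the load model). Default `NULL` (off).
#' @param load_model Lognormal load model used when `load_effect` is on;
#'   see [load_model()].
#' @param seed Optional integer seed consumed by [run_passage_experiment()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_plated = 1e5, n_analyzed = 1e6,
                       spores_per_germling = 1e4,
                       selection_mode = c("positive_sort", "none"),
                       sort_purity = 1,
                       delayed_fraction_pos = 0.2,
                       delayed_fraction_neg = 0.05,
                       load_effect = NULL,
                       load_model = NULL,
                       seed = NULL) {
  selection_mode <- match.arg(selection_mode)
  for (nm in c("n_plated", "n_analyzed", "spores_per_germling")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != floor(v))
      stop(sprintf("'%s' must be a positive whole number", nm), call. = FALSE)
  }
  for (nm in c("sort_purity", "delayed_fraction_pos", "delayed_fraction_neg")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
  }
  if (!is.null(load_effect) && !is.function(load_effect))
    stop("'load_effect' must be NULL or a function(load) -> probability",
         call. = FALSE)
  structure(list(n_plated = n_plated, n_analyzed = n_analyzed,
                 spores_per_germling = spores_per_germling,
                 selection_mode = selection_mode, sort_purity = sort_purity,
                 delayed_fraction_pos = delayed_fraction_pos,
                 delayed_fraction_neg = delayed_fraction_neg,
                 load_effect = load_effect, load_model = load_model,
                 seed = seed),
            class = "sim_config")
}

# Binomial sampler that tolerates population sizes beyond .Machine$integer.max.
# Exact rbinom when the size fits an R integer; otherwise a Poisson
# approximation for rare events or a rounded-normal approximation, both
# clamped to [0, size]. Pools of ~1e9-1e10 spores make this necessary.
rbinom_large <- function(n, size, prob) {
  stopifnot(all(size >= 0), all(prob >= 0), all(prob <= 1))
  size <- as.numeric(size)
  out <- numeric(n)
  if (length(size) == 1L) size <- rep(size, n)
  if (length(prob) == 1L) prob <- rep(prob, n)
  small <- size <= .Machine$integer.max
  if (any(small))
    out[small] <- as.numeric(stats::rbinom(sum(small), size[small], prob[small]))
  if (any(!small)) {
    s <- size[!small]; p <- prob[!small]
    mu <- s * p
    k <- ifelse(mu < 1e4 | (s - mu) < 1e4,
                # rare (or near-total) events: Poisson on the small side
                ifelse(mu <= s - mu,
                       stats::rpois(length(s), mu),
                       s - stats::rpois(length(s), s - mu)),
                round(stats::rnorm(length(s), mu, sqrt(s * p * (1 - p)))))
    out[!small] <- pmin(pmax(k, 0), s)
  }
  out
}

#' Germinate a spore pool
#'
#' Each positive spore germinates independently with probability
#' `params$g`, each negative spore with probability `params$e`. Draws come
#' from the current R random stream; seed upstream for reproducibility.
#'
#' @param pool A [spore_pool()].
#' @param params A [transmission_params()] object.
#' @return A list with counts `germlings_pos` and `germlings_neg`.
#' @export
germinate <- function(pool, params) {
  params <- as_transmission_params(params)
  stopifnot(inherits(pool, "spore_pool"))
  list(germlings_pos = rbinom_large(1L, pool$n_pos, params$g),
       germlings_neg = rbinom_large(1L, pool$n_neg, params$e))
}

#' Sporulate germlings into a new spore pool
#'
#' Each germling yields `S` spores. A positive germling transmits bacteria
#' to each of its spores independently with probability `p0`; negative
#' germlings yield only negative spores. Total spore count is conserved:
#' exactly `S * (germlings_pos + germlings_neg)` spores are produced.
#'
#' @param germlings_pos,germlings_neg Germling counts.
#' @param p0 Transmission fidelity in `[0, 1]`.
#' @param S Spores per germling (integer >= 1).
#' @return A [spore_pool()].
#' @export
sporulate <- function(germlings_pos, germlings_neg, p0, S) {
  stopifnot(germlings_pos >= 0, germlings_neg >= 0, S >= 1, S == floor(S))
  check_fraction(p0, "p0")
  # sum of independent Binomial(S, p0) over germlings collapses to one draw
  n_from_pos <- germlings_pos * S
  n_pos <- rbinom_large(1L, n_from_pos, p0)
  spore_pool(n_pos, (n_from_pos - n_pos) + germlings_neg * S)
}

#' Flow-cytometric measurement of the positive fraction
#'
#' Samples `n_analyzed` spores from the pool without replacement
#' (hypergeometric) and reports the measured positive fraction. For pools
#' at least 100x larger than the sample, a binomial approximation is used
#' (the depletion correction is negligible and hypergeometric draws
#' overflow R's integer range for large pools).
#'
#' @param pool A [spore_pool()].
#' @param n_analyzed Number of spores analysed (>= 1, at most the pool
#'   size).
#' @return A list with `p_hat` (= k/n_analyzed), `k` (positives detected),
#'   `n_analyzed`, and `below_detection` (`TRUE` when k = 0).
#' @export
facs_measure <- function(pool, n_analyzed) {
  stopifnot(inherits(pool, "spore_pool"))
  if (!is.numeric(n_analyzed) || length(n_analyzed) != 1L || n_analyzed < 1 ||
      n_analyzed != floor(n_analyzed))
    stop("'n_analyzed' must be a positive whole number", call. = FALSE)
  tot <- pool_total(pool)
  if (n_analyzed > tot)
    stop(sprintf("cannot analyse %s spores from a pool of %s without replacement",
                 format(n_analyzed), format(tot)), call. = FALSE)
  if (tot >= 100 * n_analyzed || tot > .Machine$integer.max) {
    k <- rbinom_large(1L, n_analyzed, pool_fraction(pool))
  } else {
    k <- as.numeric(stats::rhyper(1L, pool$n_pos, pool$n_neg, n_analyzed))
  }
  list(p_hat = k / n_analyzed, k = k, n_analyzed = n_analyzed,
       below_detection = k == 0)
}

#' Bulk-sort positive spores from a pool
#'
#' Models FACS bulk sorting for the positive gate: `n_sorted` spores are
#' kept, of which `Binomial(n_sorted, sort_purity)` truly carry bacteria.
#' The truly positive portion must be available in the pool; the
#' contaminating portion comes from the negative spores.
#'
#' @param pool A [spore_pool()].
#' @param n_sorted Number of spores to sort.
#' @param sort_purity Fraction of sorted spores that are truly positive
#'   (default 1).
#' @return A [spore_pool()] of exactly `n_sorted` spores.
#' @export
sort_positive <- function(pool, n_sorted, sort_purity = 1) {
  stopifnot(inherits(pool, "spore_pool"))
  if (!is.numeric(n_sorted) || length(n_sorted) != 1L || n_sorted < 1 ||
      n_sorted != floor(n_sorted))
    stop("'n_sorted' must be a positive whole number", call. = FALSE)
  check_fraction(sort_purity, "sort_purity")
  k_pos <- if (sort_purity == 1) n_sorted
           else rbinom_large(1L, n_sorted, sort_purity)
  if (k_pos > pool$n_pos)
    stop(sprintf(
      "insufficient positive spores: sort requires %s but the pool holds %s (shortfall %s)",
      format(k_pos), format(pool$n_pos), format(k_pos - pool$n_pos)),
      call. = FALSE)
  if (n_sorted - k_pos > pool$n_neg)
    stop(sprintf(
      "insufficient negative spores for impure sort: need %s, pool holds %s",
      format(n_sorted - k_pos), format(pool$n_neg)), call. = FALSE)
  spore_pool(k_pos, n_sorted - k_pos)
}

# Draw an unsorted plating sample of n from the pool (hypergeometric with
# binomial shortcut, as in facs_measure).
plate_sample <- function(pool, n) {
  tot <- pool_total(pool)
  n <- min(n, tot)  # plate everything when fewer spores exist than wanted
  if (n == 0) return(spore_pool(0, 0))
  if (tot >= 100 * n || tot > .Machine$integer.max) {
    k <- rbinom_large(1L, n, pool_fraction(pool))
  } else {
    k <- as.numeric(stats::rhyper(1L, pool$n_pos, pool$n_neg, n))
  }
  spore_pool(k, n - k)
}

# Load-dependent germination of positive spores: draws per-spore lognormal
# loads and Bernoulli germination with probability load_effect(load).
# For very large pools the mean germination probability is estimated from
# a Monte Carlo sample of loads and applied binomially.
germinate_with_load <- function(n_pos, load_effect, lm) {
  if (n_pos == 0) return(0)
  if (n_pos <= 1e6) {
    loads <- stats::rlnorm(n_pos, meanlog = log(lm$median), sdlog = lm$sigma)
    pr <- pmin(pmax(load_effect(loads), 0), 1)
    sum(stats::runif(n_pos) < pr)
  } else {
    loads <- stats::rlnorm(1e5, meanlog = log(lm$median), sdlog = lm$sigma)
    pbar <- mean(pmin(pmax(load_effect(loads), 0), 1))
    rbinom_large(1L, n_pos, pbar)
  }
}

#' Run a serial-passage experiment
#'
#' Simulates `n_rounds` rounds of the spore propagation cycle on a finite
#' population. Each round: measure the positive fraction by FACS, then
#' either bulk-sort positives (`selection_mode = "positive_sort"`) or take
#' an unsorted sample (`"none"`), plate `n_plated` spores (or all
#' available if fewer), germinate, and sporulate. If no germling forms,
#' the run terminates with status `"extinct"`.
#'
#' @param config A [sim_config()].
#' @param params A [transmission_params()] object, or a list of one per
#'   round (a parameter schedule emulating host adaptation).
#' @param p_init Initial true positive fraction used to build the starting
#'   pool (ignored when `pool_init` is given).
#' @param n_rounds Number of rounds (>= 0).
#' @param pool_init Optional starting [spore_pool()]. Default: a pool of
#'   `n_plated * spores_per_germling` spores at fraction `p_init`.
#' @param line_id Label written into the records (default `"L1"`).
#' @param seed Optional integer seed; defaults to `config$seed`. The R
#'   random stream is seeded once at entry when non-NULL.
#' @return A data frame of per-round records with columns `line_id`,
#'   `round`, `n_analyzed`, `n_positive_detected`, `p_hat`,
#'   `below_detection`, `n_plated`, `germlings_pos`, `germlings_neg`,
#'   `status`, plus `true_fraction` and the threshold flags `below_prop`,
#'   `below_det` computed from the pool's true fraction. Round 0 is the
#'   state of the initial pool.
#' @examples
#' cfg <- sim_config(selection_mode = "none", seed = 1)
#' pars <- transmission_params(g = 0.88, e = 0.69, p0 = 0.29)
#' run_passage_experiment(cfg, pars, p_init = 0.29, n_rounds = 3)
#' @export
run_passage_experiment <- function(config, params, p_init, n_rounds,
                                   pool_init = NULL, line_id = "L1",
                                   seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  schedule <- params_schedule(params, n_rounds)
  if (is.null(pool_init)) {
    check_fraction(p_init, "p_init")
    n0 <- config$n_plated * config$spores_per_germling
    pool_init <- spore_pool(round(n0 * p_init), n0 - round(n0 * p_init))
  }
  stopifnot(inherits(pool_init, "spore_pool"))
  if (!is.numeric(n_rounds) || n_rounds < 0 || n_rounds != floor(n_rounds))
    stop("'n_rounds' must be a non-negative integer", call. = FALSE)

  pool <- pool_init
  rows <- vector("list", n_rounds + 1L)
  rows[[1L]] <- passage_record(line_id, 0L, pool, config, schedule[[1L]],
                               germ = NULL, status = "ok")
  status <- "ok"
  if (n_rounds > 0) for (r in seq_len(n_rounds)) {
    pars_r <- schedule[[min(r, length(schedule))]]
    # selection / plating
    plated <- if (config$selection_mode == "positive_sort") {
      n_want <- min(config$n_plated, pool$n_pos)
      if (n_want < 1)
        stop(sprintf("round %d: no positive spores left to sort", r),
             call. = FALSE)
      sort_positive(pool, n_want, config$sort_purity)
    } else {
      plate_sample(pool, config$n_plated)
    }
    # germination
    germ <- if (is.null(config$load_effect)) {
      germinate(plated, pars_r)
    } else {
      lm <- config$load_model %||% load_model()
      list(germlings_pos = germinate_with_load(plated$n_pos,
                                               config$load_effect, lm),
           germlings_neg = rbinom_large(1L, plated$n_neg, pars_r$e))
    }
    if (germ$germlings_pos + germ$germlings_neg == 0) {
      status <- "extinct"
      pool <- spore_pool(0, 0)
      rows[[r + 1L]] <- passage_record(line_id, r, pool, config, pars_r,
                                       germ, status)
      break
    }
    pool <- sporulate(germ$germlings_pos, germ$germlings_neg,
                      pars_r$p0, config$spores_per_germling)
    rows[[r + 1L]] <- passage_record(line_id, r, pool, config, pars_r,
                                     germ, status)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

params_schedule <- function(params, n_rounds) {
  if (inherits(params, "transmission_params")) return(list(params))
  if (is.list(params) &&
      all(vapply(params, inherits, logical(1L), "transmission_params"))) {
    if (length(params) < 1L)
      stop("parameter schedule must contain at least one entry", call. = FALSE)
    return(params)
  }
  stop("'params' must be a transmission_params object or a list of them",
       call. = FALSE)
}

passage_record <- function(line_id, round, pool, config, pars, germ, status) {
  meas <- if (status == "extinct") {
    list(p_hat = 0, k = 0, n_analyzed = config$n_analyzed,
         below_detection = TRUE)
  } else {
    facs_measure(pool, min(config$n_analyzed, pool_total(pool)))
  }
  tf <- pool_fraction(pool)
  data.frame(
    line_id = line_id, round = as.integer(round),
    n_analyzed = meas$n_analyzed, n_positive_detected = meas$k,
    p_hat = meas$p_hat, below_detection = meas$below_detection,
    n_plated = config$n_plated,
    germlings_pos = if (is.null(germ)) NA_real_ else germ$germlings_pos,
    germlings_neg = if (is.null(germ)) NA_real_ else germ$germlings_neg,
    status = status,
    true_fraction = tf,
    below_prop = tf < pars$t_prop,
    below_det = tf < pars$t_det
  )
}
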
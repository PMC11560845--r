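#' Lognormal model of per-spore bacterial load
#'
#' Right-skewed per-spore load distribution (in um^3 of bacterial volume)
#' for bacteria-positive spores, plus the linear load-to-fluorescence map
#' used when emulating FACS intensities.
#'
#' @param median Median load per positive spore, um^3 (default 2: a
#'   handful of 0.3 um^3 rod bacteria).
#' @param sigma Lognormal shape (sd of log load; default 0.6).
#' @param intensity_per_load Fluorescence units per um^3 of bacteria
#'   (default 1000).
#' @param baseline Autofluorescence baseline intensity of a spore
#'   (default 100).
#' @param baseline_sd Spread of the autofluorescence (default 20).
#' @return A list of class `"load_model"`.
#' @export
load_model <- function(median = 2, sigma = 0.6, intensity_per_load = 1000,
                       baseline = 100, baseline_sd = 20) {
  stopifnot(median > 0, sigma >= 0, intensity_per_load >= 0,
            baseline >= 0, baseline_sd >= 0)
  structure(list(median = median, sigma = sigma,
                 intensity_per_load = intensity_per_load,
                 baseline = baseline, baseline_sd = baseline_sd),
            class = "load_model")
}

#' Ground-truth configuration for a synthetic experiment
#'
#' The stated world of the synthetic serial-passage experiment: model
#' parameters plus the experimental design — 10 lines started from ~300
#' positive spores each, 100,000 spores plated per round, up to 1,000,000
#' spores analysed per FACS measurement, 96-well germination plates (3
#' positive + 1 negative plate per sample, 5 positive plates in round 1),
#' and pooling of the 7 weakest lines after round 7.
#'
#' @param params A [transmission_params()] object, or a list of one per
#'   round (schedule emulating host adaptation across rounds).
#' @param n_lines Evolution lines (default 10).
#' @param n_rounds Propagation rounds (default 10).
#' @param round1_spores Positive spores per line at round 1 (default 300).
#' @param round1_pool Size of the unsorted spore collection from the
#'   injected germling out of which the round-1 lines are sorted
#'   (default 1e8). Round-1 FACS rows measure this collection, whose
#'   true positive fraction is `p0`.
#' @param n_plated Spores plated per round (default 100,000).
#' @param n_analyzed Spores per FACS measurement (default 1,000,000).
#' @param pool_after_round Round after which the weakest lines are pooled
#'   (default 7; `NA` disables pooling).
#' @param n_kept_lines Lines kept individual at pooling (default 3, the
#'   best by fitness index).
#' @param plates_pos,plates_neg 96-well plates sorted per sample for the
#'   positive/negative germination arm (defaults 3 and 1).
#' @param plates_pos_round1 Positive plates in round 1 (default 5).
#' @param wells_per_plate Wells per plate (default 96).
#' @param spores_per_germling Spore yield per germling (default 10,000).
#' @param delayed_fraction_pos,delayed_fraction_neg Probability a
#'   germinating positive/negative spore appears only on day 2 (defaults
#'   0.2 and 0.05: positives germinate late more often).
#' @param selection_mode `"positive_sort"` (default) or `"none"`.
#' @param load_mod A [load_model()].
#' @param sweep_model Data frame describing logistic allele-frequency
#'   sweeps: columns `mutation_id`, `line_id`, `s` (logistic steepness
#'   per round), `midpoint_round`, `present_in_ancestor`. Default: the
#'   built-in example set (9 sweeping + 3 non-sweeping mutations).
#' @param aging_days Storage age of spores in days (default 0); when
#'   positive, `g` decays as `g * exp(-aging_rate * aging_days)`.
#' @param aging_rate Exponential decay rate of positive-spore germination
#'   per day of storage (default 0.09, reproducing a fall from >50% to
#'   <5% over about a month).
#' @param seed Integer seed for the whole generated experiment.
#' @return A list of class `"truth_config"`.
#' @export
truth_config <- function(params, n_lines = 10, n_rounds = 10,
                         round1_spores = 300, round1_pool = 1e8,
                         n_plated = 1e5,
                         n_analyzed = 1e6, pool_after_round = 7,
                         n_kept_lines = 3, plates_pos = 3, plates_neg = 1,
                         plates_pos_round1 = 5, wells_per_plate = 96,
                         spores_per_germling = 1e4,
                         delayed_fraction_pos = 0.2,
                         delayed_fraction_neg = 0.05,
                         selection_mode = c("positive_sort", "none"),
                         load_mod = load_model(),
                         sweep_model = default_sweep_model(),
                         aging_days = 0, aging_rate = 0.09,
                         seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  params_schedule(params, n_rounds)  # validates
  stopifnot(n_lines >= 1, n_rounds >= 1, round1_spores >= 1,
            aging_days >= 0, aging_rate >= 0)
  structure(list(params = params, n_lines = n_lines, n_rounds = n_rounds,
                 round1_spores = round1_spores, round1_pool = round1_pool,
                 n_plated = n_plated,
                 n_analyzed = n_analyzed, pool_after_round = pool_after_round,
                 n_kept_lines = n_kept_lines, plates_pos = plates_pos,
                 plates_neg = plates_neg, plates_pos_round1 = plates_pos_round1,
                 wells_per_plate = wells_per_plate,
                 spores_per_germling = spores_per_germling,
                 delayed_fraction_pos = delayed_fraction_pos,
                 delayed_fraction_neg = delayed_fraction_neg,
                 selection_mode = selection_mode, load_mod = load_mod,
                 sweep_model = sweep_model,
                 aging_days = aging_days, aging_rate = aging_rate,
                 seed = seed),
            class = "truth_config")
}

# Example sweep set: 9 mutations that reach >= 50% in some line (4 of them
# in the fittest line, L4) and 3 that stay below threshold or were already
# present in the ancestor.
default_sweep_model <- function() {
  data.frame(
    mutation_id = c(paste0("mut_L4_", 1:4), paste0("mut_other_", 1:5),
                    "mut_low_1", "mut_low_2", "mut_ancestral"),
    line_id = c(rep("L4", 4), "L1", "L2", "L2", "L7", "L9",
                "L4", "L3", "L4"),
    s = c(rep(1.6, 4), rep(1.4, 5), 0.5, 0.4, 0),
    midpoint_round = c(8, 8.5, 8, 9, 6, 7, 8, 6.5, 7.5, 14, 15, 0),
    present_in_ancestor = c(rep(FALSE, 11), TRUE)
  )
}

#' Generate a complete synthetic serial-passage experiment
#'
#' Drives the stochastic simulator round by round for every line of the
#' configured design — FACS measurement, germination plates for both
#' arms, positive sorting (or unsorted plating), germination,
#' sporulation, and the pooling of the weakest lines after the configured
#' round — and emits the measurement table in the analysis schema, an
#' allele-frequency table, and a run manifest. The manifest records the
#' seed and the ground truth and is kept separate from the data so
#' analyses can be run blind to truth.
#'
#' @param truth A [truth_config()].
#' @return A list with `measurements` (round-measurement data frame),
#'   `alleles` (allele-frequency data frame), and `manifest` (list with
#'   `seed`, `truth`, `package_version`).
#' @examples
#' pars <- transmission_params(g = 0.6, e = 0.69, p0 = 0.1)
#' out <- generate_experiment(truth_config(pars, n_lines = 2, n_rounds = 3,
#'                                         seed = 7))
#' head(out$measurements)
#' @export
generate_experiment <- function(truth) {
  stopifnot(inherits(truth, "truth_config"))
  set.seed(truth$seed)
  schedule <- params_schedule(truth$params, truth$n_rounds)
  pars_at <- function(r) {
    p <- schedule[[min(r, length(schedule))]]
    if (truth$aging_days > 0)
      p <- transmission_params(
        g = p$g * exp(-truth$aging_rate * truth$aging_days),
        e = p$e, p0 = p$p0, t_prop = p$t_prop, t_det = p$t_det)
    p
  }

  lines <- paste0("L", seq_len(truth$n_lines))
  # Round 1: the spore collection of the single injected germling, with
  # true positive fraction p0, is measured and then the lines are founded
  # from equal numbers of sorted positive spores.
  pars1 <- pars_at(1)
  coll_pos <- rbinom_large(1L, truth$round1_pool, pars1$p0)
  collection <- spore_pool(coll_pos, truth$round1_pool - coll_pos)
  need_pos <- truth$n_lines * truth$round1_spores +
    truth$plates_pos_round1 * truth$wells_per_plate
  if (collection$n_pos < need_pos && pars1$p0 > 0)
    stop(sprintf(
      "infeasible design (round 1, all lines): %s positive spores needed but the collection of %s holds only %s",
      format(need_pos), format(truth$round1_pool), format(collection$n_pos)),
      call. = FALSE)
  # with p0 = 0 there is nothing positive to sort: lines are founded from
  # negative spores and the positive fraction is 0 throughout
  found_pool <- if (pars1$p0 > 0) spore_pool(truth$round1_spores, 0)
                else spore_pool(0, truth$round1_spores)
  pools <- stats::setNames(
    lapply(lines, function(l) found_pool), lines)
  active <- lines
  rows <- list()
  fitness_by_line <- stats::setNames(numeric(length(lines)), lines)

  for (r in seq_len(truth$n_rounds)) {
    pars <- pars_at(r)
    for (l in active) {
      pool <- pools[[l]]
      n_avail <- pool_total(pool)
      if (n_avail < 1) stop(sprintf(
        "infeasible design: line %s entered round %d with no spores", l, r),
        call. = FALSE)
      # FACS: round 1 measures the shared collection, later rounds the
      # line's own spore pool
      meas_pool <- if (r == 1) collection else pool
      n_an <- min(truth$n_analyzed, pool_total(meas_pool))
      meas <- facs_measure(meas_pool, n_an)
      # germination plates: single spores sorted per arm
      n_wp <- (if (r == 1) truth$plates_pos_round1 else truth$plates_pos) *
        truth$wells_per_plate
      n_wn <- truth$plates_neg * truth$wells_per_plate
      arm_pos <- germination_arm(min(n_wp, meas_pool$n_pos), pars$g,
                                 truth$delayed_fraction_pos)
      arm_neg <- germination_arm(min(n_wn, meas_pool$n_neg), pars$e,
                                 truth$delayed_fraction_neg)
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = l, round = r,
        facs_analyzed = meas$n_analyzed, facs_positive = meas$k,
        wells_sorted_pos = arm_pos$wells,
        germinated_day1_pos = arm_pos$day1,
        germinated_day2_pos = arm_pos$day2,
        wells_sorted_neg = arm_neg$wells,
        germinated_day1_neg = arm_neg$day1,
        germinated_day2_neg = arm_neg$day2
      )
      fitness_by_line[[l]] <-
        (meas$k / meas$n_analyzed) *
        (if (arm_pos$wells > 0) arm_pos$day2 / arm_pos$wells else 0)
      # propagate to the next round
      if (r < truth$n_rounds) {
        plated <- if (truth$selection_mode == "positive_sort") {
          n_want <- min(truth$n_plated, pool$n_pos)
          if (n_want < 1) stop(sprintf(
            "infeasible design: line %s has no positive spores to sort in round %d",
            l, r), call. = FALSE)
          sort_positive(pool, n_want)
        } else {
          plate_sample(pool, truth$n_plated)
        }
        germ <- germinate(plated, pars)
        if (germ$germlings_pos + germ$germlings_neg == 0) stop(sprintf(
          "infeasible design: line %s went extinct in round %d (no germlings)",
          l, r), call. = FALSE)
        pools[[l]] <- sporulate(germ$germlings_pos, germ$germlings_neg,
                                pars$p0, truth$spores_per_germling)
      }
    }
    # pooling: keep the best lines individual, merge the rest
    if (!is.na(truth$pool_after_round) && r == truth$pool_after_round &&
        r < truth$n_rounds && length(active) > truth$n_kept_lines) {
      keep <- names(sort(fitness_by_line[active], decreasing = TRUE))[
        seq_len(truth$n_kept_lines)]
      merged <- setdiff(active, keep)
      # equal amounts of positive spores from each pooled line
      n_each <- min(vapply(pools[merged], function(p) p$n_pos, numeric(1)))
      contrib <- lapply(pools[merged], function(p) {
        if (p$n_pos == n_each) p else sort_positive(p, n_each)
      })
      pools[["LP"]] <- spore_pool(sum(vapply(contrib, function(p) p$n_pos,
                                             numeric(1))),
                                  sum(vapply(contrib, function(p) p$n_neg,
                                             numeric(1))))
      fitness_by_line[["LP"]] <- mean(fitness_by_line[merged])
      active <- c(keep, "LP")
    }
  }

  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  alleles <- generate_allele_table(truth)
  manifest <- list(seed = truth$seed,
                   truth = truth_to_manifest(truth),
                   package_version = as.character(utils::packageVersion("endosim")))
  list(measurements = measurements, alleles = alleles, manifest = manifest)
}

# one germination arm: wells single-spore-sorted, each germinates with
# probability pr; of the germinators, a delayed fraction shows on day 2 only
germination_arm <- function(wells, pr, delayed) {
  if (wells < 1) return(list(wells = 0, day1 = 0, day2 = 0))
  day2 <- as.numeric(stats::rbinom(1L, wells, pr))
  day1 <- as.numeric(stats::rbinom(1L, day2, 1 - delayed))
  list(wells = wells, day1 = day1, day2 = day2)
}

# logistic sweep trajectories sampled at integer rounds with small
# binomial-style measurement noise
generate_allele_table <- function(truth) {
  sm <- truth$sweep_model
  if (is.null(sm) || nrow(sm) == 0L)
    return(data.frame(mutation_id = character(0), round = integer(0),
                      frequency = numeric(0),
                      present_in_ancestor = logical(0)))
  rounds <- seq_len(truth$n_rounds)
  depth <- 200  # simulated read depth per locus/round
  out <- do.call(rbind, lapply(seq_len(nrow(sm)), function(i) {
    f <- if (sm$present_in_ancestor[i]) rep(0.95, length(rounds))
         else stats::plogis(sm$s[i] * (rounds - sm$midpoint_round[i]))
    f_obs <- stats::rbinom(length(rounds), depth, f) / depth
    data.frame(mutation_id = sm$mutation_id[i], round = rounds,
               frequency = f_obs,
               present_in_ancestor = sm$present_in_ancestor[i])
  }))
  rownames(out) <- NULL
  out
}

truth_to_manifest <- function(truth) {
  t <- unclass(truth)
  t$params <- if (inherits(truth$params, "transmission_params"))
    unclass(truth$params) else lapply(truth$params, unclass)
  t$load_mod <- unclass(t$load_mod)
  t
}

#' Generate a round-0 measurement at known parameters
#'
#' Produces a single measurement row of the round-measurement schema at a
#' known ground truth: a large spore pool at true positive fraction
#' `params$p0` is measured by FACS, and single spores of each class are
#' sorted into germination wells. Used for parameter-recovery validation
#' of [estimate_transmission_params()].
#'
#' @param params A [transmission_params()] object (the truth).
#' @param n_analyzed FACS sample size (default 1,000,000).
#' @param wells_pos,wells_neg Germination wells per arm (default 288 and
#'   96, i.e. three positive plates and one negative plate of 96 wells).
#' @param delayed_fraction_pos,delayed_fraction_neg Day-2-only detection
#'   probabilities.
#' @param seed Optional seed.
#' @return A one-row data frame in the round-measurement schema.
#' @export
generate_round0_measurement <- function(params, n_analyzed = 1e6,
                                        wells_pos = 288, wells_neg = 96,
                                        delayed_fraction_pos = 0.2,
                                        delayed_fraction_neg = 0.05,
                                        seed = NULL) {
  params <- as_transmission_params(params)
  if (!is.null(seed)) set.seed(seed)
  k <- as.numeric(stats::rbinom(1L, n_analyzed, params$p0))
  arm_pos <- germination_arm(wells_pos, params$g, delayed_fraction_pos)
  arm_neg <- germination_arm(wells_neg, params$e, delayed_fraction_neg)
  data.frame(
    line_id = "round0", round = 0L,
    facs_analyzed = n_analyzed, facs_positive = k,
    wells_sorted_pos = arm_pos$wells,
    germinated_day1_pos = arm_pos$day1, germinated_day2_pos = arm_pos$day2,
    wells_sorted_neg = arm_neg$wells,
    germinated_day1_neg = arm_neg$day1, germinated_day2_neg = arm_neg$day2
  )
}

#' Generate a synthetic 3D spore image stack
#'
#' Builds a voxel stack of one spore: rod-shaped bacteria (about 0.5 x 2
#' um) placed at random inside an ellipsoidal spore mask, optionally
#' blurred with an isotropic Gaussian point-spread function, with Poisson
#' shot noise and Gaussian read noise added on top. The pre-noise count
#' of above-background voxels is returned as ground truth.
#'
#' @param n_bacteria Number of rods to place (>= 0).
#' @param shape Stack dimensions (z, y, x) in voxels (default
#'   `c(24, 64, 64)`).
#' @param voxel_dims Voxel size in um (z, y, x), default
#'   `c(0.2, 0.1, 0.1)`.
#' @param psf_sigma Gaussian blur sigma in um (default 0 = no blur).
#' @param background Background intensity level (default 10).
#' @param signal Intensity of bacterial voxels before blur/noise
#'   (default 200).
#' @param poisson_noise Logical: apply Poisson resampling of intensities
#'   (default `FALSE`).
#' @param gaussian_sd Sd of additive Gaussian noise (default 0).
#' @param seed Optional seed.
#' @param max_tries Placement attempts per rod before declaring the
#'   geometry overcrowded (default 200).
#' @return A list with `stack` (a [voxel_stack()]) and `truth_voxels`
#'   (the pre-noise above-background voxel count).
#' @examples
#' gs <- generate_spore_stack(3, seed = 1)
#' quantify_load(gs$stack, threshold = 100)$n_voxels == gs$truth_voxels
#' @export
generate_spore_stack <- function(n_bacteria, shape = c(24, 64, 64),
                                 voxel_dims = c(0.2, 0.1, 0.1),
                                 psf_sigma = 0, background = 10,
                                 signal = 200, poisson_noise = FALSE,
                                 gaussian_sd = 0, seed = NULL,
                                 max_tries = 200) {
  stopifnot(n_bacteria >= 0, length(shape) == 3L, all(shape >= 4),
            signal > background)
  if (!is.null(seed)) set.seed(seed)
  arr <- array(0, shape)
  centre <- (shape + 1) / 2
  semi <- (shape - 2) / 2  # ellipsoid semi-axes in voxels, 1-voxel margin
  # rod half-dimensions in voxels: ~2 um long, ~0.5 um wide
  rod_len_vox <- pmax(1, round(2 / voxel_dims))    # per axis if oriented along it
  rod_wid_vox <- pmax(1, round(0.5 / voxel_dims))
  placed <- 0L
  occupied <- array(FALSE, shape)
  while (placed < n_bacteria) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      axis <- sample(2:3, 1L)  # rods lie in the imaging plane (y or x)
      half <- rod_wid_vox
      half[axis] <- rod_len_vox[axis]
      half <- pmax(1, floor(half / 2))
      pos <- round(centre + (stats::runif(3) * 2 - 1) * (semi - half - 1))
      zr <- (pos[1] - half[1]):(pos[1] + half[1])
      yr <- (pos[2] - half[2]):(pos[2] + half[2])
      xr <- (pos[3] - half[3]):(pos[3] + half[3])
      if (any(zr < 1 | zr > shape[1]) || any(yr < 1 | yr > shape[2]) ||
          any(xr < 1 | xr > shape[3])) next
      # inside the ellipsoid? check rod corners
      corners <- expand.grid(z = range(zr), y = range(yr), x = range(xr))
      inside <- all(((corners$z - centre[1]) / semi[1])^2 +
                      ((corners$y - centre[2]) / semi[2])^2 +
                      ((corners$x - centre[3]) / semi[3])^2 <= 1)
      if (!inside) next
      if (any(occupied[zr, yr, xr])) next
      occupied[zr, yr, xr] <- TRUE
      arr[zr, yr, xr] <- signal
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(
        "overcrowded geometry: could not place bacterium %d of %d in %s voxels",
        placed + 1L, n_bacteria, paste(shape, collapse = "x")), call. = FALSE)
    placed <- placed + 1L
  }
  truth_voxels <- sum(arr > 0)
  arr <- arr + background
  if (psf_sigma > 0)
    arr <- gaussian_blur3d(arr, psf_sigma / voxel_dims)
  if (poisson_noise)
    arr <- array(stats::rpois(length(arr), lambda = pmax(arr, 0)), dim(arr))
  if (gaussian_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, gaussian_sd)
  arr[arr < 0] <- 0
  list(stack = voxel_stack(arr, voxel_dims), truth_voxels = truth_voxels)
}

# separable 3D Gaussian blur; sigma per axis in voxels
gaussian_blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    radius <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-radius:radius, sd = s)
    kern <- kern / sum(kern)
    arr <- apply_along(arr, axis, function(v) convolve_reflect(v, kern, radius))
  }
  arr
}

convolve_reflect <- function(v, kern, radius) {
  n <- length(v)
  idx <- c(rev(seq_len(min(radius, n))), seq_len(n),
           n + 1 - rev(seq_len(min(radius, n))))
  padded <- v[idx]
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(radius + 1):(radius + n)])
}

# apply a vector function along one axis of a 3D array, preserving shape
apply_along <- function(arr, axis, f) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- apply(m, 2L, f)
  a <- array(m, d[perm])
  aperm(a, order(perm))
}

#' Generate synthetic FACS intensities for a spore pool
#'
#' Emulates the flow-cytometric intensity readout: positive spores get
#' `baseline + intensity_per_load * load` with lognormal per-spore loads,
#' negative spores get autofluorescence around the baseline. True labels
#' are returned for gate-evaluation tests.
#'
#' @param pool A [spore_pool()] (counts should be modest; intensities are
#'   per spore).
#' @param lm A [load_model()].
#' @param seed Optional seed.
#' @return A data frame with columns `intensity`, `positive` (logical),
#'   `load` (um^3; 0 for negatives).
#' @export
generate_facs_intensities <- function(pool, lm = load_model(), seed = NULL) {
  stopifnot(inherits(pool, "spore_pool"), inherits(lm, "load_model"))
  if (!is.null(seed)) set.seed(seed)
  n_pos <- pool$n_pos; n_neg <- pool$n_neg
  loads <- if (n_pos > 0)
    stats::rlnorm(n_pos, meanlog = log(lm$median), sdlog = lm$sigma)
  else numeric(0)
  int_pos <- lm$baseline + lm$intensity_per_load * loads
  int_neg <- if (n_neg > 0)
    pmax(0, stats::rnorm(n_neg, lm$baseline, lm$baseline_sd))
  else numeric(0)
  data.frame(
    intensity = c(int_pos, int_neg),
    positive = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
    load = c(loads, numeric(n_neg))
  )
}
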
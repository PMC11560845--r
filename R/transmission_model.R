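#' Transmission model parameters
#'
#' Bundles the parameters of the discrete-generation recursion for the
#' bacteria-positive spore fraction of a fungal endosymbiosis propagated
#' without selection, plus the two operational thresholds of the
#' serial-passage design.
#'
#' One propagation round is: plate spores, let them germinate, let the
#' resulting mycelium sporulate, collect the spores. Bacteria-positive
#' spores germinate with probability `g`, bacteria-negative spores with
#' probability `e`, and a germling grown from a positive spore produces a
#' fraction `p0` of positive spores (transmission fidelity). All three are
#' probabilities in `[0, 1]`.
#'
#' `t_prop` is the wash-out threshold: with 100,000 spores plated per
#' round, a positive fraction below 1/100,000 means no positive spore is
#' expected on the next plate. `t_det` is the detection limit of the flow
#' cytometric measurement (1/1,000,000 when a million spores are
#' analysed).
#'
#' @param g Germination probability of bacteria-positive spores.
#' @param e Germination probability of bacteria-negative spores. Default
#'   0.69, the long-term average germination of negative spores observed
#'   across the selection experiment.
#' @param p0 Transmission fidelity: fraction of spores produced by a
#'   positive germling that are again positive.
#' @param t_prop Wash-out threshold on the positive fraction (default
#'   `1e-5`, i.e. 1/100,000 plated spores).
#' @param t_det Detection limit on the positive fraction (default `1e-6`,
#'   i.e. 1/1,000,000 analysed spores). Must satisfy `t_det <= t_prop`.
#'
#' @return An object of class `"transmission_params"`: a list with fields
#'   `g`, `e`, `p0`, `t_prop`, `t_det`.
#' @examples
#' transmission_params(g = 0.88, e = 0.69, p0 = 0.29)
#' @export
transmission_params <- function(g, e = 0.69, p0, t_prop = 1e-5, t_det = 1e-6) {
  for (nm in c("g", "e", "p0", "t_prop", "t_det")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single number in [0, 1], got %s",
                   nm, deparse(v)), call. = FALSE)
  }
  if (t_det > t_prop)
    stop("'t_det' must not exceed 't_prop'", call. = FALSE)
  structure(list(g = g, e = e, p0 = p0, t_prop = t_prop, t_det = t_det),
            class = "transmission_params")
}

#' @export
print.transmission_params <- function(x, ...) {
  cat("Transmission model parameters\n")
  cat(sprintf("  g  (germination, positive spores): %.4g\n", x$g))
  cat(sprintf("  e  (germination, negative spores): %.4g\n", x$e))
  cat(sprintf("  p0 (transmission fidelity):        %.4g\n", x$p0))
  cat(sprintf("  wash-out threshold: %.3g   detection limit: %.3g\n",
              x$t_prop, x$t_det))
  invisible(x)
}

as_transmission_params <- function(params) {
  if (inherits(params, "transmission_params")) return(params)
  stop("'params' must be a 'transmission_params' object; see transmission_params()",
       call. = FALSE)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be numeric in [0, 1]", name), call. = FALSE)
  x
}

#' Fitness index of an endosymbiosis
#'
#' The fitness index is the product of the positive fraction `p` (fraction
#' of spores carrying the endosymbiont) and the germination success `g` of
#' those positive spores: the expected fraction of plated spores that
#' yield a bacteria-carrying germling, i.e. viable offspring with the
#' endosymbiont.
#'
#' @param p Positive fraction(s), in `[0, 1]`.
#' @param g Germination success(es) of positive spores, in `[0, 1]`.
#' @return `p * g`, vectorised with recycling; always in `[0, 1]`.
#' @examples
#' fitness_index(0.0001, 0.063)  # ancestral pairing: 6.3e-06 (0.0006 %)
#' fitness_index(0.29, 0.88)     # evolved pairing:   0.2552  (25.5 %)
#' @export
fitness_index <- function(p, g) {
  check_fraction(p, "p")
  check_fraction(g, "g")
  p * g
}

#' One round of the positive-fraction recursion
#'
#' Advances the bacteria-positive spore fraction by one propagation round
#' without selection:
#' \deqn{p_x = \frac{p_{x-1}\, g\, p_0}{p_{x-1}\, g + (1 - p_{x-1})\, e}}
#' The denominator is the fraction of plated spores that germinate; the
#' numerator is the fraction of plated spores that germinate, carry
#' bacteria, and pass them on.
#'
#' When the denominator is exactly zero no spore germinates at all: there
#' is no next generation. The function then returns 0 and sets the
#' `"extinct"` attribute, rather than raising an error.
#'
#' @param p_prev Positive fraction entering the round, in `[0, 1]`.
#'   Vectorised.
#' @param params A [transmission_params()] object.
#' @return Numeric vector of next-round positive fractions in `[0, 1]`,
#'   with a logical attribute `"extinct"` marking zero-denominator
#'   entries.
#' @examples
#' pars <- transmission_params(g = 0.88, e = 0.69, p0 = 0.29)
#' transmission_step(0.29, pars)
#' @export
transmission_step <- function(p_prev, params) {
  params <- as_transmission_params(params)
  check_fraction(p_prev, "p_prev")
  denom <- p_prev * params$g + (1 - p_prev) * params$e
  extinct <- denom == 0
  p_next <- ifelse(extinct, 0, (p_prev * params$g * params$p0) / denom)
  # guard rounding excursions just above 1
  p_next <- pmin(pmax(p_next, 0), 1)
  structure(p_next, extinct = extinct)
}

#' Predicted positive-fraction trajectory
#'
#' Iterates [transmission_step()] from an initial positive fraction,
#' flagging each round against the wash-out threshold and the detection
#' limit (strict `<` comparisons: a fraction exactly at a threshold counts
#' as not below it).
#'
#' @param p_init Initial positive fraction (round 0), in `[0, 1]`.
#' @param params A [transmission_params()] object.
#' @param n_rounds Number of rounds to iterate (non-negative integer).
#' @return A data frame of class `"transmission_trajectory"` with columns
#'   `round` (0..n_rounds), `p`, `below_prop`, `below_det`, `extinct`.
#' @examples
#' pars <- transmission_params(g = 0.88, e = 0.69, p0 = 0.29)
#' iterate_trajectory(0.29, pars, n_rounds = 5)
#' @export
iterate_trajectory <- function(p_init, params, n_rounds) {
  params <- as_transmission_params(params)
  check_fraction(p_init, "p_init")
  stopifnot(length(p_init) == 1L)
  if (!is.numeric(n_rounds) || length(n_rounds) != 1L || is.na(n_rounds) ||
      n_rounds < 0 || n_rounds != floor(n_rounds))
    stop("'n_rounds' must be a single non-negative integer", call. = FALSE)
  n_rounds <- as.integer(n_rounds)
  p <- numeric(n_rounds + 1L)
  ext <- logical(n_rounds + 1L)
  p[1L] <- p_init
  if (n_rounds > 0L) {
    for (x in seq_len(n_rounds)) {
      s <- transmission_step(p[x], params)
      p[x + 1L] <- as.numeric(s)
      ext[x + 1L] <- attr(s, "extinct")
    }
  }
  out <- data.frame(
    round      = 0:n_rounds,
    p          = p,
    below_prop = p < params$t_prop,
    below_det  = p < params$t_det,
    extinct    = ext
  )
  class(out) <- c("transmission_trajectory", "data.frame")
  out
}

#' Fixed points of the recursion
#'
#' Solves `transmission_step(p) = p`. The origin `p = 0` (endosymbiont
#' lost) is always fixed. When `g != e` there is an additional candidate
#' \eqn{p^* = (g p_0 - e)/(g - e)}, kept when it lies in `(0, 1]`. When
#' `g = e` the map reduces to `p -> p * p0`, so nonzero fixed points exist
#' only for `p0 = 1`, in which case every `p` is fixed (degenerate case).
#'
#' @param params A [transmission_params()] object.
#' @return A list of class `"transmission_fixed_points"` with `points`
#'   (numeric, sorted, always containing 0) and `degenerate_all_fixed`
#'   (logical: `TRUE` when every `p` in `[0, 1]` is fixed).
#' @examples
#' fixed_points(transmission_params(g = 1, e = 0.5, p0 = 0.75))  # 0 and 0.5
#' @export
fixed_points <- function(params) {
  params <- as_transmission_params(params)
  g <- params$g; e <- params$e; p0 <- params$p0
  pts <- 0
  degenerate <- FALSE
  if (g == e) {
    # g = e = 0 means nothing germinates: only extinction is fixed
    if (p0 == 1 && g > 0) degenerate <- TRUE  # p -> p: everything fixed
  } else {
    p_star <- (g * p0 - e) / (g - e)
    if (p_star > 0 && p_star <= 1) pts <- c(pts, p_star)
  }
  structure(list(points = sort(pts), degenerate_all_fixed = degenerate),
            class = "transmission_fixed_points")
}

#' @export
print.transmission_fixed_points <- function(x, ...) {
  if (x$degenerate_all_fixed)
    cat("Degenerate map: every positive fraction in [0, 1] is fixed\n")
  else
    cat("Fixed points:", paste(signif(x$points, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Per-round decline factor of a rare endosymbiont
#'
#' In the rare-symbiont limit (`p -> 0`) the recursion is linear:
#' `p_x ~ lambda * p_(x-1)` with `lambda = g * p0 / e`. A value below 1
#' means the positive fraction is diluted out geometrically; above 1 the
#' endosymbiosis invades.
#'
#' @param params A [transmission_params()] object with `e > 0`.
#' @return The decline factor `g * p0 / e` (non-negative).
#' @examples
#' decline_factor(transmission_params(g = 0.88, e = 0.69, p0 = 0.29))
#' @export
decline_factor <- function(params) {
  params <- as_transmission_params(params)
  if (params$e == 0)
    stop("decline factor is undefined for e = 0 (no negative spore germinates)",
         call. = FALSE)
  params$g * params$p0 / params$e
}

#' Wash-out round of the positive fraction
#'
#' Finds the first round at which the predicted positive fraction falls
#' strictly below `threshold`, or reports `"persists"` when it never does.
#' Termination is decided analytically from the map's limit rather than by
#' an iteration cap: the recursion is a Moebius map, so the trajectory is
#' monotone and converges to 0 or to the attracting nonzero fixed point.
#'
#' @param p_init Initial positive fraction (round 0).
#' @param params A [transmission_params()] object.
#' @param threshold Wash-out threshold in `(0, 1]`; defaults to
#'   `params$t_prop`.
#' @return The smallest round index `x >= 0` with `p_x < threshold`
#'   (integer), or the character string `"persists"`.
#' @examples
#' pars <- transmission_params(g = 0.88, e = 0.69, p0 = 0.29)
#' washout_round(0.29, pars)           # 11
#' washout_round(0.5, transmission_params(g = 1, e = 0.5, p0 = 0.75))
#' @export
washout_round <- function(p_init, params, threshold = params$t_prop) {
  params <- as_transmission_params(params)
  check_fraction(p_init, "p_init")
  stopifnot(length(p_init) == 1L)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single number in (0, 1]", call. = FALSE)
  if (p_init < threshold) return(0L)

  limit <- trajectory_limit(p_init, params)
  x <- 0L
  p <- p_init
  repeat {
    s <- transmission_step(p, params)
    p_next <- as.numeric(s)
    x <- x + 1L
    if (p_next < threshold) return(x)
    # monotone convergence: once at (or numerically at) a limit that is
    # >= threshold, the fraction can never cross below it
    if (limit >= threshold &&
        abs(p_next - limit) <= 1e-14 + 1e-12 * limit) return("persists")
    if (p_next == p) return("persists")  # exactly fixed (incl. degenerate map)
    p <- p_next
  }
}

# Limit of the trajectory started at p_init: 0, p_init (degenerate all-fixed
# map) or the attracting interior fixed point.
trajectory_limit <- function(p_init, params) {
  if (p_init == 0) return(0)
  fp <- fixed_points(params)
  if (fp$degenerate_all_fixed) return(p_init)
  nonzero <- fp$points[fp$points > 0]
  if (length(nonzero) == 0L) return(0)
  p_star <- nonzero[[1L]]
  # interior fixed point exists iff lambda > 1, and is then attracting
  # from every p_init > 0
  lambda <- if (params$e > 0) params$g * params$p0 / params$e else Inf
  if (lambda > 1) p_star else 0
}
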
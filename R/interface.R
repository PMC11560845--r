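measurement_columns <- c(
  "line_id", "round", "facs_analyzed", "facs_positive",
  "wells_sorted_pos", "germinated_day1_pos", "germinated_day2_pos",
  "wells_sorted_neg", "germinated_day1_neg", "germinated_day2_neg")

allele_columns <- c("mutation_id", "round", "frequency",
                    "present_in_ancestor")

# Validate a measurement data frame; report offending rows by number.
# Fraction-valued columns are not part of this schema: counts only.
validate_measurements <- function(m) {
  if (!is.data.frame(m))
    stop("measurements must be a data frame", call. = FALSE)
  missing_cols <- setdiff(measurement_columns, names(m))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
  }
  with_na_ok <- function(x, f) !is.na(x) & f(x)
  bad(with_na_ok(m$facs_positive, function(x) x > m$facs_analyzed),
      "facs_positive exceeds facs_analyzed")
  bad(with_na_ok(m$germinated_day1_pos,
                 function(x) x > m$germinated_day2_pos),
      "germinated_day1_pos exceeds germinated_day2_pos")
  bad(with_na_ok(m$germinated_day2_pos,
                 function(x) x > m$wells_sorted_pos),
      "germinated_day2_pos exceeds wells_sorted_pos")
  bad(with_na_ok(m$germinated_day1_neg,
                 function(x) x > m$germinated_day2_neg),
      "germinated_day1_neg exceeds germinated_day2_neg")
  bad(with_na_ok(m$germinated_day2_neg,
                 function(x) x > m$wells_sorted_neg),
      "germinated_day2_neg exceeds wells_sorted_neg")
  count_cols <- setdiff(measurement_columns, "line_id")
  for (cc in count_cols)
    bad(with_na_ok(m[[cc]], function(x) x < 0), paste("negative", cc))
  m
}

#' Read / write a round-measurement table
#'
#' CSV schema for round-by-round observations of the selection
#' experiment, one row per line and round: `line_id`, `round`,
#' `facs_analyzed`, `facs_positive`, `wells_sorted_pos`,
#' `germinated_day1_pos`, `germinated_day2_pos`, `wells_sorted_neg`,
#' `germinated_day1_neg`, `germinated_day2_neg`.
#'
#' Columns suffixed `_pct` are percent-valued and converted to fractions
#' exactly once on read (the suffix is dropped); internally everything is
#' a fraction or a count. Validation failures name the offending row.
#'
#' @param path CSV file path.
#' @param measurements A data frame in the schema above.
#' @return `read_measurement_table` returns a validated data frame;
#'   `write_measurement_table` returns `path` invisibly.
#' @export
read_measurement_table <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- convert_pct_columns(m)
  validate_measurements(m)
}

#' @rdname read_measurement_table
#' @export
write_measurement_table <- function(measurements, path) {
  m <- validate_measurements(measurements)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

convert_pct_columns <- function(df) {
  pct <- grep("_pct$", names(df), value = TRUE)
  for (cc in pct) {
    target <- sub("_pct$", "", cc)
    if (target %in% names(df))
      stop(sprintf("both '%s' and '%s' present: percent conversion would be ambiguous",
                   cc, target), call. = FALSE)
    df[[target]] <- as.numeric(df[[cc]]) / 100
    df[[cc]] <- NULL
  }
  df
}

#' Read / write an allele-frequency table
#'
#' CSV schema for mutation trajectories: `mutation_id`, `round`,
#' `frequency` (fraction; `frequency_pct` accepted and converted),
#' `present_in_ancestor` (logical).
#'
#' @param path CSV file path.
#' @param alleles A data frame in the schema above.
#' @return A validated data frame / `path` invisibly.
#' @export
read_allele_table <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  a <- convert_pct_columns(a)
  missing_cols <- setdiff(allele_columns, names(a))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  a$present_in_ancestor <- as.logical(a$present_in_ancestor)
  if (any(a$frequency < 0 | a$frequency > 1, na.rm = TRUE))
    stop("frequencies must be in [0, 1] after percent conversion",
         call. = FALSE)
  a
}

#' @rdname read_allele_table
#' @export
write_allele_table <- function(alleles, path) {
  utils::write.csv(alleles[, allele_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

command_schemas <- list(
  predict  = list(required = c("g", "p0", "p_init", "rounds"),
                  optional = c("e", "threshold", "t_det", "out"),
                  stochastic = FALSE),
  washout  = list(required = c("g", "p0", "p_init"),
                  optional = c("e", "threshold", "t_det", "out"),
                  stochastic = FALSE),
  simulate = list(required = c("g", "p0", "p_init", "rounds", "seed"),
                  optional = c("e", "n_plated", "n_analyzed",
                               "spores_per_germling", "selection_mode",
                               "sort_purity", "out"),
                  stochastic = TRUE),
  fit      = list(required = c("measurements"),
                  optional = c("fallback_e", "rounds", "out"),
                  stochastic = FALSE),
  synth    = list(required = c("g", "p0", "seed", "out"),
                  optional = c("e", "n_lines", "rounds", "round1_spores",
                               "n_plated", "n_analyzed"),
                  stochastic = TRUE),
  loadquant = list(required = c("stacks"),
                   optional = c("threshold", "connectivity", "out"),
                   stochastic = FALSE),
  report   = list(required = c("measurements"),
                  optional = c("out"),
                  stochastic = FALSE)
)

#' Validated run configuration
#'
#' Builds and validates the configuration for one [run_command()] call.
#' Unknown keys are rejected outright (the design constants 100,000 /
#' 1,000,000 / 1e-5 / 1e-6 are too easy to transpose for silent typo
#' tolerance), and every stochastic command must carry an explicit seed.
#'
#' @param command One of `predict`, `washout`, `simulate`, `fit`,
#'   `synth`, `loadquant`, `report`.
#' @param ... Named configuration entries (see the schemas in the CLI
#'   documentation).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(command, ...) {
  if (!command %in% names(command_schemas))
    stop("unknown command '", command, "'; available: ",
         paste(names(command_schemas), collapse = ", "), call. = FALSE)
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all configuration entries must be named", call. = FALSE)
  schema <- command_schemas[[command]]
  known <- c(schema$required, schema$optional)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s) for '", command, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_keys <- setdiff(schema$required, names(cfg))
  if (length(missing_keys))
    stop("missing required key(s) for '", command, "': ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  if (schema$stochastic && (is.null(cfg$seed) || is.na(cfg$seed)))
    stop("stochastic command '", command, "' requires an explicit seed",
         call. = FALSE)
  structure(c(list(command = command), cfg), class = "run_config")
}

#' Read a run configuration file
#'
#' JSON is the documented configuration format; YAML is accepted when the
#' yaml package is installed. The file must contain a `command` entry and
#' the keys of that command's schema.
#'
#' @param path Path to a `.json` (or `.yaml`/`.yml`) configuration file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config given but the yaml package is not installed; use JSON",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$command))
    stop("configuration must name a 'command'", call. = FALSE)
  do.call(run_config, c(list(command = cfg$command),
                        cfg[setdiff(names(cfg), "command")]))
}

#' Execute a pipeline command
#'
#' Dispatches one validated configuration to its module: `predict` runs
#' the deterministic recursion and wash-out analysis, `washout` only the
#' latter, `simulate` the stochastic serial-passage simulator, `fit`
#' parameter estimation (plus model-fit error when a predicted trajectory
#' can be formed), `synth` the synthetic-data generator, `loadquant`
#' voxel-based load quantification over a directory of stacks, and
#' `report` the fitness table. When `out` is set, results are written
#' there as CSV plus a JSON manifest recording the command, seed, config
#' hash and package version.
#'
#' @param config A [run_config()] (or a command name plus `...` entries).
#' @param ... Passed to [run_config()] when `config` is a character
#'   command name.
#' @return A list with `status` (0 on success), `result` (command-
#'   specific object), and `files` (paths written, possibly empty).
#' @examples
#' run_command("predict", g = 0.88, e = 0.69, p0 = 0.29,
#'             p_init = 0.29, rounds = 5)$result
#' @export
run_command <- function(config, ...) {
  if (is.character(config)) config <- run_config(config, ...)
  stopifnot(inherits(config, "run_config"))
  result <- switch(config$command,
    predict = cmd_predict(config),
    washout = cmd_washout(config),
    simulate = cmd_simulate(config),
    fit = cmd_fit(config),
    synth = cmd_synth(config),
    loadquant = cmd_loadquant(config),
    report = cmd_report(config)
  )
  files <- character(0)
  if (!is.null(config$out))
    files <- write_outputs(config, result)
  list(status = 0L, result = result, files = files)
}

config_params <- function(config) {
  transmission_params(
    g = config$g, e = config$e %||% 0.69, p0 = config$p0,
    t_prop = config$threshold %||% 1e-5, t_det = config$t_det %||% 1e-6)
}

cmd_predict <- function(config) {
  params <- config_params(config)
  traj <- iterate_trajectory(config$p_init, params, config$rounds)
  list(trajectory = traj,
       washout = washout_round(config$p_init, params),
       decline_factor = if (params$e > 0) decline_factor(params) else NA_real_,
       fixed_points = fixed_points(params)$points)
}

cmd_washout <- function(config) {
  params <- config_params(config)
  list(washout = washout_round(config$p_init, params))
}

cmd_simulate <- function(config) {
  params <- config_params(config)
  cfg <- sim_config(
    n_plated = config$n_plated %||% 1e5,
    n_analyzed = config$n_analyzed %||% 1e6,
    spores_per_germling = config$spores_per_germling %||% 1e4,
    selection_mode = config$selection_mode %||% "positive_sort",
    sort_purity = config$sort_purity %||% 1,
    seed = config$seed)
  list(records = run_passage_experiment(cfg, params, config$p_init,
                                        config$rounds))
}

cmd_fit <- function(config) {
  m <- read_measurement_table(config$measurements)
  round0 <- m[which.min(m$round), , drop = FALSE]
  params <- estimate_transmission_params(round0,
                                         fallback_e = config$fallback_e %||% 0.69)
  rounds <- config$rounds %||% max(m$round)
  traj <- iterate_trajectory(params$p0, params, rounds)
  observed <- data.frame(round = m$round,
                         p = m$facs_positive / m$facs_analyzed,
                         below_det = m$facs_positive == 0)
  fit_err <- tryCatch(model_fit_error(observed, traj), error = function(e) NA_real_)
  list(params = params, predicted = traj, model_fit_error = fit_err)
}

cmd_synth <- function(config) {
  params <- transmission_params(g = config$g, e = config$e %||% 0.69,
                                p0 = config$p0)
  truth <- truth_config(params,
                        n_lines = config$n_lines %||% 10,
                        n_rounds = config$rounds %||% 10,
                        round1_spores = config$round1_spores %||% 300,
                        n_plated = config$n_plated %||% 1e5,
                        n_analyzed = config$n_analyzed %||% 1e6,
                        seed = config$seed)
  generate_experiment(truth)
}

cmd_loadquant <- function(config) {
  paths <- if (dir.exists(config$stacks))
    list.files(config$stacks, pattern = "\\.txt$", full.names = TRUE)
  else config$stacks
  if (length(paths) == 0L)
    stop("no stack files found under ", config$stacks, call. = FALSE)
  rows <- lapply(paths, function(p) {
    st <- read_voxel_stack(p)
    thr <- config$threshold %||% otsu_threshold(st)
    lr <- quantify_load(st, thr, connectivity = config$connectivity %||% 26)
    data.frame(spore_id = sub("\\.txt$", "", basename(p)),
               n_voxels = lr$n_voxels, volume_um3 = lr$volume,
               threshold_used = lr$threshold_used,
               n_components = lr$n_components)
  })
  res <- do.call(rbind, rows)
  res$bin <- as.character(classify_intensity_bins_safe(res$volume_um3))
  list(loads = res)
}

classify_intensity_bins_safe <- function(x) {
  tryCatch(classify_intensity_bins(x),
           error = function(e) rep(NA_character_, length(x)))
}

cmd_report <- function(config) {
  m <- read_measurement_table(config$measurements)
  list(fitness = fitness_table(m))
}

write_outputs <- function(config, result) {
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (is.data.frame(obj)) emit_csv(obj, paste0(nm, ".csv"))
  }
  if (config$command == "synth") {
    emit_csv(result$measurements, "measurements.csv")
    emit_csv(result$alleles, "alleles.csv")
    manifest_path <- file.path(out_dir, "truth_manifest.json")
    jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    files <- c(files, manifest_path)
  }
  cfg_for_hash <- unclass(config)
  run_manifest <- list(
    command = config$command,
    seed = config$seed,
    config = cfg_for_hash,
    config_hash = digest::digest(cfg_for_hash, algo = "sha256"),
    package_version = as.character(utils::packageVersion("endosim"))
  )
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unique(c(files, mp))
}
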
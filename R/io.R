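#' Read a scenario configuration file
#'
#' Loads a YAML or JSON scenario description into a validated
#' `scenario_config`. The file must carry a `schema_version`, a `scenario`
#' block with an explicit `units` key (`percent` or `proportion`; percent
#' values are divided by 100 on load), a `question`
#' (`disease_probability_threshold`, `outcome_risk_threshold`, `decide`, or
#' `sweep`), and optionally a `sweep` block and a `rounding_mode` (`exact`,
#' the default, or `paper`). All violations found are reported together in
#' one validation error, not one at a time.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `scenario_config`: list with `schema_version`, `scenario` (an
#'   [ebm_scenario()]), `question`, `rounding_mode`, `sweep` (or `NULL`),
#'   and `estimate` (for `decide` questions).
#' @examples
#' cfg <- read_scenario(system.file("extdata", "einstein.yaml",
#'                                  package = "treatthresh"))
#' scenario_threshold(cfg$scenario, "outcome_risk")
#' @export
read_scenario <- function(path) {
  if (!file.exists(path))
    stop(validation_error(paste0("config file not found: ", path)))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(validation_error(paste0("cannot parse ", path, ": ",
                                 conditionMessage(e)))))
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (is.null(raw$schema_version)) note("missing schema_version")
  question <- raw$question
  questions <- c("disease_probability_threshold", "outcome_risk_threshold",
                 "decide", "sweep")
  if (is.null(question) || !question %in% questions)
    note(paste0("question must be one of: ", paste(questions, collapse = ", ")))
  rounding_mode <- raw$rounding_mode %||% "exact"
  if (!rounding_mode %in% c("exact", "paper"))
    note("rounding_mode must be 'exact' or 'paper'")

  sc <- raw$scenario
  scale <- 1
  if (is.null(sc) || !is.list(sc)) {
    note("missing scenario block")
  } else {
    units <- sc$units
    if (is.null(units) || !units %in% c("percent", "proportion")) {
      note("scenario$units is mandatory and must be 'percent' or 'proportion'")
    } else if (units == "percent") {
      scale <- 1 / 100
    }
    if (is.null(sc$baseline_risk)) note("missing scenario$baseline_risk")
    if (is.null(sc$treated_risk) && is.null(sc$rrr))
      note("scenario needs treated_risk or rrr")
    if (is.null(sc$harm_rx)) note("missing scenario$harm_rx")
    num_fields <- c("baseline_risk", "treated_risk", "rrr", "harm_rx",
                    "rv_harm", "disease_prob")
    for (f in num_fields) {
      v <- sc[[f]]
      if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || is.na(v)))
        note(paste0("scenario$", f, " must be a single number"))
    }
    if (!is.null(sc$regime) && !sc$regime %in% c("independent", "dependent"))
      note("scenario$regime must be 'independent' or 'dependent'")
  }
  if (identical(raw$question, "decide") &&
      (is.null(raw$estimate) || !is.numeric(raw$estimate)))
    note("question 'decide' requires a numeric top-level estimate")

  scenario <- NULL
  if (length(problems) == 0L) {
    pct <- function(v) if (is.null(v)) NULL else v * scale
    scenario <- tryCatch(
      ebm_scenario(
        baseline_risk = sc$baseline_risk * scale,
        treated_risk = pct(sc$treated_risk),
        rrr = sc$rrr,  # RRR is a ratio, never rescaled by units
        harm_rx = sc$harm_rx * scale,
        rv_harm = sc$rv_harm %||% 1,
        disease_prob = pct(sc$disease_prob),
        regime = sc$regime %||% "independent"),
      error = function(e) {
        note(conditionMessage(e))
        NULL
      })
  }
  if (length(problems) > 0L)
    stop(validation_error(paste0(
      "invalid scenario config ", path, ":\n  - ",
      paste(problems, collapse = "\n  - "))))

  structure(
    list(schema_version = as.character(raw$schema_version),
         scenario = scenario, question = question,
         rounding_mode = rounding_mode, sweep = raw$sweep,
         estimate = if (!is.null(raw$estimate)) raw$estimate * scale else NULL),
    class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration back to YAML
#'
#' Dumps a `scenario_config` in proportion units; loading the dumped file
#' reproduces the original configuration (load, dump, load is the
#' identity on the validated fields).
#'
#' @param config A `scenario_config` from [read_scenario()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  s <- config$scenario
  out <- list(
    schema_version = config$schema_version,
    question = config$question,
    rounding_mode = config$rounding_mode,
    scenario = list(
      units = "proportion",
      baseline_risk = s$baseline_risk,
      treated_risk = s$treated_risk,
      harm_rx = s$harm_rx,
      rv_harm = s$rv_harm,
      regime = s$regime))
  if (!is.null(s$disease_prob)) out$scenario$disease_prob <- s$disease_prob
  if (!is.null(config$sweep)) out$sweep <- config$sweep
  if (!is.null(config$estimate)) out$estimate <- config$estimate
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

validation_error <- function(msg) {
  structure(class = c("treatthresh_validation_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Write a threshold or sweep result to disk
#'
#' Threshold results serialise to JSON embedding the echoed inputs, the
#' stored (unrounded) value, a percent display string, the decision rule
#' flags, and the package version. Sweep results serialise to the long CSV
#' schema of [write_sweep_csv()] (or to JSON row-wise).
#'
#' @param result A [threshold_result()] or `sweep_result`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @param rounding_mode Recorded in JSON output for provenance.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "csv"),
                         rounding_mode = "exact") {
  format <- match.arg(format)
  if (inherits(result, "threshold_result")) {
    if (format == "csv")
      stop("threshold results serialise to JSON; CSV is for sweeps",
           call. = FALSE)
    digits <- if (result$kind == "outcome_risk") 1 else 0
    payload <- list(
      kind = result$kind,
      value = result$value,
      display = if (is.finite(result$value)) format_percent(result$value, digits)
                else "never treat",
      valid = result$valid,
      never_treat = result$never_treat,
      note = result$note,
      inputs = result$inputs,
      rounding_mode = rounding_mode,
      package_version = as.character(utils::packageVersion("treatthresh")))
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null")
      TRUE
    }, error = function(e) {
      stop("failed writing ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  } else if (inherits(result, "sweep_result")) {
    if (format == "csv") write_sweep_csv(result, path)
    else jsonlite::write_json(as.data.frame(result), path, digits = NA)
  } else {
    stop("result must be a threshold_result or sweep_result", call. = FALSE)
  }
  invisible(path)
}

#' Generate random valid scenarios for property testing
#'
#' Draws `n` scenarios with parameters spanning the clinically plausible
#' ranges (baseline risk 0.001--0.5, RRR 0.05--0.99, harm risk 0--0.2,
#' preference weight 0.02--1.5, regime sampled uniformly), rejecting any
#' draw whose terminal utilities would leave the 0--1 scale. Deterministic
#' given the seed; the caller's RNG state is untouched.
#'
#' @param n Number of scenarios, at least 1.
#' @param seed Integer RNG seed.
#' @return A list of [ebm_scenario()] objects.
#' @examples
#' sc <- generate_scenarios(5, seed = 7)
#' sapply(sc, function(s) outcome_threshold(s$rv_harm, s$harm_rx, s$rrr)$value)
#' @export
generate_scenarios <- function(n, seed) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == as.integer(n))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(seed, {
    out <- vector("list", n)
    i <- 1L
    while (i <= n) {
      s <- try(ebm_scenario(
        baseline_risk = stats::runif(1, 0.001, 0.5),
        rrr = stats::runif(1, 0.05, 0.99),
        harm_rx = stats::runif(1, 0, 0.2),
        rv_harm = stats::runif(1, 0.02, 1.5),
        disease_prob = stats::runif(1),
        regime = sample(c("independent", "dependent"), 1)),
        silent = TRUE)
      valid <- !inherits(s, "try-error") &&
        !inherits(try(utilities_from_ebm(s), silent = TRUE), "try-error")
      if (valid) {
        out[[i]] <- s
        i <- i + 1L
      }
    }
    out
  })
}
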
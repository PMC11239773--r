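#' True coefficients of the data-generating linear probability model
#'
#' The generator draws each individual's binary booster-vaccination outcome
#' from a Bernoulli distribution whose success probability is linear in the
#' covariates (a linear probability model), so every coefficient is a risk
#' difference in probability units:
#'
#' \deqn{p = \beta_0 + \beta_{trt} A + \beta_{urban} Z_1 + \beta_{race} Z_2 +
#'   \beta_{region} R + \beta_{trt:urban} A Z_1 + \beta_{trt:race} A Z_2}
#'
#' Defaults are the "all effects on" values used throughout the simulation
#' study: a 14 percentage-point intervention effect, 3 points for
#' urban/suburban location, 1 point for self-reported race, a 10-point
#' intervention-by-urban interaction and a 15-point intervention-by-race
#' interaction. The baseline probability defaults to 0.30 (consistent with a
#' trial-eligibility cap of 60% baseline vaccination) and the region effect to
#' 0; both are configurable. Scenario flags zero out individual effects via
#' [build_coefficients()].
#'
#' @param beta0 Baseline probability of the outcome (control arm, rural,
#'   race = 0, region = 0).
#' @param beta_trt Intervention main effect (risk difference).
#' @param beta_urban Urban/suburban main effect.
#' @param beta_race Self-reported race main effect.
#' @param beta_region Region main effect (region is always retained as an
#'   adjustment covariate because it is a randomization stratum).
#' @param beta_trt_urban Intervention-by-urban interaction (HTE by urban
#'   status).
#' @param beta_trt_race Intervention-by-race interaction (HTE by race).
#' @param check If `TRUE` (default), fail unless every implied probability on
#'   the binary covariate support lies in \[0, 1\].
#'
#' @return A named numeric vector of class `crt_coefs`.
#' @seealso [validate_support()], [build_coefficients()]
#' @examples
#' true_coefficients()
#' true_coefficients(beta0 = 0.2, beta_trt_race = 0)
#' @export
true_coefficients <- function(beta0 = 0.30,
                              beta_trt = 0.14,
                              beta_urban = 0.03,
                              beta_race = 0.01,
                              beta_region = 0,
                              beta_trt_urban = 0.10,
                              beta_trt_race = 0.15,
                              check = TRUE) {
  coefs <- c(
    beta0 = beta0, beta_trt = beta_trt, beta_urban = beta_urban,
    beta_race = beta_race, beta_region = beta_region,
    beta_trt_urban = beta_trt_urban, beta_trt_race = beta_trt_race
  )
  if (anyNA(coefs) || !is.numeric(coefs)) {
    abort("all coefficients must be non-missing numbers")
  }
  class(coefs) <- c("crt_coefs", "numeric")
  if (check) {
    bad <- validate_support(coefs)
    if (nrow(bad) > 0) {
      abort(c(
        "implied outcome probabilities fall outside [0, 1]",
        "x" = sprintf(
          "%d of 16 covariate patterns violated; first: arm=%d urban=%d race=%d region=%d -> p=%.3f",
          nrow(bad), bad$arm[1], bad$urban[1], bad$race[1], bad$region[1],
          bad$probability[1]
        )
      ))
    }
  }
  coefs
}

#' Check the linear probability model on its covariate support
#'
#' Enumerates all 16 binary covariate patterns (arm, urban, race, region) and
#' returns those whose implied outcome probability lies outside \[0, 1\]. The
#' generator draws Bernoulli outcomes directly from the linear predictor, so a
#' coefficient set is usable only when this check returns zero rows.
#'
#' @param coefs A `crt_coefs` vector (see [true_coefficients()]).
#' @return A tibble with columns `arm`, `urban`, `race`, `region`,
#'   `probability`, one row per violated pattern; zero rows when valid.
#' @examples
#' validate_support(true_coefficients())                    # empty
#' validate_support(true_coefficients(beta0 = 0.9, check = FALSE))
#' @export
validate_support <- function(coefs) {
  grid <- tidyr::expand_grid(
    arm = 0:1, urban = 0:1, race = 0:1, region = 0:1
  )
  p <- linear_predictor(grid, coefs)
  grid$probability <- p
  grid[p < 0 | p > 1, , drop = FALSE]
}

# linear predictor of the generating model on a covariate table
linear_predictor <- function(data, coefs) {
  coefs[["beta0"]] +
    coefs[["beta_trt"]] * data$arm +
    coefs[["beta_urban"]] * data$urban +
    coefs[["beta_race"]] * data$race +
    coefs[["beta_region"]] * data$region +
    coefs[["beta_trt_urban"]] * data$arm * data$urban +
    coefs[["beta_trt_race"]] * data$arm * data$race
}

#' The nine named data-generating scenarios
#'
#' Each scenario toggles four features of the generating model: an urban main
#' effect, a race main effect, HTE by urban status, and HTE by race. Scenario
#' 1 has no subgroup effects at all, scenario 6 is the simplest scenario with
#' HTE by self-reported race (race main effect plus race HTE), and scenario 9
#' turns everything on. The intervention main effect is present in every
#' scenario.
#'
#' @return A tibble with columns `scenario_id`, `urban_main`, `race_main`,
#'   `hte_urban`, `hte_race`.
#' @examples
#' scenario_table()
#' @export
scenario_table <- function() {
  tibble(
    scenario_id = 1:9,
    urban_main = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    race_main  = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    hte_urban  = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    hte_race   = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

#' Specify a data-generating scenario
#'
#' Either pick one of the nine named scenarios by id (see [scenario_table()])
#' or pass `scenario = "custom"` and set the four effect flags directly. The
#' three realism-extension switches — cluster-level heterogeneity in the urban
#' distribution, cluster-level heterogeneity in race prevalence, and a
#' fraction of participants already boosted at baseline — are off by default
#' and can be combined with any scenario.
#'
#' @param scenario Integer 1–9, or `"custom"`.
#' @param urban_main,race_main,hte_urban,hte_race Effect flags; ignored unless
#'   `scenario = "custom"`, where they must all be supplied.
#' @param urban_heterogeneity If `TRUE`, each cluster's urban flag is an
#'   independent Bernoulli draw instead of a fixed balanced composition.
#' @param race_heterogeneity If `TRUE`, each cluster draws its own race
#'   prevalence from a Beta distribution before sampling individuals.
#' @param baseline_boosted_fraction Proportion in \[0, 1) of individuals
#'   flagged as already boosted at baseline (their outcome is forced to 1).
#' @return A list of class `crt_scenario`.
#' @examples
#' scenario_spec(6)
#' scenario_spec("custom", urban_main = TRUE, race_main = FALSE,
#'               hte_urban = TRUE, hte_race = FALSE)
#' @export
scenario_spec <- function(scenario = 1,
                          urban_main = NULL, race_main = NULL,
                          hte_urban = NULL, hte_race = NULL,
                          urban_heterogeneity = FALSE,
                          race_heterogeneity = FALSE,
                          baseline_boosted_fraction = 0) {
  if (baseline_boosted_fraction < 0 || baseline_boosted_fraction >= 1) {
    abort("`baseline_boosted_fraction` must lie in [0, 1)")
  }
  if (identical(scenario, "custom")) {
    flags <- list(
      urban_main = urban_main, race_main = race_main,
      hte_urban = hte_urban, hte_race = hte_race
    )
    if (any(vapply(flags, is.null, logical(1)))) {
      abort("all four effect flags must be supplied when scenario = \"custom\"")
    }
    flags <- lapply(flags, isTRUE)
    scenario_id <- "custom"
  } else {
    if (!is.numeric(scenario) || length(scenario) != 1 ||
        !scenario %in% 1:9) {
      abort("`scenario` must be an integer 1-9 or \"custom\"")
    }
    row <- scenario_table()[scenario_table()$scenario_id == scenario, ]
    flags <- list(
      urban_main = row$urban_main, race_main = row$race_main,
      hte_urban = row$hte_urban, hte_race = row$hte_race
    )
    scenario_id <- as.integer(scenario)
  }
  structure(
    c(list(scenario_id = scenario_id), flags,
      list(
        urban_heterogeneity = isTRUE(urban_heterogeneity),
        race_heterogeneity = isTRUE(race_heterogeneity),
        baseline_boosted_fraction = baseline_boosted_fraction
      )),
    class = "crt_scenario"
  )
}

#' @export
print.crt_scenario <- function(x, ...) {
  on <- names(Filter(isTRUE, x[c("urban_main", "race_main",
                                 "hte_urban", "hte_race")]))
  cat("<crt_scenario> id:", x$scenario_id,
      if (length(on)) paste0("(", paste(on, collapse = ", "), ")")
      else "(no subgroup effects)", "\n")
  ext <- c(
    if (x$urban_heterogeneity) "urban heterogeneity",
    if (x$race_heterogeneity) "race heterogeneity",
    if (x$baseline_boosted_fraction > 0)
      sprintf("baseline boosted %.0f%%", 100 * x$baseline_boosted_fraction)
  )
  if (length(ext)) cat("  extensions:", paste(ext, collapse = ", "), "\n")
  invisible(x)
}

#' Map a scenario to concrete generating coefficients
#'
#' Takes the scenario's effect flags and a base coefficient set and returns
#' the generating truth: the intervention effect is always kept, while each
#' subgroup main effect and interaction is retained iff its flag is on and is
#' set to exactly zero otherwise (so null hypotheses tested downstream are
#' exactly true in null scenarios). The result is validated on the full binary
#' covariate support.
#'
#' @param spec A `crt_scenario` (or an integer scenario id, passed to
#'   [scenario_spec()]).
#' @param base Base coefficients; defaults to [true_coefficients()].
#' @return A `crt_coefs` vector.
#' @examples
#' build_coefficients(scenario_spec(1)) # only beta0 and beta_trt non-zero
#' build_coefficients(scenario_spec(9))
#' @export
build_coefficients <- function(spec, base = true_coefficients()) {
  if (!inherits(spec, "crt_scenario")) spec <- scenario_spec(spec)
  out <- unclass(base)
  if (!spec$urban_main) out[["beta_urban"]] <- 0
  if (!spec$race_main) out[["beta_race"]] <- 0
  if (!spec$hte_urban) out[["beta_trt_urban"]] <- 0
  if (!spec$hte_race) out[["beta_trt_race"]] <- 0
  do.call(true_coefficients, as.list(out))
}
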
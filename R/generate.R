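#' Generate the cluster frame for a simulated trial
#'
#' Clusters (long-term care centers) sit in one of two regions and are either
#' urban/suburban or rural. Region membership is deterministic:
#' `round(K * region_split)` clusters in region 1, the rest in region 0.
#' Urban composition is either `"fixed"` — exactly `round(p_urban * K_r)`
#' urban clusters within each region, a deterministic balanced composition —
#' or `"heterogeneous"`, where each cluster's urban flag is an independent
#' Bernoulli(`p_urban`) draw.
#'
#' @param K Number of clusters (at least 4 so both region strata can be
#'   randomized).
#' @param n_staff Staff members per cluster (default 100).
#' @param region_split Proportion of clusters in region 1, in (0, 1).
#' @param urban_scheme `"fixed"` or `"heterogeneous"`.
#' @param p_urban Urban proportion (fixed scheme) or probability
#'   (heterogeneous scheme).
#' @return A tibble with columns `cluster_id`, `region`, `urban`, `n_staff`.
#' @examples
#' generate_clusters(K = 8)
#' @export
generate_clusters <- function(K, n_staff = 100, region_split = 0.5,
                              urban_scheme = c("fixed", "heterogeneous"),
                              p_urban = 0.5) {
  urban_scheme <- match.arg(urban_scheme)
  if (K < 4) abort("`K` must be at least 4 (two clusters per region stratum)")
  if (region_split <= 0 || region_split >= 1) {
    abort("`region_split` must lie strictly between 0 and 1")
  }
  K1 <- round(K * region_split)
  if (K1 == 0 || K1 == K) abort("both regions must be non-empty")
  region <- rep(c(1L, 0L), c(K1, K - K1))
  urban <- integer(K)
  if (urban_scheme == "fixed") {
    for (r in c(1L, 0L)) {
      idx <- which(region == r)
      n_urb <- round(p_urban * length(idx))
      urban[idx[seq_len(n_urb)]] <- 1L
    }
  } else {
    urban <- rbinom(K, 1L, p_urban)
  }
  tibble(
    cluster_id = seq_len(K),
    region = region,
    urban = as.integer(urban),
    n_staff = as.integer(n_staff)
  )
}

#' Generate staff-level records within clusters
#'
#' Each cluster contributes `n_staff` individuals carrying a binary
#' self-reported race variable (1 = identifies as Black/African American).
#' Under the `"fixed"` scheme all individuals share a common prevalence
#' `p_race`; under `"heterogeneous"` each cluster first draws its own
#' prevalence from a Beta distribution with mean `p_race` and concentration
#' `beta_concentration` (shape1 = mean*conc, shape2 = (1-mean)*conc), the
#' standard over-dispersion device — as the concentration grows the scheme
#' converges to the fixed one.
#'
#' @param clusters Cluster frame from [generate_clusters()].
#' @param race_scheme `"fixed"` or `"heterogeneous"`.
#' @param p_race Marginal race prevalence, strictly inside (0, 1).
#' @param beta_concentration Positive concentration of the Beta mixing
#'   distribution (heterogeneous scheme only).
#' @return A tibble with columns `cluster_id`, `individual_id`, `race`,
#'   `baseline_boosted` (initialized to 0).
#' @examples
#' cl <- generate_clusters(K = 4, n_staff = 5)
#' generate_individuals(cl)
#' @export
generate_individuals <- function(clusters,
                                 race_scheme = c("fixed", "heterogeneous"),
                                 p_race = 0.5, beta_concentration = 10) {
  race_scheme <- match.arg(race_scheme)
  if (p_race <= 0 || p_race >= 1) {
    abort("`p_race` must lie strictly between 0 and 1")
  }
  if (beta_concentration <= 0) abort("`beta_concentration` must be positive")
  n_each <- clusters$n_staff
  total <- sum(n_each)
  if (race_scheme == "fixed") {
    p_vec <- rep(p_race, total)
  } else {
    p_c <- rbeta(nrow(clusters),
                 shape1 = p_race * beta_concentration,
                 shape2 = (1 - p_race) * beta_concentration)
    p_vec <- rep(p_c, n_each)
  }
  tibble(
    cluster_id = rep(clusters$cluster_id, n_each),
    individual_id = sequence(n_each),
    race = rbinom(total, 1L, p_vec),
    baseline_boosted = 0L
  )
}

#' Flag individuals as already boosted at baseline
#'
#' Each individual is independently flagged with probability `fraction`,
#' independent of race, urban status, and region. Flagged individuals have
#' their outcome forced to 1 by [generate_outcomes()], emulating participants
#' who received a booster vaccine before the trial started. With
#' `fraction = 0` the data mechanism is unchanged (no RNG draws consumed).
#'
#' @param individuals Individual frame from [generate_individuals()].
#' @param fraction Probability in \[0, 1) of being boosted at baseline.
#' @return `individuals` with the `baseline_boosted` column filled in.
#' @export
assign_baseline_boosted <- function(individuals, fraction) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must lie in [0, 1)")
  if (fraction > 0) {
    individuals$baseline_boosted <- rbinom(nrow(individuals), 1L, fraction)
  }
  individuals
}

#' Draw binary outcomes from the linear probability model
#'
#' Joins arm assignment and cluster covariates onto the individual table and
#' draws each outcome as Bernoulli(p) with
#' p = beta0 + beta_trt*A + beta_urban*Z1 + beta_race*Z2 + beta_region*R +
#' beta_trt_urban*A*Z1 + beta_trt_race*A*Z2. Individuals flagged as boosted
#' at baseline get outcome 1 regardless of p. One vectorized Bernoulli draw
#' is consumed per individual, in table order (baseline-boosted individuals
#' included, then overwritten), so a fixed seed reproduces the dataset
#' bit-for-bit and `fraction = 0` matches the base mechanism exactly.
#'
#' @param individuals Individual frame (with `baseline_boosted` set).
#' @param clusters Cluster frame.
#' @param allocation Allocation from [constrained_randomize()] (columns
#'   `cluster_id`, `arm`, covering every cluster).
#' @param coefs Generating coefficients (`crt_coefs`); must pass
#'   [validate_support()].
#' @return The individual table with `region`, `urban`, `arm`, and `outcome`
#'   columns added.
#' @examples
#' set.seed(1)
#' cl <- generate_clusters(K = 4, n_staff = 50)
#' ind <- generate_individuals(cl)
#' alloc <- constrained_randomize(cl)
#' out <- generate_outcomes(ind, cl, alloc, build_coefficients(1))
#' mean(out$outcome)
#' @export
generate_outcomes <- function(individuals, clusters, allocation, coefs) {
  if (!all(clusters$cluster_id %in% allocation$cluster_id)) {
    abort("`allocation` must cover every cluster")
  }
  bad <- validate_support(coefs)
  if (nrow(bad) > 0) {
    abort("generating coefficients imply probabilities outside [0, 1]; see validate_support()")
  }
  idx <- match(individuals$cluster_id, clusters$cluster_id)
  out <- individuals
  out$region <- clusters$region[idx]
  out$urban <- clusters$urban[idx]
  out$arm <- allocation$arm[match(individuals$cluster_id,
                                  allocation$cluster_id)]
  p <- linear_predictor(out, coefs)
  out$outcome <- rbinom(nrow(out), 1L, p)
  out$outcome[out$baseline_boosted == 1L] <- 1L
  out[, c("cluster_id", "individual_id", "region", "urban", "race",
          "baseline_boosted", "arm", "outcome")]
}

#' Simulate one complete cluster-randomized trial
#'
#' Runs the full generating pipeline for a single dataset: cluster frame,
#' individual race draws, baseline-boosted flags, constrained randomization
#' (stratified by region, balancing urban/rural), outcome draws, and
#' cluster-level aggregation (mean outcome, race proportion, centered
#' proportion, and threshold indicator). RNG is consumed in exactly that
#' order.
#'
#' @param K Number of clusters.
#' @param scenario A `crt_scenario` or integer scenario id (default 1).
#' @param coefs Generating coefficients; defaults to
#'   `build_coefficients(scenario, base_coefs)`.
#' @param base_coefs Base coefficient set used when `coefs` is `NULL`.
#' @param n_staff Staff per cluster.
#' @param region_split,p_urban,p_race,beta_concentration Generator settings;
#'   see [generate_clusters()] and [generate_individuals()].
#' @param threshold Cutoff for the cluster-level race indicator (strict `>`).
#' @param n_candidates,acceptance Constrained-randomization settings; see
#'   [constrained_randomize()].
#' @param seed Optional integer seed set before any draw.
#' @return A list of class `crt_trial` with elements `clusters`,
#'   `individuals`, `allocation`, `summary`, `scenario`, `coefs`.
#' @examples
#' trial <- simulate_trial(K = 8, scenario = 6, n_staff = 20, seed = 7)
#' trial$summary
#' @export
simulate_trial <- function(K = 40, scenario = 1, coefs = NULL,
                           base_coefs = true_coefficients(),
                           n_staff = 100, region_split = 0.5, p_urban = 0.5,
                           p_race = 0.5, beta_concentration = 10,
                           threshold = 0.5,
                           n_candidates = 50000,
                           acceptance = list(rule = "min"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(scenario, "crt_scenario")) scenario <- scenario_spec(scenario)
  if (is.null(coefs)) coefs <- build_coefficients(scenario, base_coefs)

  clusters <- generate_clusters(
    K, n_staff = n_staff, region_split = region_split,
    urban_scheme = if (scenario$urban_heterogeneity) "heterogeneous" else "fixed",
    p_urban = p_urban
  )
  individuals <- generate_individuals(
    clusters,
    race_scheme = if (scenario$race_heterogeneity) "heterogeneous" else "fixed",
    p_race = p_race, beta_concentration = beta_concentration
  )
  individuals <- assign_baseline_boosted(
    individuals, scenario$baseline_boosted_fraction
  )
  allocation <- constrained_randomize(
    clusters, n_candidates = n_candidates, acceptance = acceptance
  )
  individuals <- generate_outcomes(individuals, clusters, allocation, coefs)
  summary <- aggregate_clusters(individuals, clusters) %>%
    center_proportions() %>%
    dichotomize_proportions(threshold = threshold)

  structure(
    list(
      clusters = clusters, individuals = individuals,
      allocation = allocation, summary = summary,
      scenario = scenario, coefs = coefs
    ),
    class = "crt_trial"
  )
}

#' @export
print.crt_trial <- function(x, ...) {
  cat(sprintf(
    "<crt_trial> K = %d clusters, %d individuals, scenario %s\n",
    nrow(x$clusters), nrow(x$individuals), format(x$scenario$scenario_id)
  ))
  invisible(x)
}
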
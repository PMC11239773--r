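#' Define a full simulation study
#'
#' A study is a factorial grid: scenarios x numbers of clusters x models,
#' with `n_reps` independently generated datasets per (scenario, K) cell and
#' every requested model fit to each dataset. Per-replication seeds are
#' derived deterministically from `master_seed`, the scenario id, K, and the
#' replication index, so any cell can be reproduced in isolation and results
#' are invariant to the worker count.
#'
#' @param scenarios Integer ids and/or `crt_scenario` objects (default 1:9).
#' @param K_values Numbers of clusters (default `c(30, 40, 80)`).
#' @param n_reps Simulated datasets per cell (default 1000, the
#'   study-faithful setting; use fewer for quick checks).
#' @param models Model ids to fit (default all 16).
#' @param master_seed Integer master seed.
#' @param base_coefs Base generating coefficients.
#' @param n_staff,region_split,p_urban,p_race,beta_concentration,threshold,
#'   n_candidates,acceptance,df_method,alpha Passed through to
#'   [simulate_trial()] and [fit_hte_model()].
#' @return A list of class `crt_study_grid`.
#' @examples
#' study_grid(scenarios = c(1, 6), K_values = 30, n_reps = 50)
#' @export
study_grid <- function(scenarios = 1:9, K_values = c(30, 40, 80),
                       n_reps = 1000, models = model_grid()$model_id,
                       master_seed = 1, base_coefs = true_coefficients(),
                       n_staff = 100, region_split = 0.5, p_urban = 0.5,
                       p_race = 0.5, beta_concentration = 10,
                       threshold = 0.5, n_candidates = 50000,
                       acceptance = list(rule = "min"),
                       df_method = "normal", alpha = 0.05) {
  if (!is.list(scenarios)) scenarios <- as.list(scenarios)
  scenarios <- lapply(scenarios, function(s) {
    if (inherits(s, "crt_scenario")) s else scenario_spec(s)
  })
  bad <- setdiff(models, model_grid()$model_id)
  if (length(bad) > 0) {
    abort(sprintf("unknown model id(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      scenarios = scenarios, K_values = K_values, n_reps = n_reps,
      models = models, master_seed = as.integer(master_seed),
      base_coefs = base_coefs, n_staff = n_staff,
      region_split = region_split, p_urban = p_urban, p_race = p_race,
      beta_concentration = beta_concentration, threshold = threshold,
      n_candidates = n_candidates, acceptance = acceptance,
      df_method = df_method, alpha = alpha
    ),
    class = "crt_study_grid"
  )
}

#' @export
print.crt_study_grid <- function(x, ...) {
  cat(sprintf(
    "<crt_study_grid> %d scenario(s) x K in {%s} x %d model(s), %d reps/cell, master seed %d\n",
    length(x$scenarios), paste(x$K_values, collapse = ", "),
    length(x$models), x$n_reps, x$master_seed
  ))
  invisible(x)
}

# Deterministic per-replication seed in [1, 2^31 - 1], distinct across rep
# indices within a cell (2^31 - 1 is prime, so the final linear step is
# injective in `rep`). All arithmetic stays below 2^53, hence exact.
rep_seed <- function(master, scenario_id, K, rep) {
  if (identical(scenario_id, "custom")) scenario_id <- 0
  h <- as.double(master) %% 2147483647
  for (v in c(as.double(scenario_id), as.double(K), as.double(rep))) {
    h <- (h * 69069 + v * 1234567 + 12345) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Generate one dataset and fit a set of models to it
#'
#' Runs the single-replication pipeline (clusters, individuals, constrained
#' randomization, outcomes, aggregation via [simulate_trial()]) and fits each
#' requested model to the same dataset. Degenerate dataset-model pairs (a
#' constant requested design column, e.g., a race indicator with all clusters
#' on one side of the threshold) are recorded as a flagged row, not an error.
#'
#' @inheritParams study_grid
#' @param scenario A `crt_scenario` or integer id.
#' @param K Number of clusters.
#' @param coefs Generating coefficients; defaults to
#'   `build_coefficients(scenario, base_coefs)`.
#' @param seed Integer seed for this replication.
#' @return A tibble with one row per (model, coefficient): `model_id`,
#'   `level`, `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `reject`, `degenerate`, `seed`.
#' @examples
#' run_replication(scenario_spec(1), K = 8, models = c("1a", "2a"),
#'                 seed = 5, n_staff = 20)
#' @export
run_replication <- function(scenario, K, coefs = NULL,
                            models = model_grid()$model_id, seed = NULL,
                            base_coefs = true_coefficients(), n_staff = 100,
                            region_split = 0.5, p_urban = 0.5, p_race = 0.5,
                            beta_concentration = 10, threshold = 0.5,
                            n_candidates = 50000,
                            acceptance = list(rule = "min"),
                            df_method = "normal", alpha = 0.05) {
  trial <- simulate_trial(
    K = K, scenario = scenario, coefs = coefs, base_coefs = base_coefs,
    n_staff = n_staff, region_split = region_split, p_urban = p_urban,
    p_race = p_race, beta_concentration = beta_concentration,
    threshold = threshold, n_candidates = n_candidates,
    acceptance = acceptance, seed = seed
  )
  grid <- model_grid()
  rows <- lapply(models, function(id) {
    spec <- grid[grid$model_id == id, ]
    data <- if (spec$level == "individual") trial$individuals else trial$summary
    fit <- fit_hte_model(data, spec, df_method = df_method)
    if (fit$degenerate) {
      tibble(
        model_id = id, level = spec$level, term = NA_character_,
        estimate = NA_real_, std.error = NA_real_, statistic = NA_real_,
        p.value = NA_real_, reject = NA, degenerate = TRUE
      )
    } else {
      res <- wald_tests(fit, alpha = alpha)
      tibble(
        model_id = id, level = spec$level, term = res$term,
        estimate = res$estimate, std.error = res$std.error,
        statistic = res$statistic, p.value = res$p.value,
        reject = res$reject, degenerate = FALSE
      )
    }
  })
  out <- bind_rows(rows)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

# generating truth for a fitted coefficient, NA when no counterpart exists
# (cluster-level race encodings and the cluster-level intercept under the
# centered-proportion encoding are aggregates with no single generating
# coefficient -- the ecological-bias point)
truth_for_term <- function(term, level, coefs) {
  if (level == "individual") {
    switch(term,
      "(Intercept)" = coefs[["beta0"]],
      arm = coefs[["beta_trt"]],
      urban = coefs[["beta_urban"]],
      region = coefs[["beta_region"]],
      race = coefs[["beta_race"]],
      "arm:urban" = coefs[["beta_trt_urban"]],
      "arm:race" = coefs[["beta_trt_race"]],
      NA_real_
    )
  } else {
    switch(term,
      arm = coefs[["beta_trt"]],
      urban = coefs[["beta_urban"]],
      region = coefs[["beta_region"]],
      "arm:urban" = coefs[["beta_trt_urban"]],
      NA_real_
    )
  }
}

#' Run a simulation study and summarize operating characteristics
#'
#' Executes every (scenario, K) cell of the grid: `n_reps` datasets each,
#' all requested models fit per dataset, then per-cell summaries per
#' (model, coefficient): rejection proportion with its Monte-Carlo standard
#' error, mean and SD of the estimates, bias against the generating
#' coefficient where one exists, and degeneracy counts. Because every
#' replication re-seeds itself from the deterministic per-cell stream, the
#' output is bitwise identical for any `workers` value.
#'
#' @param grid A `crt_study_grid`.
#' @param workers Number of worker processes (forked via
#'   [parallel::mclapply()]; 1 = sequential).
#' @return A tibble of class `crt_oc` with columns `scenario_id`, `K`,
#'   `model_id`, `level`, `term`, `n_eff`, `n_degenerate`, `rejection`,
#'   `mc_se`, `mean_est`, `sd_est`, `truth`, `bias`.
#' @examples
#' grid <- study_grid(scenarios = 1, K_values = 8, n_reps = 20,
#'                    models = c("1a", "1e"), n_staff = 20)
#' run_study(grid)
#' @export
run_study <- function(grid, workers = 1) {
  stopifnot(inherits(grid, "crt_study_grid"))
  cells <- tidyr::expand_grid(
    s_idx = seq_along(grid$scenarios), K = grid$K_values
  )
  cell_results <- lapply(seq_len(nrow(cells)), function(i) {
    scenario <- grid$scenarios[[cells$s_idx[i]]]
    K <- cells$K[i]
    coefs <- build_coefficients(scenario, grid$base_coefs)
    one_rep <- function(r) {
      run_replication(
        scenario, K, coefs = coefs, models = grid$models,
        seed = rep_seed(grid$master_seed, scenario$scenario_id, K, r),
        n_staff = grid$n_staff, region_split = grid$region_split,
        p_urban = grid$p_urban, p_race = grid$p_race,
        beta_concentration = grid$beta_concentration,
        threshold = grid$threshold, n_candidates = grid$n_candidates,
        acceptance = grid$acceptance, df_method = grid$df_method,
        alpha = grid$alpha
      )
    }
    reps <- if (workers > 1) {
      parallel::mclapply(seq_len(grid$n_reps), one_rep, mc.cores = workers)
    } else {
      lapply(seq_len(grid$n_reps), one_rep)
    }
    raw <- bind_rows(reps)
    summarize_cell(raw, scenario, K, coefs)
  })
  out <- bind_rows(cell_results)
  structure(out, class = c("crt_oc", class(out)),
            grid = grid)
}

summarize_cell <- function(raw, scenario, K, coefs) {
  degen <- raw %>%
    group_by(.data$model_id) %>%
    summarise(n_degenerate = sum(.data$degenerate), .groups = "drop")
  est <- raw %>%
    filter(!.data$degenerate) %>%
    group_by(.data$model_id, .data$level, .data$term) %>%
    summarise(
      n_eff = dplyr::n(),
      rejection = mean(.data$reject),
      mean_est = mean(.data$estimate),
      sd_est = sd(.data$estimate),
      .groups = "drop"
    ) %>%
    mutate(mc_se = sqrt(.data$rejection * (1 - .data$rejection) / .data$n_eff))
  est$truth <- vapply(
    seq_len(nrow(est)),
    function(i) truth_for_term(est$term[i], est$level[i], coefs),
    numeric(1)
  )
  est %>%
    mutate(
      bias = .data$mean_est - .data$truth,
      scenario_id = scenario$scenario_id,
      K = K
    ) %>%
    # full join so a model degenerate in every replication still surfaces
    # (with NA summaries and its degeneracy count)
    dplyr::full_join(degen, by = "model_id") %>%
    mutate(
      scenario_id = scenario$scenario_id, K = K,
      n_eff = ifelse(is.na(.data$n_eff), 0L, .data$n_eff)
    ) %>%
    select(
      "scenario_id", "K", "model_id", "level", "term", "n_eff",
      "n_degenerate", "rejection", "mc_se", "mean_est", "sd_est",
      "truth", "bias"
    )
}

#' Compare individual- versus cluster-level power for one HTE coefficient
#'
#' For each (scenario, K) cell, pairs every individual-level model containing
#' the coefficient with every cluster-level model containing it and reports
#' the rejection proportions, their difference (individual minus cluster),
#' and the Monte-Carlo standard error of that difference. In cells where the
#' generating interaction is truly zero the rejection proportions are type-I
#' errors, and the `quantity` column says so.
#'
#' @param oc A `crt_oc` from [run_study()] containing the coefficient at both
#'   levels.
#' @param term Coefficient name (default `"arm:race"`, the race-HTE term).
#' @return A tibble with columns `scenario_id`, `K`, `quantity`,
#'   `individual_model`, `cluster_model`, `power_individual`,
#'   `power_cluster`, `difference`, `mc_se_difference`.
#' @export
compare_power <- function(oc, term = "arm:race") {
  rows <- oc %>% filter(.data$term == !!term)
  ind <- rows %>% filter(.data$level == "individual")
  clu <- rows %>% filter(.data$level == "cluster")
  if (nrow(ind) == 0 || nrow(clu) == 0) {
    abort("`oc` must contain the coefficient at both the individual and cluster level")
  }
  grid <- attr(oc, "grid")
  hte_on <- function(sid) {
    if (is.null(grid)) return(NA)
    for (s in grid$scenarios) {
      if (identical(s$scenario_id, sid)) {
        return(if (term == "arm:race") s$hte_race else s$hte_urban)
      }
    }
    NA
  }
  out <- ind %>%
    select(scenario_id = "scenario_id", K = "K",
           individual_model = "model_id",
           power_individual = "rejection", se_i = "mc_se") %>%
    left_join(
      clu %>% select(scenario_id = "scenario_id", K = "K",
                     cluster_model = "model_id",
                     power_cluster = "rejection", se_c = "mc_se"),
      by = c("scenario_id", "K"), relationship = "many-to-many"
    ) %>%
    mutate(
      difference = .data$power_individual - .data$power_cluster,
      mc_se_difference = sqrt(.data$se_i^2 + .data$se_c^2),
      quantity = ifelse(
        vapply(.data$scenario_id, function(s) isTRUE(hte_on(s)), logical(1)),
        "power", "type I error"
      )
    ) %>%
    select(
      "scenario_id", "K", "quantity", "individual_model", "cluster_model",
      "power_individual", "power_cluster", "difference", "mc_se_difference"
    )
  out
}

#' Rejection-proportion plot of a simulation study
#'
#' Displays the rejection proportion for one coefficient across the study
#' grid in the standard layout: rows = number of clusters K, columns =
#' scenarios, bars = models, with a dashed line at the nominal level. Under
#' null scenarios the bars are type-I error; under alternative scenarios,
#' power.
#'
#' @param object A `crt_oc` from [run_study()].
#' @param term Coefficient to display (default `"arm:race"`).
#' @param nominal Nominal test level drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crt_oc
#' @export
autoplot.crt_oc <- function(object, term = "arm:race", nominal = 0.05, ...) {
  dat <- object %>% filter(.data$term == !!term)
  if (nrow(dat) == 0) abort(sprintf("no results for term \"%s\"", term))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$model_id, y = .data$rejection,
                 fill = .data$level)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$rejection - 2 * .data$mc_se),
                   ymax = pmin(1, .data$rejection + 2 * .data$mc_se)),
      width = 0.3
    ) +
    ggplot2::geom_hline(yintercept = nominal, linetype = "dashed") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$K),
      cols = ggplot2::vars(.data$scenario_id),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "model", y = "proportion of tests rejected",
      fill = "data level",
      title = sprintf("Rejection proportion for the %s coefficient", term)
    ) +
    ggplot2::theme_bw()
}
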
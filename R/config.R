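#' Read a study configuration from a YAML file
#'
#' The config file holds plain `key: value` pairs naming [study_grid()]
#' arguments, plus two optional nested blocks: `coefficients:` (overrides for
#' [true_coefficients()], e.g., `beta0: 0.25`) and `extensions:`
#' (`urban_heterogeneity`, `race_heterogeneity`,
#' `baseline_boosted_fraction`, applied to every scenario). See
#' `system.file("extdata", "example-config.yaml", package = "crthte")`.
#'
#' @param path Path to the YAML file.
#' @return A `crt_study_grid`.
#' @examples
#' cfg <- system.file("extdata", "example-config.yaml", package = "crthte")
#' read_study_config(cfg)
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  coef_over <- raw$coefficients %||% list()
  base_coefs <- do.call(true_coefficients, coef_over)
  ext <- raw$extensions %||% list()
  scenarios <- lapply(raw$scenarios %||% 1:9, function(s) {
    scenario_spec(
      s,
      urban_heterogeneity = ext$urban_heterogeneity %||% FALSE,
      race_heterogeneity = ext$race_heterogeneity %||% FALSE,
      baseline_boosted_fraction = ext$baseline_boosted_fraction %||% 0
    )
  })
  args <- raw[setdiff(names(raw), c("coefficients", "extensions", "scenarios"))]
  allowed <- setdiff(names(formals(study_grid)),
                     c("scenarios", "base_coefs"))
  bad <- setdiff(names(args), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(study_grid, c(list(scenarios = scenarios, base_coefs = base_coefs),
                        args))
}

#' Write a simulated trial to delimited tables
#'
#' Writes `individuals.tsv`, `clusters.tsv`, `allocation.tsv` and
#' `cluster_summary.tsv` (tab-separated, with headers) into `dir`.
#'
#' @param trial A `crt_trial` from [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_data <- function(trial, dir) {
  stopifnot(inherits(trial, "crt_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(trial$individuals, file.path(dir, "individuals.tsv"))
  readr::write_tsv(trial$clusters, file.path(dir, "clusters.tsv"))
  readr::write_tsv(as_tibble(trial$allocation),
                   file.path(dir, "allocation.tsv"))
  readr::write_tsv(trial$summary, file.path(dir, "cluster_summary.tsv"))
  invisible(dir)
}

#' Read a simulated trial back from delimited tables
#'
#' @param dir Directory written by [write_trial_data()].
#' @return A list with `individuals`, `clusters`, `allocation`, `summary`.
#' @export
read_trial_data <- function(dir) {
  read1 <- function(f) {
    readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
  }
  list(
    individuals = read1("individuals.tsv"),
    clusters = read1("clusters.tsv"),
    allocation = read1("allocation.tsv"),
    summary = read1("cluster_summary.tsv")
  )
}
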
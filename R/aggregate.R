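#' Aggregate individual-level data to the cluster level
#'
#' Builds the cluster-level analysis dataset: one row per cluster carrying
#' the region, urban flag, arm, the within-cluster mean outcome (the observed
#' cluster-level booster vaccination rate), and the within-cluster proportion
#' identifying as Black/African American.
#'
#' @param individuals Individual table with `arm` and `outcome` filled in.
#' @param clusters Cluster frame; every cluster must have at least one
#'   individual.
#' @return A tibble with columns `cluster_id`, `region`, `urban`, `arm`,
#'   `n`, `mean_outcome`, `race_proportion`.
#' @seealso [center_proportions()], [dichotomize_proportions()]
#' @export
aggregate_clusters <- function(individuals, clusters) {
  missing <- setdiff(clusters$cluster_id, individuals$cluster_id)
  if (length(missing) > 0) {
    abort(sprintf("cluster(s) with zero individuals: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- individuals %>%
    group_by(.data$cluster_id) %>%
    summarise(
      region = .data$region[1],
      urban = .data$urban[1],
      arm = .data$arm[1],
      n = dplyr::n(),
      mean_outcome = mean(.data$outcome),
      race_proportion = mean(.data$race),
      .groups = "drop"
    ) %>%
    arrange(.data$cluster_id)
  out
}

#' Mean-center cluster-level race proportions
#'
#' Adds `race_proportion_centered`: each cluster's proportion minus the
#' unweighted mean proportion over the K clusters in this dataset (recomputed
#' per dataset, so coefficients on it are interpreted as differences from the
#' study-mean composition). Centered values sum to zero by construction.
#'
#' @param summaries Cluster summary from [aggregate_clusters()] (K >= 2 rows).
#' @return `summaries` with `race_proportion_centered` added.
#' @export
center_proportions <- function(summaries) {
  if (nrow(summaries) < 2) abort("need at least 2 clusters to center")
  summaries$race_proportion_centered <-
    summaries$race_proportion - mean(summaries$race_proportion)
  summaries
}

#' Dichotomize cluster-level race proportions
#'
#' Adds `race_indicator`: 1 iff the cluster's race proportion strictly
#' exceeds `threshold` (default 0.5), defining "high" versus "low" proportion
#' clusters. The boundary is strict, so a cluster exactly at the threshold
#' (attainable with 100 staff) is coded 0.
#'
#' @param summaries Cluster summary from [aggregate_clusters()].
#' @param threshold Cutoff in (0, 1); default 0.5.
#' @return `summaries` with `race_indicator` added.
#' @export
dichotomize_proportions <- function(summaries, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1")
  }
  summaries$race_indicator <-
    as.integer(summaries$race_proportion > threshold)
  summaries
}
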
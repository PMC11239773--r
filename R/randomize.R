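#' Urban/rural balance score of an allocation
#'
#' Within each region stratum, computes the absolute difference between the
#' number of urban clusters assigned to arm 1 and to arm 0, and sums over
#' regions. Zero means exact urban balance in both regions; lower is better.
#'
#' @param allocation A tibble with `cluster_id` and `arm` covering every
#'   cluster.
#' @param clusters Cluster frame with `cluster_id`, `region`, `urban`.
#' @return A non-negative integer.
#' @examples
#' cl <- generate_clusters(K = 8)
#' alloc <- constrained_randomize(cl)
#' balance_score(alloc, cl)
#' @export
balance_score <- function(allocation, clusters) {
  if (!all(clusters$cluster_id %in% allocation$cluster_id)) {
    abort("`allocation` is missing clusters")
  }
  arm <- allocation$arm[match(clusters$cluster_id, allocation$cluster_id)]
  score <- 0L
  for (r in unique(clusters$region)) {
    in_r <- clusters$region == r
    u1 <- sum(clusters$urban[in_r] & arm[in_r] == 1L)
    u0 <- sum(clusters$urban[in_r] & arm[in_r] == 0L)
    score <- score + abs(u1 - u0)
  }
  as.integer(score)
}

#' Constrained randomization stratified by region
#'
#' Assigns clusters to two arms with exactly half of each region stratum in
#' arm 1, restricted to allocations that balance urban/rural composition
#' between arms. Candidate stratified half-split allocations are drawn
#' uniformly (all of them, when the total count does not exceed
#' `n_candidates`; otherwise a Monte-Carlo sample of `n_candidates`); the
#' accepted set is either every candidate achieving the minimum observed
#' balance score (`rule = "min"`, the default — exact balance whenever the
#' composition permits) or the best `q` fraction by score
#' (`rule = "quantile"`, useful when heterogeneous composition makes exact
#' balance impossible); the returned allocation is drawn uniformly from the
#' accepted set.
#'
#' On the Monte-Carlo path the per-region number of urban clusters assigned
#' to arm 1 — the sufficient statistic for the balance score — is sampled
#' from its exact hypergeometric distribution for each candidate, and the
#' selected candidate is then realized as a uniform allocation given those
#' counts; this is distributionally identical to scoring fully enumerated
#' candidate allocations.
#'
#' Odd strata assign `floor(K_r/2)` clusters to arm 1 plus one more with
#' probability 1/2 (defaults use even strata).
#'
#' @param clusters Cluster frame from [generate_clusters()]; every region
#'   stratum needs at least 2 clusters.
#' @param n_candidates Number of candidate allocations (default 50000).
#' @param acceptance `list(rule = "min")` or `list(rule = "quantile", q = 0.1)`.
#' @return A tibble (`cluster_id`, `arm`) of class `crt_allocation`, with
#'   attributes `balance_score`, `method` ("enumeration" or "sampling"),
#'   `n_candidates`, `n_accepted`, and `acceptance`.
#' @examples
#' set.seed(3)
#' cl <- generate_clusters(K = 8)
#' alloc <- constrained_randomize(cl)
#' attr(alloc, "balance_score") # 0 under balanced composition
#' @export
constrained_randomize <- function(clusters, n_candidates = 50000,
                                  acceptance = list(rule = "min")) {
  rule <- match.arg(acceptance$rule, c("min", "quantile"))
  q <- if (rule == "quantile") acceptance$q %||% 0.1 else NA_real_
  regions <- unique(clusters$region)
  strata <- lapply(regions, function(r) {
    ids <- clusters$cluster_id[clusters$region == r]
    urb <- clusters$urban[clusters$region == r]
    m <- length(ids)
    if (m < 2) abort("each region stratum needs at least 2 clusters")
    h <- m %/% 2L
    if (m %% 2L == 1L) h <- h + rbinom(1L, 1L, 0.5)
    list(ids = ids, urban_ids = ids[urb == 1L], rural_ids = ids[urb == 0L],
         m = m, h = h, n_urban = sum(urb))
  })

  total <- prod(vapply(strata, function(s) choose(s$m, s$h), numeric(1)))
  if (total <= n_candidates) {
    res <- randomize_enumerate(strata, rule, q)
  } else {
    res <- randomize_sample(strata, n_candidates, rule, q)
  }

  alloc <- tibble(
    cluster_id = clusters$cluster_id,
    arm = as.integer(clusters$cluster_id %in% res$arm1_ids)
  )
  structure(
    alloc,
    class = c("crt_allocation", class(alloc)),
    balance_score = res$score,
    method = res$method,
    n_candidates = res$n_candidates,
    n_accepted = res$n_accepted,
    acceptance = list(rule = rule, q = q)
  )
}

# exhaustive path: all stratified half-splits, scored, accepted set, uniform draw
randomize_enumerate <- function(strata, rule, q) {
  per_region <- lapply(strata, function(s) {
    sets <- combn(s$ids, s$h, simplify = FALSE)
    u1 <- vapply(sets, function(ids) sum(ids %in% s$urban_ids), integer(1))
    list(sets = sets, contrib = abs(2L * u1 - s$n_urban))
  })
  idx_grid <- expand.grid(lapply(per_region, function(p) seq_along(p$sets)))
  scores <- Reduce(`+`, lapply(seq_along(per_region), function(j) {
    per_region[[j]]$contrib[idx_grid[[j]]]
  }))
  keep <- accepted_indices(scores, rule, q)
  pick <- keep[sample.int(length(keep), 1L)]
  arm1 <- unlist(lapply(seq_along(per_region), function(j) {
    per_region[[j]]$sets[[idx_grid[[j]][pick]]]
  }))
  list(arm1_ids = arm1, score = scores[pick], method = "enumeration",
       n_candidates = length(scores), n_accepted = length(keep))
}

# Monte-Carlo path: per-region urban-in-arm-1 counts ~ hypergeometric
randomize_sample <- function(strata, n_candidates, rule, q) {
  u1 <- vapply(strata, function(s) {
    rhyper(n_candidates, s$n_urban, s$m - s$n_urban, s$h)
  }, numeric(n_candidates))
  u1 <- matrix(u1, nrow = n_candidates)
  contrib <- vapply(seq_along(strata), function(j) {
    abs(2 * u1[, j] - strata[[j]]$n_urban)
  }, numeric(n_candidates))
  scores <- as.integer(rowSums(matrix(contrib, nrow = n_candidates)))
  keep <- accepted_indices(scores, rule, q)
  pick <- keep[sample.int(length(keep), 1L)]
  arm1 <- unlist(lapply(seq_along(strata), function(j) {
    s <- strata[[j]]
    k_urb <- u1[pick, j]
    c(resample(s$urban_ids, k_urb), resample(s$rural_ids, s$h - k_urb))
  }))
  list(arm1_ids = arm1, score = scores[pick], method = "sampling",
       n_candidates = n_candidates, n_accepted = length(keep))
}

accepted_indices <- function(scores, rule, q) {
  if (rule == "min") {
    which(scores == min(scores))
  } else {
    cutoff <- quantile(scores, probs = q, type = 1)
    keep <- which(scores <= cutoff)
    if (length(keep) == 0) which(scores == min(scores)) else keep
  }
}

# sample() without the length-1 surprise
resample <- function(x, size) x[sample.int(length(x), size)]

`%||%` <- function(a, b) if (is.null(a)) b else a
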
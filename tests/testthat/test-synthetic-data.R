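test_that("cluster generation splits regions and urban composition exactly under the fixed scheme", {
  cl <- generate_clusters(K = 40, region_split = 0.5, p_urban = 0.5)
  expect_equal(sum(cl$region == 1), 20)
  expect_equal(sum(cl$region == 0), 20)
  for (r in 0:1) {
    expect_equal(sum(cl$urban[cl$region == r]), 10)
  }
  expect_equal(unique(cl$n_staff), 100L)
  expect_equal(anyDuplicated(cl$cluster_id), 0L)

  expect_error(generate_clusters(K = 3), "at least 4")
  expect_error(generate_clusters(K = 8, region_split = 1), "strictly between")
})

test_that("heterogeneous urban composition is Bernoulli with the right mean", {
  set.seed(101)
  counts <- replicate(1000, {
    cl <- generate_clusters(K = 80, urban_scheme = "heterogeneous",
                            p_urban = 0.5)
    sum(cl$urban[cl$region == 1])
  })
  # Binomial(40, 0.5): mean 20, var 10 -> SE of the MC mean ~ 0.1
  expect_lt(abs(mean(counts) - 20), 0.5)
  expect_gt(var(counts), 5) # actually random, unlike the fixed scheme
})

test_that("race draws match the fixed and Beta-heterogeneous schemes", {
  set.seed(202)
  cl <- generate_clusters(K = 40)
  ind <- generate_individuals(cl, p_race = 0.5)
  expect_equal(nrow(ind), 4000)
  # SE of the prevalence ~ 0.008
  expect_lt(abs(mean(ind$race) - 0.5), 0.04)
  expect_true(all(ind$cluster_id %in% cl$cluster_id))

  expect_error(generate_individuals(cl, p_race = 0), "strictly between")
  expect_error(generate_individuals(cl, p_race = 1), "strictly between")

  # cluster-level prevalence variance: at huge concentration the
  # heterogeneous scheme collapses to the fixed one (variance ~ p(1-p)/n);
  # at concentration 10 it is strongly over-dispersed
  big <- generate_clusters(K = 500, n_staff = 100)
  prop_of <- function(ind) tapply(ind$race, ind$cluster_id, mean)
  v_fixed <- 0.5 * 0.5 / 100
  v_tight <- var(prop_of(generate_individuals(
    big, "heterogeneous", 0.5, beta_concentration = 1e6
  )))
  v_loose <- var(prop_of(generate_individuals(
    big, "heterogeneous", 0.5, beta_concentration = 10
  )))
  expect_lt(v_tight / v_fixed, 1.4)
  expect_gt(v_tight / v_fixed, 0.7)
  expect_gt(v_loose / v_fixed, 4)
})

test_that("baseline-boosted flags are drawn at the requested rate and force outcome 1", {
  set.seed(303)
  cl <- generate_clusters(K = 40)
  ind <- generate_individuals(cl)
  expect_identical(assign_baseline_boosted(ind, 0), ind)

  flagged <- assign_baseline_boosted(ind, 0.2)
  # Binomial(4000, 0.2): mean 800, SD ~ 25
  expect_lt(abs(sum(flagged$baseline_boosted) - 800), 110)
  expect_error(assign_baseline_boosted(ind, 1), "\\[0, 1\\)")

  alloc <- constrained_randomize(cl)
  out <- generate_outcomes(flagged, cl, alloc, build_coefficients(1))
  expect_true(all(out$outcome[out$baseline_boosted == 1] == 1))

  # law of total probability: marginal rate ~ f + (1-f) * base rate, where
  # the scenario-1 base rate averaged over arms is 0.30 + 0.14/2 = 0.37
  trial <- simulate_trial(
    K = 80, scenario = scenario_spec(1, baseline_boosted_fraction = 0.2),
    seed = 404
  )
  expect_lt(abs(mean(trial$individuals$outcome) - (0.2 + 0.8 * 0.37)), 0.03)
})

test_that("outcome rates track the generating linear probability model", {
  set.seed(505)
  cl <- generate_clusters(K = 80)
  ind <- generate_individuals(cl)
  alloc <- constrained_randomize(cl)

  flat <- true_coefficients(0.3, 0, 0, 0, 0, 0, 0)
  out <- generate_outcomes(ind, cl, alloc, flat)
  for (a in 0:1) {
    expect_lt(abs(mean(out$outcome[out$arm == a]) - 0.30), 0.03)
  }

  # scenario 1: 14-point risk difference between arms
  diffs <- replicate(5, {
    t1 <- simulate_trial(K = 80, scenario = 1)
    with(t1$individuals, mean(outcome[arm == 1]) - mean(outcome[arm == 0]))
  })
  expect_lt(abs(mean(diffs) - 0.14), 0.03)

  # scenario 6: the arm contrast is 15 points larger among race = 1
  dids <- replicate(5, {
    t6 <- simulate_trial(K = 80, scenario = 6)
    with(
      t6$individuals,
      (mean(outcome[arm == 1 & race == 1]) - mean(outcome[arm == 0 & race == 1])) -
        (mean(outcome[arm == 1 & race == 0]) - mean(outcome[arm == 0 & race == 0]))
    )
  })
  expect_lt(abs(mean(dids) - 0.15), 0.05)

  expect_error(
    generate_outcomes(ind, cl, alloc,
                      true_coefficients(beta0 = 0.95, check = FALSE)),
    "outside"
  )
})

test_that("a fixed seed reproduces a dataset bit-for-bit and arms are cluster-constant", {
  t1 <- simulate_trial(K = 8, n_staff = 20, scenario = 9, seed = 99)
  t2 <- simulate_trial(K = 8, n_staff = 20, scenario = 9, seed = 99)
  expect_identical(t1$individuals, t2$individuals)
  expect_identical(t1$summary, t2$summary)

  arms <- tapply(t1$individuals$arm, t1$individuals$cluster_id,
                 function(a) length(unique(a)))
  expect_true(all(arms == 1))
})
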
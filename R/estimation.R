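#' The 16-model analysis grid
#'
#' Six individual-level models (1a-1f) and ten cluster-level models (2a-2j).
#' Every model includes the intervention assignment and adjustment for the
#' two randomization factors (region and urban/rural status). Models differ
#' in whether they adjust for self-reported race, how race is encoded at the
#' cluster level (mean-centered proportion or >0.5 indicator), and which
#' intervention interactions (HTE terms) they allow:
#'
#' | model | level | race | A x urban | A x race |
#' |-------|------------|-------------|-----------|----------|
#' | 1a | individual | - | | |
#' | 1b | individual | - | yes | |
#' | 1c | individual | binary | | |
#' | 1d | individual | binary | yes | |
#' | 1e | individual | binary | | yes |
#' | 1f | individual | binary | yes | yes |
#' | 2a | cluster | - | | |
#' | 2b | cluster | - | yes | |
#' | 2c | cluster | proportion | | |
#' | 2d | cluster | indicator | | |
#' | 2e | cluster | proportion | yes | |
#' | 2f | cluster | indicator | yes | |
#' | 2g | cluster | proportion | | yes |
#' | 2h | cluster | indicator | | yes |
#' | 2i | cluster | proportion | yes | yes |
#' | 2j | cluster | indicator | yes | yes |
#'
#' @return A tibble with columns `model_id`, `level`, `adjust_race`,
#'   `race_encoding`, `hte_urban`, `hte_race`.
#' @examples
#' model_grid()
#' @export
model_grid <- function() {
  tibble(
    model_id = c(paste0("1", letters[1:6]), paste0("2", letters[1:10])),
    level = rep(c("individual", "cluster"), c(6, 10)),
    adjust_race = c(
      FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
      FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE
    ),
    race_encoding = c(
      "none", "none", "binary", "binary", "binary", "binary",
      "none", "none", "proportion", "indicator", "proportion", "indicator",
      "proportion", "indicator", "proportion", "indicator"
    ),
    hte_urban = c(
      FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
      FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE
    ),
    hte_race = c(
      FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE
    )
  )
}

#' Look up one model specification
#'
#' @param model_id One of `"1a"`-`"1f"`, `"2a"`-`"2j"`.
#' @return A one-row tibble from [model_grid()].
#' @export
model_spec <- function(model_id) {
  grid <- model_grid()
  row <- grid[grid$model_id == model_id, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown model id \"%s\"", format(model_id)))
  }
  row
}

#' Build the design matrix for one model
#'
#' Columns, in order: intercept, intervention (`arm`), `urban`, `region`,
#' the race encoding (when adjusted), `arm:urban`, `arm:race`; interaction
#' columns are elementwise products of the already-built main-effect columns.
#' Individual-level models use the raw binary race variable; cluster-level
#' models use the mean-centered proportion or the threshold indicator
#' (columns added by [center_proportions()] / [dichotomize_proportions()]).
#' Any requested non-intercept column that is constant is reported in
#' `degenerate_terms`, and such a dataset-model pair is refused by
#' [fit_hte_model()] rather than fit.
#'
#' @param data Individual table (individual-level models) or cluster summary
#'   (cluster-level models).
#' @param spec A one-row model specification (see [model_spec()]).
#' @return A list with elements `x` (design matrix), `y` (response),
#'   `cluster` (cluster id per row), `degenerate_terms` (character).
#' @export
build_design_matrix <- function(data, spec) {
  if (spec$level == "individual") {
    y <- data$outcome
    race <- data$race
  } else {
    y <- data$mean_outcome
    race <- switch(spec$race_encoding,
      proportion = data$race_proportion_centered,
      indicator = data$race_indicator,
      none = NULL
    )
    if (spec$adjust_race && is.null(race)) {
      abort("cluster summary lacks the requested race encoding column")
    }
  }
  required <- c("arm", "urban", "region")
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }

  x <- cbind(
    "(Intercept)" = rep(1, nrow(data)),
    arm = data$arm, urban = data$urban, region = data$region
  )
  if (spec$adjust_race) x <- cbind(x, race = race)
  if (spec$hte_urban) x <- cbind(x, "arm:urban" = x[, "arm"] * x[, "urban"])
  if (spec$hte_race) x <- cbind(x, "arm:race" = x[, "arm"] * x[, "race"])

  non_int <- colnames(x)[-1]
  degenerate <- non_int[apply(x[, -1, drop = FALSE], 2, function(col) {
    diff(range(col)) == 0
  })]
  list(x = x, y = y, cluster = data$cluster_id,
       degenerate_terms = degenerate)
}

#' Cluster-robust (sandwich) covariance of a fitted linear model
#'
#' The sandwich estimator with an independent working correlation:
#' \eqn{(X'X)^{-1} [\sum_c X_c' r_c r_c' X_c] (X'X)^{-1}}, summing residual
#' cross-products within clusters (delegates to [sandwich::vcovCL()] with
#' `type = "HC0"` and no finite-sample adjustment, which computes exactly
#' this). With one observation per cluster — as in the cluster-level models —
#' it reduces to the heteroskedasticity-robust HC0 form.
#'
#' @param object A fitted [stats::lm] object.
#' @param cluster Cluster id for each observation.
#' @return A covariance matrix.
#' @seealso [small_sample_correction()]
#' @export
cluster_robust_vcov <- function(object, cluster) {
  sandwich::vcovCL(object, cluster = cluster, type = "HC0", cadjust = FALSE)
}

#' Small-sample variance correction K/(K-2)
#'
#' Inflates every entry of the covariance matrix by K/(K-2), the correction
#' appropriate when two variables were used in constrained randomization.
#'
#' @param vcov Covariance matrix.
#' @param K Number of clusters; must exceed 2.
#' @return The corrected covariance matrix.
#' @examples
#' small_sample_correction(diag(2), K = 40) # multiplies by 40/38
#' @export
small_sample_correction <- function(vcov, K) {
  if (K <= 2) abort("`K` must exceed 2 for the K/(K-2) correction")
  vcov * K / (K - 2)
}

#' Fit one model of the analysis grid
#'
#' Ordinary least squares on the linear probability (individual level) or
#' cluster-mean (cluster level) model, with cluster-robust sandwich
#' covariance, the K/(K-2) small-sample correction, and per-coefficient Wald
#' tests. Point estimates coincide exactly with a GEE fit under an identity
#' link and independence working correlation. If any requested design column
#' is constant (e.g., all clusters on the same side of the race-indicator
#' threshold) the fit is refused and the result flagged degenerate so that
#' simulation summaries can exclude and count it, rather than crash.
#'
#' @param data Individual table or cluster summary, matching `spec$level`.
#' @param spec A one-row model specification, or a model id string.
#' @param df_method Reference distribution for Wald tests: `"normal"`
#'   (default) or `"t"` with K-2 degrees of freedom.
#' @return An object of class `crt_fit`: a list with `model_id`, `level`,
#'   `coefficients` (tibble: term, estimate, std.error, statistic, p.value),
#'   `vcov`, `K`, `nobs`, `r.squared`, `degenerate`, `degenerate_terms`.
#' @examples
#' trial <- simulate_trial(K = 20, scenario = 6, n_staff = 50, seed = 11)
#' fit <- fit_hte_model(trial$individuals, "1f")
#' tidy(fit)
#' @export
fit_hte_model <- function(data, spec, df_method = c("normal", "t")) {
  df_method <- match.arg(df_method)
  if (is.character(spec)) spec <- model_spec(spec)
  dm <- build_design_matrix(data, spec)
  K <- length(unique(dm$cluster))

  empty <- tibble(
    term = character(), estimate = double(), std.error = double(),
    statistic = double(), p.value = double()
  )
  base <- list(
    model_id = spec$model_id, level = spec$level,
    coefficients = empty, vcov = NULL, K = K, nobs = length(dm$y),
    r.squared = NA_real_, df_method = df_method,
    degenerate = FALSE, degenerate_terms = character()
  )

  if (length(dm$degenerate_terms) > 0) {
    base$degenerate <- TRUE
    base$degenerate_terms <- dm$degenerate_terms
    return(structure(base, class = "crt_fit"))
  }

  X <- dm$x
  y <- dm$y
  fit <- lm(y ~ X - 1)
  if (fit$rank < ncol(X)) {
    base$degenerate <- TRUE
    base$degenerate_terms <- colnames(X)[is.na(fit$coefficients)]
    return(structure(base, class = "crt_fit"))
  }

  V <- small_sample_correction(cluster_robust_vcov(fit, dm$cluster), K)
  est <- unname(fit$coefficients)
  se <- sqrt(diag(V))
  stat <- est / se
  p <- if (df_method == "normal") {
    2 * pnorm(-abs(stat))
  } else {
    2 * pt(-abs(stat), df = K - 2)
  }
  p[se == 0] <- NA_real_

  dimnames(V) <- list(colnames(X), colnames(X))
  base$coefficients <- tibble(
    term = colnames(X), estimate = est, std.error = unname(se),
    statistic = unname(stat), p.value = unname(p)
  )
  base$vcov <- V
  base$r.squared <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(base, class = "crt_fit")
}

#' Wald tests on a fitted model
#'
#' Per-coefficient two-sided tests of zero: statistic = estimate / corrected
#' standard error, referred to the standard normal (or t with K-2 df if the
#' fit used that reference); reject iff p < `alpha`.
#'
#' @param fit A `crt_fit`.
#' @param alpha Test level (default 0.05).
#' @return The coefficient tibble with a logical `reject` column (zero rows
#'   for degenerate fits).
#' @export
wald_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "crt_fit"))
  out <- fit$coefficients
  out$reject <- !is.na(out$p.value) & out$p.value < alpha
  out
}

#' @export
print.crt_fit <- function(x, ...) {
  cat(sprintf("<crt_fit> model %s (%s level), K = %d, n = %d\n",
              x$model_id, x$level, x$K, x$nobs))
  if (x$degenerate) {
    cat("  degenerate fit; constant/aliased term(s):",
        paste(x$degenerate_terms, collapse = ", "), "\n")
  } else {
    print(x$coefficients)
  }
  invisible(x)
}

#' @rdname fit_hte_model
#' @param x A `crt_fit` object.
#' @param ... Unused.
#' @method tidy crt_fit
#' @export
tidy.crt_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_hte_model
#' @method glance crt_fit
#' @export
glance.crt_fit <- function(x, ...) {
  tibble(
    model_id = x$model_id, level = x$level, K = x$K, nobs = x$nobs,
    r.squared = x$r.squared, degenerate = x$degenerate
  )
}

#' @rdname fit_hte_model
#' @param object A `crt_fit` object.
#' @method autoplot crt_fit
#' @export
autoplot.crt_fit <- function(object, ...) {
  if (object$degenerate) abort("cannot plot a degenerate fit")
  dat <- object$coefficients %>%
    mutate(
      lo = .data$estimate - 1.96 * .data$std.error,
      hi = .data$estimate + 1.96 * .data$std.error,
      term = factor(.data$term, levels = rev(.data$term))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(
      x = "estimate (risk difference) with 95% CI", y = NULL,
      title = sprintf("Model %s (%s level), K = %d",
                      object$model_id, object$level, object$K)
    )
}
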
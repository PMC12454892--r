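#' Convert within-experiment well means to percent of the reference variant
#'
#' Absolute MFI values are not comparable across days, so each experiment is
#' expressed relative to the benign reference variant measured in the same
#' run. The reference itself maps to exactly 100.
#'
#' @param well_means Named numeric vector of per-variant mean MFIs within one
#'   experiment (replicate wells already averaged).
#' @param reference_id Name of the benign reference variant.
#' @return Named numeric vector of percentages.
#' @export
percent_of_reference <- function(well_means, reference_id = "p.(Ala391Thr)") {
  if (!reference_id %in% names(well_means)) {
    stop(sprintf("reference variant '%s' is missing from the experiment", reference_id))
  }
  ref <- well_means[[reference_id]]
  if (!is.finite(ref) || ref <= 0) {
    stop(sprintf("reference variant '%s' has non-positive mean MFI", reference_id))
  }
  out <- 100 * well_means / ref
  out[reference_id] <- 100
  out
}

#' Aggregate per-experiment percentages for one variant and assay
#'
#' @param percents Numeric vector, one percent-of-reference value per
#'   experiment (replicate wells averaged beforehand).
#' @param variant_id,assay Metadata carried into the result.
#' @param min_experiments Minimum number of experiments for a reportable
#'   result (three in the assay design); fewer experiments flag the result.
#' @return One-row `data.frame` with `mean_percent`, `sd_percent` (sample SD),
#'   `n_experiments`, `below_minimum`, and the per-experiment values as a
#'   list column `per_experiment_percents`.
#' @export
aggregate_experiments <- function(percents, variant_id = NA_character_,
                                  assay = NA_character_, min_experiments = 3L) {
  percents <- percents[is.finite(percents)]
  n <- length(percents)
  data.frame(
    variant_id = variant_id, assay = assay,
    mean_percent = if (n) mean(percents) else NA_real_,
    sd_percent = if (n > 1) stats::sd(percents) else ifelse(n == 1, NA_real_, NA_real_),
    n_experiments = n,
    below_minimum = n < min_experiments,
    per_experiment_percents = I(list(percents)),
    stringsAsFactors = FALSE
  )
}

# Two-sided critical values at alpha = 0.05 for Dixon's ratio statistics
# (Rorabacher 1991 convention): r10 for n = 3..7, r11 for 8..10, r21 for
# 11..13, r22 for 14..30.
dixon_critical_05 <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.615, `9` = 0.570, `10` = 0.534,
  `11` = 0.625, `12` = 0.592, `13` = 0.565,
  `14` = 0.590, `15` = 0.568, `16` = 0.548, `17` = 0.531, `18` = 0.516,
  `19` = 0.503, `20` = 0.491, `21` = 0.480, `22` = 0.470, `23` = 0.461,
  `24` = 0.452, `25` = 0.445, `26` = 0.438, `27` = 0.432, `28` = 0.426,
  `29` = 0.419, `30` = 0.414
)

# Dixon ratio for the candidate at each end of the sorted sample; the variant
# of the statistic follows the sample size, as is conventional.
dixon_statistics <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n <= 7) {
    low <- (x[2] - x[1]) / (x[n] - x[1])
    high <- (x[n] - x[n - 1]) / (x[n] - x[1])
  } else if (n <= 10) {
    low <- (x[2] - x[1]) / (x[n - 1] - x[1])
    high <- (x[n] - x[n - 1]) / (x[n] - x[2])
  } else if (n <= 13) {
    low <- (x[3] - x[1]) / (x[n - 1] - x[1])
    high <- (x[n] - x[n - 2]) / (x[n] - x[2])
  } else {
    low <- (x[3] - x[1]) / (x[n - 2] - x[1])
    high <- (x[n] - x[n - 2]) / (x[n] - x[3])
  }
  c(low = low, high = high)
}

#' Dixon's Q test for a single outlier
#'
#' Tests the most extreme value of a small sample against its neighbors
#' relative to the sample spread, using the two-sided critical values at
#' `alpha = 0.05`. At most one value is ever flagged.
#'
#' @param values Numeric vector with 3 to 30 values.
#' @param alpha Significance level; only 0.05 is tabulated.
#' @return A list with `outlier_index` (index into `values`, or `NA` if no
#'   outlier), `statistic`, and `critical`.
#' @examples
#' dixon_q(c(100, 101, 160))$outlier_index  # 3
#' dixon_q(c(100, 102, 160))$outlier_index  # NA
#' @export
dixon_q <- function(values, alpha = 0.05) {
  if (alpha != 0.05) stop("only alpha = 0.05 critical values are tabulated")
  n <- length(values)
  if (n < 3 || n > 30) {
    stop(sprintf("Dixon's Q test requires 3 to 30 values (got %d)", n))
  }
  rng <- range(values)
  crit <- dixon_critical_05[[as.character(n)]]
  if (diff(rng) == 0) {
    return(list(outlier_index = NA_integer_, statistic = 0, critical = crit))
  }
  stat <- dixon_statistics(values)
  if (stat[["low"]] >= stat[["high"]]) {
    q <- stat[["low"]]
    idx <- which.min(values)
  } else {
    q <- stat[["high"]]
    idx <- which.max(values)
  }
  list(outlier_index = if (q > crit) idx else NA_integer_,
       statistic = unname(q), critical = crit)
}

#' Map a p-value to a significance label
#'
#' @param p Numeric p-value(s).
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, otherwise `"ns"`.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

# Nodes and weights of probabilists' Gauss-Hermite quadrature
# (Golub-Welsch on the Jacobi matrix; weights sum to 1).
gauss_hermite_prob <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1))
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# P(max_j |T_j| <= t) for a multivariate t with product correlation
# rho_ij = lambda_i * lambda_j and df degrees of freedom. Uses the one-factor
# representation Z_j = lambda_j Z0 + sqrt(1 - lambda_j^2) e_j conditioned on
# the common factor (Gauss-Hermite) and on the chi-distributed scale of the
# t (adaptive quadrature). Deterministic.
dunnett_prob_inside <- function(t_val, lambda, df, n_nodes = 48) {
  gh <- gauss_hermite_prob(n_nodes)
  s <- sqrt(1 - lambda^2)
  inner <- function(u) {
    # u: vector of half-widths on the normal scale; returns P(all |Z_j| <= u)
    vapply(u, function(ui) {
      pr <- rep(1, n_nodes)
      for (j in seq_along(lambda)) {
        pr <- pr * (stats::pnorm((ui - lambda[j] * gh$nodes) / s[j]) -
                      stats::pnorm((-ui - lambda[j] * gh$nodes) / s[j]))
      }
      sum(gh$weights * pr)
    }, numeric(1))
  }
  # W = sqrt(chisq_df / df); density f_W(w) = 2 df w dchisq(df w^2, df)
  f <- function(w) 2 * df * w * stats::dchisq(df * w^2, df) * inner(t_val * w)
  stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' One-way ANOVA with Dunnett's many-to-one post hoc test
#'
#' Compares every variant against the control using the pooled ANOVA error
#' variance and two-sided Dunnett-adjusted p-values. The adjustment integrates
#' the multivariate t distribution with the product correlation structure
#' `rho_ij = sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))` (equal to 1/2 in a
#' balanced design), using the one-factor decomposition of the equicorrelated
#' normal conditioned on the chi-distributed scale; the integration is
#' deterministic quadrature.
#'
#' @param groups Named list mapping variant id to its per-experiment percent
#'   values; must include `control_id` and at least one other group, each with
#'   n >= 2.
#' @param control_id Name of the control group (the wild-type receptor by
#'   design: the reference variant is 100% in every experiment and carries no
#'   variance).
#' @return A `data.frame` with one row per non-control group: `variant_id`,
#'   `estimate_diff` (group mean minus control mean, percentage points),
#'   `t_value`, `adjusted_p`, `stars`.
#' @export
anova_dunnett <- function(groups, control_id = "WT") {
  if (!is.list(groups) || is.null(names(groups))) {
    stop("'groups' must be a named list of numeric vectors")
  }
  if (!control_id %in% names(groups)) {
    stop(sprintf("control group '%s' is missing", control_id))
  }
  if (length(groups) < 2) stop("need at least two groups (control plus one)")
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least two observations for a pooled variance")
  }
  means <- vapply(groups, mean, numeric(1))
  n_tot <- sum(sizes)
  k <- length(groups)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- n_tot - k
  s2 <- sse / df

  others <- setdiff(names(groups), control_id)
  n0 <- sizes[[control_id]]
  ni <- sizes[others]
  est <- means[others] - means[[control_id]]
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tval <- est / se

  lambda <- unname(sqrt(ni / (ni + n0)))
  m <- length(others)

  adj_p <- vapply(seq_len(m), function(i) {
    if (se[i] == 0) return(as.numeric(est[i] == 0))  # degenerate: no variance
    tt <- abs(tval[i])
    p_inside <- dunnett_prob_inside(tt, lambda, df)
    min(max(1 - p_inside, 0), 1)
  }, numeric(1))

  data.frame(
    variant_id = others,
    estimate_diff = unname(est),
    t_value = unname(tval),
    adjusted_p = adj_p,
    stars = significance_stars(adj_p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
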
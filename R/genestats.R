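#' Sliding-window medians along a ranking variable
#'
#' Stably sorts the records by `sort_key` (ties keep input order) and
#' computes rolling medians of every tracked variable over windows of
#' `window` consecutive observations advanced by `step`, so each point is
#' supported by exactly `window` observations. Intended for visualising
#' trends; correlation coefficients should always be computed on the raw
#' data.
#'
#' @param data A data frame.
#' @param sort_key Name of the numeric ranking column.
#' @param vars Character vector of tracked columns (the sort key itself is
#'   always tracked too).
#' @param window Window width in observations.
#' @param step Step between window starts.
#' @return A tibble of class `"sliding_window_series"`: `window_start`
#'   (rank of the first supporting observation) and one median column per
#'   tracked variable.
#' @export
sliding_window_median <- function(data, sort_key, vars, window = 2000L,
                                  step = 1L) {
  n <- nrow(data)
  if (n < window) {
    abort(sprintf("need at least %d observations, got %d", window, n))
  }
  ord <- order(data[[sort_key]])  # stable for ties
  vars <- union(sort_key, vars)
  meds <- lapply(vars, function(v) {
    zoo::rollapply(data[[v]][ord], width = window, by = step, FUN = median,
                   align = "left")
  })
  out <- tibble(window_start = seq(1L, n - window + 1L, by = step))
  for (i in seq_along(vars)) out[[vars[i]]] <- meds[[i]]
  structure(out, class = c("sliding_window_series", class(out)),
            sort_key = sort_key, window = window, step = step)
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' @param x,y Equal-length numeric vectors.
#' @return A one-row tibble: `tau`, `n`, `p`, `method`. `tau` is `NA`
#'   (flagged via `method`) when either vector has zero variance. P-values
#'   use exact enumeration for n <= 8 without ties and a normal
#'   approximation otherwise.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) abort("need at least two observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(tibble(tau = NA_real_, n = n, p = NA_real_,
                  method = "undefined: zero variance"))
  }
  tau <- cor(x, y, method = "kendall")
  exact <- n <= 8 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = exact))
  tibble(tau = tau, n = n, p = ct$p.value,
         method = if (exact) "tau-b, exact" else "tau-b, normal approx.")
}

#' Partial Kendall correlation of x and y given z
#'
#' tau_xy.z = (tau_xy - tau_xz * tau_yz) /
#' sqrt((1 - tau_xz^2) (1 - tau_yz^2)), each pairwise coefficient being
#' tau-b. The p-value applies the tau normal approximation to the partial
#' coefficient and is approximate.
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return A one-row tibble: `tau`, `n`, `p`, `method`.
#' @export
partial_kendall_tau <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  n <- length(x)
  t_xy <- cor(x, y, method = "kendall")
  t_xz <- cor(x, z, method = "kendall")
  t_yz <- cor(y, z, method = "kendall")
  den <- (1 - t_xz^2) * (1 - t_yz^2)
  if (!is.finite(den) || den <= 0) {
    return(tibble(tau = NA_real_, n = n, p = NA_real_,
                  method = "undefined: |tau| with conditioning variable = 1"))
  }
  tau <- (t_xy - t_xz * t_yz) / sqrt(den)
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  p <- 2 * pnorm(-abs(tau) / se)
  tibble(tau = tau, n = n, p = p, method = "partial tau, normal approx.")
}

#' Kruskal-Wallis rank test across groups
#'
#' @param data A data frame.
#' @param value,group Names of the value and grouping columns.
#' @return A one-row tibble: `H`, `df`, `p`, `n`, `n_groups`. `H` is 0 by
#'   convention when all observations are identical (flagged in `method`).
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (length(unique(v)) == 1) {
    return(tibble(H = 0, df = nlevels(g) - 1L, p = 1, n = length(v),
                  n_groups = nlevels(g),
                  method = "degenerate: all observations identical"))
  }
  kt <- kruskal.test(v, g)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, n = length(v), n_groups = nlevels(g),
         method = "Kruskal-Wallis")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-norm distance between the two empirical CDFs with the asymptotic
#' p-value.
#'
#' @param a,b Numeric samples.
#' @return A one-row tibble: `D`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(D = unname(kt$statistic), p = kt$p.value,
         n_a = length(a), n_b = length(b))
}

#' Pearson chi-square tests without continuity correction
#'
#' `chi_square_independence()` tests independence in a contingency table;
#' `chi_square_gof()` tests observed counts against expected counts.
#'
#' @param table A matrix or table of non-negative counts.
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected == 0)) abort("zero expected cell")
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' @rdname chi_square_independence
#' @param observed,expected Non-negative count vectors; `expected` is
#'   rescaled to the observed total.
#' @export
chi_square_gof <- function(observed, expected) {
  if (any(expected <= 0)) abort("zero expected cell")
  expected <- expected / sum(expected) * sum(observed)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  tibble(statistic = stat, df = df,
         p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Randomization test for nonrandom intron / next-exon association
#'
#' Compares the actual IpE unit size distribution of a positional group
#' with `n_sim` null distributions built by sampling (with replacement,
#' uniformly) equally many introns and next exons from the group's pools
#' and summing their lengths. Each null distribution is compared to the
#' actual one with a two-sample Kolmogorov-Smirnov test; the overall P is
#' the fraction of simulations whose KS test is nonsignificant
#' (p >= `alpha`), i.e. the probability that a random intron-exon pairing
#' is indistinguishable from the observed architecture.
#'
#' @param actual_sizes Observed unit sizes (intron + next exon, nt).
#' @param intron_pool,exon_pool Length pools (nt) of the same positional
#'   group.
#' @param n_sim Number of simulations.
#' @param alpha Significance threshold for each KS test.
#' @param seed RNG seed.
#' @return An object of class `"ipe_randomization"`: per-simulation KS
#'   p-values, `overall_P`, and the call parameters.
#' @export
ipe_randomization_test <- function(actual_sizes, intron_pool, exon_pool,
                                   n_sim = 100000L, alpha = 0.05,
                                   seed = 1L) {
  if (length(intron_pool) == 0 || length(exon_pool) == 0) {
    abort("empty sampling pool")
  }
  m <- length(actual_sizes)
  p_values <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      sim <- intron_pool[sample.int(length(intron_pool), m, replace = TRUE)] +
        exon_pool[sample.int(length(exon_pool), m, replace = TRUE)]
      suppressWarnings(ks.test(sim, actual_sizes, exact = FALSE))$p.value
    }, numeric(1))
  })
  structure(list(p_values = p_values,
                 overall_P = mean(p_values >= alpha),
                 n_sim = n_sim, alpha = alpha, seed = seed,
                 n_actual = m),
            class = "ipe_randomization")
}

#' @export
print.ipe_randomization <- function(x, ...) {
  cat(sprintf(
    "<ipe_randomization> %d simulations, n = %d, alpha = %g\noverall P = %.4g\n",
    x$n_sim, x$n_actual, x$alpha, x$overall_P))
  invisible(x)
}
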
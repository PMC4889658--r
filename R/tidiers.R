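#' Tidy a dense maximum-entropy fit
#'
#' Returns the fitted single-position marginal probabilities.
#'
#' @param x A `maxent_fit`.
#' @param ... Unused.
#' @return A tibble: `position`, `base`, `prob`.
#' @export
tidy.maxent_fit <- function(x, ...) {
  purrr::map(seq_len(x$k), function(p) {
    tibble(position = p, base = BASES,
           prob = as.vector(rowsum(x$prob, grid_index(x$k, p))))
  }) |>
    purrr::list_rbind()
}

#' @rdname tidy.maxent_fit
#' @export
glance.maxent_fit <- function(x, ...) {
  tibble(k = x$k, n_train = x$n_train, n_constraints = length(x$constraints),
         iterations = x$iterations, max_dev = x$max_dev,
         converged = x$converged, pseudocount = x$pseudocount)
}

#' Tidy a splice-site model
#'
#' Per-position signal and background marginals, side by side.
#'
#' @param x A `splice_model`.
#' @param ... Unused.
#' @return A tibble: `position`, `base`, `signal`, `background`.
#' @export
tidy.splice_model <- function(x, ...) {
  marg <- function(m) {
    if (inherits(m, "maxent_fit")) {
      tidy(m)
    } else if (inherits(m, "maxent_factorized")) {
      purrr::map(m$fragments, function(fr) {
        keep <- if (length(fr$overlap) > 0) {
          !fr$positions %in% fr$overlap
        } else {
          rep(TRUE, length(fr$positions))
        }
        tidy(fr$fit) |>
          mutate(position = fr$positions[.data$position]) |>
          filter(.data$position %in% fr$positions[keep])
      }) |>
        purrr::list_rbind()
    } else {
      purrr::map(seq_len(x$k), function(p) {
        tibble(position = p, base = BASES,
               prob = unname(m$base_probs))
      }) |>
        purrr::list_rbind()
    }
  }
  marg(x$signal) |>
    rename(signal = "prob") |>
    left_join(marg(x$background) |> rename(background = "prob"),
              by = c("position", "base"))
}

#' @rdname tidy.splice_model
#' @export
glance.splice_model <- function(x, ...) {
  tibble(site = x$site_kind, k = x$k,
         n_signal = x$signal$n_train %||% NA_integer_,
         n_background = x$background$n_train %||% NA_integer_)
}

#' Tidy an IpE randomization test
#'
#' @param x An `ipe_randomization`.
#' @param ... Unused.
#' @return `tidy()`: one row per simulation (`sim`, `p_value`,
#'   `nonsignificant`); `glance()`: a one-row summary with `overall_P`.
#' @export
tidy.ipe_randomization <- function(x, ...) {
  tibble(sim = seq_len(x$n_sim), p_value = x$p_values,
         nonsignificant = x$p_values >= x$alpha)
}

#' @rdname tidy.ipe_randomization
#' @export
glance.ipe_randomization <- function(x, ...) {
  tibble(overall_P = x$overall_P, n_sim = x$n_sim, alpha = x$alpha,
         n_actual = x$n_actual, seed = x$seed)
}

#' Tidy a co-occurrence table
#'
#' @param x A `cooccurrence_table`.
#' @param ... Unused.
#' @return `tidy()`: the counts in long form; `glance()`: statistic, df,
#'   p, and the degenerate flag.
#' @export
tidy.cooccurrence_table <- function(x, ...) {
  as.data.frame(x$table, responseName = "count") |> as_tibble()
}

#' @rdname tidy.cooccurrence_table
#' @export
glance.cooccurrence_table <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p = x$p, method = x$method,
         degenerate = x$degenerate)
}
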
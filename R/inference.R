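#' Observed double-labelling rate implied by a true divergence rate
#'
#' The binomial double-infection model. With per-jump transfer efficiency `e`,
#' a non-divergent premotor neuron is labelled with probability `e`; a
#' divergent neuron is labelled by each of the two viruses independently with
#' probability `e`, so it is double-labelled with probability `e^2` and
#' labelled at all with probability `2e - e^2`. The observed rate — double
#' labelled over labelled at least once — is therefore
#' \deqn{r = \frac{d e}{1 + d (1 - e)}.}
#' The rate observed in a tracing experiment always understates `d` when
#' `e < 1`, with ceiling `r_max = e / (2 - e)` reached only at `d = 1`.
#'
#' @param d True divergent fraction(s), in `[0, 1]`.
#' @param e Per-jump efficiency, in `(0, 1]`.
#' @return Observed fraction(s) `r`. Vectorised over `d`.
#' @seealso [true_rate()] for the inverse, [mc_observed_rate()] for the Monte
#'   Carlo cross-check.
#' @export
#' @examples
#' observed_rate(0.18, 0.25) # ~0.0397: an 18% true rate looks like 4%
observed_rate <- function(d, e) {
  check_efficiency(e)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    abort("`d` must lie in [0, 1].", class = "divtrace_domain_error")
  }
  d * e / (1 + d * (1 - e))
}

#' True divergence rate recovered from an observed rate
#'
#' Exact algebraic inverse of [observed_rate()]:
#' \deqn{d = \frac{r}{e - r (1 - e)}.}
#' Only observed rates strictly below the model ceiling `e / (2 - e)` are
#' feasible; at or above it (within `1e-9`) no `d` in `[0, 1]` can produce the
#' observation under the assumed efficiency, and an infeasibility error is
#' raised that reports both the ceiling and the minimum efficiency able to
#' explain the data ([implied_min_e()]).
#'
#' @param r Observed fraction(s), `0 <= r < e/(2 - e)`.
#' @param e Per-jump efficiency, in `(0, 1]`.
#' @return True fraction(s) `d`. Vectorised over `r`.
#' @export
#' @examples
#' true_rate(0.04, 0.25) # 0.1818...: the observed 4% implies 18% true
true_rate <- function(r, e) {
  check_efficiency(e)
  if (any(!is.finite(r)) || any(r < 0)) {
    abort("`r` must be non-negative.", class = "divtrace_domain_error")
  }
  r_max <- e / (2 - e)
  bad <- r >= r_max - 1e-9
  if (any(bad)) {
    abort(
      sprintf(paste0(
        "observed rate %.6g is not feasible under efficiency e = %.4g: ",
        "the model ceiling is e/(2-e) = %.6g; explaining this rate requires ",
        "e >= %.4g."),
        max(r[bad]), e, r_max, implied_min_e(max(r[bad]))),
      class = "divtrace_infeasible_error"
    )
  }
  r / (e - r * (1 - e))
}

#' Minimum efficiency consistent with an observed rate
#'
#' Solves `r = e/(2 - e)` for `e`: the smallest per-jump efficiency under
#' which an observed double-labelling rate `r` is attainable (at `d = 1`).
#' Useful for populations whose observed rates exceed the ceiling of an
#' assumed efficiency.
#'
#' @param r Observed fraction(s) in `[0, 1]`.
#' @return Efficiency bound(s) `2r / (1 + r)`.
#' @export
#' @examples
#' implied_min_e(0.45) # cervical-like observed rates need e >= 0.62
implied_min_e <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    abort("`r` must lie in [0, 1].", class = "divtrace_domain_error")
  }
  2 * r / (1 + r)
}

check_efficiency <- function(e) {
  if (length(e) != 1L || !is.finite(e) || e <= 0 || e > 1) {
    abort("`e` must be a single efficiency in (0, 1].",
          class = "divtrace_domain_error")
  }
}

#' Monte Carlo estimate of the observed rate
#'
#' Forward-simulates the double-injection experiment: per replicate, `n`
#' neurons are divergent with probability `d`; each neuron-to-pool connection
#' transmits with probability `e` independently (no interference); the
#' replicate's observed rate is double-labelled over labelled. Converges to
#' [observed_rate()] and serves as its independent cross-check.
#'
#' @param d True divergent fraction.
#' @param e Per-jump efficiency.
#' @param n Population size per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return A one-row tibble: `mean` and `sd` of the replicate rates, `se`
#'   (standard error of the mean), percentile `ci_low`/`ci_high` (2.5/97.5%),
#'   `n_zero_label` replicates with no labelled neuron (excluded from the
#'   averages, not counted as zero rate), `n`, `reps`.
#' @export
#' @examples
#' mc_observed_rate(0.18, 0.25, n = 1e5, reps = 50, seed = 1)
mc_observed_rate <- function(d, e, n, reps = 100L, seed) {
  check_efficiency(e)
  if (length(d) != 1L || !is.finite(d) || d < 0 || d > 1) {
    abort("`d` must lie in [0, 1].", class = "divtrace_domain_error")
  }
  if (n < 1 || reps < 1) {
    abort("`n` and `reps` must be >= 1.", class = "divtrace_domain_error")
  }
  rates <- withr::with_seed(as.integer(seed), {
    n_div <- rbinom(reps, n, d)
    # Divergent: both labels w.p. e^2; exactly one w.p. 2e(1-e), i.e.
    # conditional on not-both, 2e(1-e)/(1-e^2) = 2e/(1+e).
    dbl <- rbinom(reps, n_div, e^2)
    one <- rbinom(reps, n_div - dbl, 2 * e / (1 + e))
    nondiv <- rbinom(reps, n - n_div, e)
    labelled <- dbl + one + nondiv
    ifelse(labelled > 0, dbl / labelled, NA_real_)
  })
  ok <- rates[!is.na(rates)]
  tibble::tibble(
    mean = mean(ok),
    sd = sd(ok),
    se = sd(ok) / sqrt(length(ok)),
    ci_low = unname(quantile(ok, 0.025)),
    ci_high = unname(quantile(ok, 0.975)),
    n_zero_label = sum(is.na(rates)),
    n = as.integer(n),
    reps = as.integer(reps)
  )
}

#' Observed-vs-true divergence curve
#'
#' Evaluates [observed_rate()] on a grid of true rates at a fixed efficiency —
#' the sensitivity curve relating what a dual-colour tracing experiment
#' reports to what the circuit actually contains. Strictly increasing in `d`.
#'
#' @param e Per-jump efficiency.
#' @param d_grid Ordered true-rate grid in `[0, 1]`.
#' @return A tibble of class `divergence_curve` with columns `d`, `r`, `e`.
#' @export
#' @examples
#' autoplot(divergence_curve(0.25))
divergence_curve <- function(e, d_grid = seq(0, 1, by = 0.01)) {
  r <- observed_rate(d_grid, e)
  out <- tibble::tibble(d = d_grid, r = r, e = e)
  class(out) <- c("divergence_curve", class(out))
  out
}

#' @rdname divergence_curve
#' @param object A `divergence_curve`.
#' @param ... Unused.
#' @method autoplot divergence_curve
#' @export
autoplot.divergence_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "true rate of divergence d",
      y = "observed rate of divergence r",
      title = sprintf("Binomial double-infection model, e = %.2f",
                      object$e[1])
    ) +
    ggplot2::theme_minimal()
}
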
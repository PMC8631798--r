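#' Compare soma cross-sectional areas across groups
#'
#' Rank-based comparison of soma areas (um^2) between cell populations, as
#' used to contrast large divergent cervical propriospinal neurons with
#' thoracic and lumbar divergent interneurons. Runs a Kruskal-Wallis test
#' across all groups, Dunn's pairwise post-hoc z tests with Bonferroni
#' adjustment, and — when exactly two groups are compared — a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. Tests use the normal approximation
#' with tie correction; descriptives are mean +/- SD on the raw scale.
#'
#' @param data Data frame of cells.
#' @param area Column of soma areas (tidy-eval), default `soma_area`.
#' @param group Grouping column (tidy-eval), default `region`.
#'
#' @return An object of class `soma_stats`: use [tidy()] for the pairwise
#'   table, [glance()] for the omnibus test, `$descriptives` for per-group
#'   mean/SD/n. Groups with fewer than 2 values are dropped with a warning.
#' @export
#' @examples
#' df <- data.frame(
#'   region = rep(c("cervical", "lumbar"), c(10, 10)),
#'   soma_area = c(rlnorm(10, log(700), 0.3), rlnorm(10, log(320), 0.3))
#' )
#' stats <- soma_area_stats(df)
#' glance(stats)
soma_area_stats <- function(data, area = soma_area, group = region) {
  df <- tibble::as_tibble(data) |>
    dplyr::transmute(
      group = as.character({{ group }}),
      area = as.numeric({{ area }})
    ) |>
    dplyr::filter(is.finite(.data$area))

  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("dropping group(s) with < 2 values: ",
                paste(small, collapse = ", ")))
    df <- dplyr::filter(df, !.data$group %in% small)
  }
  groups <- unique(df$group)
  if (length(groups) < 2) {
    abort("need at least two groups with >= 2 values each.",
          class = "divtrace_config_error")
  }

  descriptives <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$area),
      sd = sd(.data$area),
      median = stats::median(.data$area),
      .groups = "drop"
    )

  kw <- stats::kruskal.test(area ~ group, data = df)
  pairwise <- dunn_test(df$area, df$group)
  mw <- NULL
  if (length(groups) == 2) {
    mw <- suppressWarnings(stats::wilcox.test(
      df$area[df$group == groups[1]], df$area[df$group == groups[2]],
      alternative = "two.sided", correct = TRUE
    ))
  }

  structure(
    list(
      descriptives = descriptives,
      kruskal = list(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p_value = kw$p.value),
      dunn = pairwise,
      mann_whitney = if (!is.null(mw)) {
        list(statistic = unname(mw$statistic), p_value = mw$p.value,
             groups = groups)
      },
      adjustment = "bonferroni"
    ),
    class = "soma_stats"
  )
}

# Dunn's post-hoc test on pooled ranks with tie correction; p-values are
# two-sided normal with Bonferroni adjustment across the m = k(k-1)/2 pairs.
dunn_test <- function(x, g) {
  g <- as.character(g)
  n <- length(x)
  r <- rank(x)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  groups <- sort(unique(g))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- purrr::map(pairs, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[p[1]]] + 1 / ni[[p[2]]]))
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) / se
    tibble::tibble(group1 = p[1], group2 = p[2], z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  }) |> purrr::list_rbind()
  res$p_adjusted <- pmin(1, res$p_value * length(pairs))
  res
}

#' @export
print.soma_stats <- function(x, ...) {
  cat("<soma_stats>\n")
  cat(sprintf("Kruskal-Wallis: chi^2 = %.3f, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  print(x$descriptives)
  cat("Dunn pairwise (", x$adjustment, "-adjusted):\n", sep = "")
  print(x$dunn)
  if (!is.null(x$mann_whitney)) {
    cat(sprintf("Mann-Whitney (%s vs %s): W = %.1f, p = %.3g\n",
                x$mann_whitney$groups[1], x$mann_whitney$groups[2],
                x$mann_whitney$statistic, x$mann_whitney$p_value))
  }
  invisible(x)
}

#' @rdname soma_area_stats
#' @param x A `soma_stats` object.
#' @param ... Unused.
#' @method tidy soma_stats
#' @export
tidy.soma_stats <- function(x, ...) {
  x$dunn
}

#' @rdname soma_area_stats
#' @method glance soma_stats
#' @export
glance.soma_stats <- function(x, ...) {
  tibble::tibble(
    statistic = x$kruskal$statistic,
    df = x$kruskal$df,
    p_value = x$kruskal$p_value,
    n_groups = nrow(x$descriptives),
    mw_p_value = if (is.null(x$mann_whitney)) NA_real_ else x$mann_whitney$p_value
  )
}
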
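#' Paired early-versus-late comparison of all features
#'
#' For every catalogue feature and every eligible group (`all`, and
#' each of `benign`/`malignant` with at least `min_n` patients):
#' medians and min-max ranges at each time point, the two-sided paired
#' Wilcoxon signed-rank p, the Spearman correlation between time
#' points, and a direction arrow (`up`/`down`) set from the sign of the
#' median paired difference only when `p < alpha` (ties break to
#' `none`). Patients lacking either time point for a feature are
#' dropped pairwise. No multiple-testing correction is applied; the
#' result records the number of tests performed so the family-wise
#' exposure is visible.
#'
#' @param features tibble from [extract_cohort_features()].
#' @param alpha significance level (default 0.05).
#' @param exact_max,zeros passed to [wilcoxon_signed_rank()].
#' @param min_n minimum patients per group (default 5).
#' @return A `timepoint_comparison` object: list with `table` (tibble
#'   of comparison rows), `n_tests`, `alpha`, `groups`, `n_patients`.
#' @export
compare_timepoints <- function(features, alpha = 0.05, exact_max = 25,
                               zeros = "discard", min_n = 5) {
  cat_tbl <- feature_catalog()
  stopifnot(all(c("patient_id", "timepoint") %in% names(features)),
            all(cat_tbl$feature %in% names(features)))
  if (!"group" %in% names(features)) features$group <- "unknown"

  wide <- features |>
    dplyr::select(dplyr::all_of(c("patient_id", "group", "timepoint",
                                  cat_tbl$feature))) |>
    tidyr::pivot_longer(dplyr::all_of(cat_tbl$feature),
                        names_to = "feature", values_to = "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")

  groups <- list(all = unique(wide$patient_id))
  for (g in c("benign", "malignant")) {
    ids <- unique(wide$patient_id[wide$group == g])
    if (length(ids) >= min_n) {
      groups[[g]] <- ids
    } else if (length(ids) > 0) {
      warning("group '", g, "' has fewer than ", min_n,
              " patients; skipped", call. = FALSE)
    }
  }

  rows <- list()
  for (gname in names(groups)) {
    sub <- wide[wide$patient_id %in% groups[[gname]], ]
    for (f in cat_tbl$feature) {
      fs <- sub[sub$feature == f, ]
      ok <- is.finite(fs$early) & is.finite(fs$late)
      e <- fs$early[ok]; l <- fs$late[ok]
      if (length(e) < min_n) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          feature = f,
          family = cat_tbl$family[cat_tbl$feature == f],
          group = gname, n = length(e),
          early_median = NA_real_, early_min = NA_real_,
          early_max = NA_real_, late_median = NA_real_,
          late_min = NA_real_, late_max = NA_real_,
          direction = "none", wilcoxon_p = NA_real_,
          spearman_r = NA_real_, spearman_p = NA_real_)
        next
      }
      # features with fewer than 5 nonzero differences are untestable;
      # carry them as NA rather than aborting the cohort table
      wt <- tryCatch(
        wilcoxon_signed_rank(e, l, exact_max = exact_max, zeros = zeros),
        error = function(err) list(p = NA_real_, statistic = NA_real_))
      sp <- tryCatch(spearman_rank(e, l),
                     error = function(err) list(r = NA_real_, p = NA_real_))
      med_diff <- median(l - e)
      dir <- "none"
      if (is.finite(wt$p) && wt$p < alpha && med_diff != 0) {
        dir <- if (med_diff > 0) "up" else "down"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = f, family = cat_tbl$family[cat_tbl$feature == f],
        group = gname, n = length(e),
        early_median = median(e), early_min = min(e), early_max = max(e),
        late_median = median(l), late_min = min(l), late_max = max(l),
        direction = dir, wilcoxon_p = wt$p,
        spearman_r = sp$r, spearman_p = sp$p)
    }
  }
  tab <- dplyr::bind_rows(rows)
  structure(list(table = tab,
                 n_tests = sum(!is.na(tab$wilcoxon_p)),
                 alpha = alpha,
                 groups = names(groups),
                 n_patients = vapply(groups, length, integer(1))),
            class = "timepoint_comparison")
}

#' @export
print.timepoint_comparison <- function(x, ...) {
  cat(sprintf("<timepoint_comparison> %d features x %d group(s), %d tests, alpha = %g\n",
              length(unique(x$table$feature)), length(x$groups),
              x$n_tests, x$alpha))
  fs <- summarize_families(x)
  print(fs, n = nrow(fs))
  invisible(x)
}

#' Family-wise counts of significant changes
#'
#' Counts, per feature family and group, how many features changed
#' significantly between time points and in which direction; the
#' denominators are the fixed family sizes 37/25/31/6 and `up + down`
#' always equals the significant count.
#'
#' @param x a `timepoint_comparison`.
#' @return Tibble with columns `group`, `family`, `family_size`,
#'   `n_significant`, `n_up`, `n_down` (plus a `total` family row per
#'   group).
#' @export
summarize_families <- function(x) {
  stopifnot(inherits(x, "timepoint_comparison"))
  sizes <- feature_family_sizes()
  fam_levels <- c(names(sizes), "total")
  out <- x$table |>
    dplyr::group_by(.data$group, .data$family) |>
    dplyr::summarise(
      n_significant = sum(.data$direction != "none"),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop") |>
    dplyr::mutate(family_size = as.integer(sizes[.data$family]))
  tot <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(family = "total",
                     n_significant = sum(.data$n_significant),
                     n_up = sum(.data$n_up),
                     n_down = sum(.data$n_down),
                     family_size = sum(.data$family_size),
                     .groups = "drop")
  dplyr::bind_rows(out, tot) |>
    dplyr::mutate(family = factor(.data$family, levels = fam_levels)) |>
    dplyr::arrange(.data$group, .data$family) |>
    dplyr::select(dplyr::all_of(c("group", "family", "family_size",
                                  "n_significant", "n_up", "n_down")))
}

#' Tidy a paired comparison
#'
#' @param x a `timepoint_comparison`.
#' @param ... unused.
#' @return The comparison table as a tibble, one row per feature x
#'   group.
#' @export
tidy.timepoint_comparison <- function(x, ...) x$table

#' One-row summary of a paired comparison
#'
#' @inheritParams tidy.timepoint_comparison
#' @return Tibble with `n_features`, `n_groups`, `n_tests`, `alpha`,
#'   `n_significant_all`, `mean_spearman_r_all`.
#' @export
glance.timepoint_comparison <- function(x, ...) {
  alltab <- x$table[x$table$group == "all", ]
  tibble::tibble(
    n_features = length(unique(x$table$feature)),
    n_groups = length(x$groups),
    n_tests = x$n_tests,
    alpha = x$alpha,
    n_significant_all = sum(alltab$direction != "none"),
    mean_spearman_r_all = mean(alltab$spearman_r, na.rm = TRUE))
}

#' Plot a paired comparison
#'
#' Volcano-style display: per feature, the relative change of the
#' median between time points against `-log10` of the Wilcoxon p,
#' coloured by feature family, one panel per group; the dashed line
#' marks the significance level.
#'
#' @param object a `timepoint_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.timepoint_comparison <- function(object, ...) {
  tab <- object$table |>
    dplyr::filter(is.finite(.data$wilcoxon_p),
                  is.finite(.data$early_median),
                  .data$early_median != 0) |>
    dplyr::mutate(
      rel_change = (.data$late_median - .data$early_median) /
        abs(.data$early_median),
      neg_log_p = -log10(pmax(.data$wilcoxon_p, 1e-12)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rel_change,
                                    y = .data$neg_log_p,
                                    colour = .data$family)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "relative change of median (late vs early)",
                  y = expression(-log[10] ~ "Wilcoxon p"),
                  colour = "family") +
    ggplot2::theme_minimal()
}

#' Plot family-wise significance counts
#'
#' @param x a `timepoint_comparison`.
#' @return A ggplot bar chart of up/down counts per family and group.
#' @export
plot_family_summary <- function(x) {
  fs <- summarize_families(x) |>
    dplyr::filter(.data$family != "total") |>
    tidyr::pivot_longer(dplyr::all_of(c("n_up", "n_down")),
                        names_to = "direction", values_to = "count")
  ggplot2::ggplot(fs, ggplot2::aes(x = .data$family, y = .data$count,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~group) +
    ggplot2::theme_minimal()
}

write_markdown_report <- function(x, path) {
  tab <- tidy(x)
  fs <- summarize_families(x)
  lines <- c(
    "# Paired early/late texture comparison", "",
    sprintf("Tests performed: %d at alpha = %g (no multiplicity correction).",
            x$n_tests, x$alpha), "",
    "## Family summary", "",
    "| group | family | significant | up | down |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %d/%d | %d | %d |", fs$group, fs$family,
            fs$n_significant, fs$family_size, fs$n_up, fs$n_down),
    "", "## Per-feature results (group: all)", "",
    "| feature | early median (range) | late median (range) | dir | p | r |",
    "|---|---|---|---|---|---|")
  at <- tab[tab$group == "all", ]
  fmt <- function(m, lo, hi) sprintf("%.4g (%.4g-%.4g)", m, lo, hi)
  lines <- c(lines, sprintf(
    "| %s | %s | %s | %s | %.3g | %.2f |", at$feature,
    fmt(at$early_median, at$early_min, at$early_max),
    fmt(at$late_median, at$late_min, at$late_max),
    c(none = "-", up = "↑", down = "↓")[at$direction],
    at$wilcoxon_p, at$spearman_r))
  writeLines(lines, path)
  invisible(path)
}
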
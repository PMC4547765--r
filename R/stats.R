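#' Rank-transform a vector
#'
#' Ascending ranks 1..n with midranks for ties, applied before parametric
#' analysis of non-parametric outcomes (e.g. ordinal behavioural scores).
#' Missing values stay missing and do not consume ranks.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector of ranks, same length, NAs preserved.
#' @export
rank_transform <- function(values) {
  if (!any(is.finite(values))) abort("rank_transform needs at least one finite value")
  rank(values, ties.method = "average", na.last = "keep")
}

#' Balanced split-plot (two-way mixed-design) repeated-measures ANOVA
#'
#' Classical partition for a design with one between-subject factor (group),
#' one within-subject factor (time) and a balanced, complete layout:
#' \deqn{SS_{total} = SS_{group} + SS_{subj(group)} + SS_{time} +
#'       SS_{group \times time} + SS_{residual}}
#' The group effect is tested against the subject-within-group mean square,
#' time and the interaction against the residual mean square; p-values come
#' from the F distribution with the matching degrees of freedom
#' (`g-1, g(s-1)` for group; `t-1` and `(g-1)(t-1)` over `g(s-1)(t-1)` for
#' time and interaction). No sphericity correction is applied by default.
#'
#' @param table longitudinal tibble (see [make_cohort_table()]).
#' @param measure which measure to analyse (default: the only one present).
#' @param value_col column holding the response: `"value"` or
#'   `"normalized_value"`.
#' @param ranked rank-transform the response first (midranks).
#' @return object of class `mixed_anova`: `anova` tibble (effect, ss, df,
#'   ms, F, p), `design` (g, s, t, labels), `cell_means`, and the grand mean.
#' @export
mixed_anova <- function(table, measure = NULL, value_col = c("value", "normalized_value"),
                        ranked = FALSE) {
  value_col <- match.arg(value_col)
  check_longitudinal(table)
  measures <- unique(table$measure)
  measure <- measure %||% {
    if (length(measures) > 1L) abort("several measures present; pick one with `measure`")
    measures
  }
  tab <- dplyr::filter(table, .data$measure == !!measure)
  if (nrow(tab) == 0L) abort(sprintf("no records for measure '%s'", measure))
  if (!value_col %in% names(tab)) abort(sprintf("column '%s' not found", value_col))
  y_all <- tab[[value_col]]
  if (anyNA(y_all)) abort("missing responses: run complete_case_filter() first")
  if (isTRUE(ranked)) y_all <- rank_transform(y_all)
  tab$.y <- y_all

  groups <- unique(tab$group)
  times <- if (is.factor(tab$time)) levels(droplevels(tab$time)) else unique(as.character(tab$time))
  g <- length(groups); t <- length(times)
  if (g < 2L) abort("need >= 2 groups")
  if (t < 2L) abort("need >= 2 time points")

  # balance check: every subject seen at every time, equal subjects per group
  cells <- tab |>
    dplyr::count(.data$subject, .data$group, time = as.character(.data$time))
  wide_n <- tidyr::pivot_wider(cells, names_from = "time", values_from = "n")
  bad <- wide_n |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(times), ~ is.na(.x) | .x != 1L))
  per_group <- dplyr::count(dplyr::distinct(tab, .data$subject, .data$group), .data$group)
  if (nrow(bad) > 0L || dplyr::n_distinct(per_group$n) != 1L) {
    offenders <- if (nrow(bad)) paste(bad$subject, collapse = ", ") else
      paste(sprintf("%s: n=%d", per_group$group, per_group$n), collapse = "; ")
    abort(paste0("design is unbalanced or incomplete (", offenders, ")"))
  }
  s <- per_group$n[1L]
  if (s < 2L) abort("need >= 2 subjects per group")

  y <- tab$.y
  grand <- mean(y)
  grp_of <- tab$group
  tim_of <- as.character(tab$time)
  sub_of <- tab$subject
  m_group <- tapply(y, grp_of, mean)[groups]
  m_time <- tapply(y, tim_of, mean)[times]
  m_subj <- tapply(y, sub_of, mean)
  m_cell <- tapply(y, list(grp_of, tim_of), mean)[groups, times, drop = FALSE]
  subj_grp <- tapply(grp_of, sub_of, function(x) x[1L])

  ss_group <- s * t * sum((m_group - grand)^2)
  ss_subj <- t * sum((m_subj - m_group[subj_grp[names(m_subj)]])^2)
  ss_time <- g * s * sum((m_time - grand)^2)
  ss_int <- s * sum((m_cell - outer(m_group, rep(1, t)) -
                       outer(rep(1, g), m_time) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_group - ss_subj - ss_time - ss_int

  df <- c(group = g - 1L, subj = g * (s - 1L), time = t - 1L,
          int = (g - 1L) * (t - 1L), resid = g * (s - 1L) * (t - 1L))
  ms <- c(ss_group, ss_subj, ss_time, ss_int, max(ss_resid, 0)) / df
  f_group <- ms[1L] / ms[2L]
  f_time <- ms[3L] / ms[5L]
  f_int <- ms[4L] / ms[5L]

  anova_tbl <- tibble::tibble(
    effect = c("group", "subject_within_group", "time", "group_x_time", "residual"),
    ss = unname(c(ss_group, ss_subj, ss_time, ss_int, max(ss_resid, 0))),
    df = unname(as.integer(df)),
    ms = unname(ms),
    statistic = unname(c(f_group, NA, f_time, f_int, NA)),
    p.value = unname(c(
      pf(f_group, df[1L], df[2L], lower.tail = FALSE), NA,
      pf(f_time, df[3L], df[5L], lower.tail = FALSE),
      pf(f_int, df[4L], df[5L], lower.tail = FALSE), NA
    ))
  )
  structure(
    list(
      anova = anova_tbl,
      design = list(g = g, s = s, t = t, groups = groups, times = times,
                    measure = measure, value_col = value_col),
      cell_means = m_cell,
      grand_mean = grand,
      ss_total = ss_total,
      table = tab
    ),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  d <- x$design
  cat(sprintf("Split-plot repeated-measures ANOVA: %s (%d groups x %d subjects x %d times)\n",
              d$measure, d$g, d$s, d$t))
  a <- x$anova
  for (i in which(!is.na(a$statistic))) {
    df1 <- a$df[i]
    df2 <- if (a$effect[i] == "group") a$df[a$effect == "subject_within_group"] else
      a$df[a$effect == "residual"]
    cat(sprintf("  %-13s F(%d,%d) = %.3f, p = %.3f\n",
                a$effect[i], df1, df2, a$statistic[i], a$p.value[i]))
  }
  invisible(x)
}

#' Fisher's LSD post-hoc group comparison at each time point
#'
#' Compares the two group means at every within-subject level with
#' unadjusted (LSD-convention) t-tests. Because a between-group contrast at
#' a fixed time mixes both error strata, the default error term is the
#' combined mean square
#' `MS_cell = (MS_subj(group) + (t - 1) * MS_residual) / t` with
#' Satterthwaite degrees of freedom; `error = "per_time"` instead runs a
#' plain unpaired t-test on each time point's values.
#'
#' @param anova a [mixed_anova()] result.
#' @param alpha significance level for the `significant` flag.
#' @param error `"combined"` (default) or `"per_time"`.
#' @return tibble of class `fisher_lsd`, one row per time: `time`,
#'   `estimate` (group mean difference, second minus first group), `se`,
#'   `statistic`, `df`, `p.value`, `significant`.
#' @export
fisher_lsd <- function(anova, alpha = 0.05, error = c("combined", "per_time")) {
  error <- match.arg(error)
  if (!inherits(anova, "mixed_anova")) abort("`anova` must be a mixed_anova result")
  d <- anova$design
  if (d$g != 2L) abort("Fisher's LSD here supports the two-arm design only")
  tab <- anova$table
  n <- d$s

  if (error == "combined") {
    a <- anova$anova
    ms_subj <- a$ms[a$effect == "subject_within_group"]
    ms_res <- a$ms[a$effect == "residual"]
    df_subj <- a$df[a$effect == "subject_within_group"]
    df_res <- a$df[a$effect == "residual"]
    t_lev <- d$t
    ms_cell <- (ms_subj + (t_lev - 1) * ms_res) / t_lev
    # Satterthwaite df of the combined mean square
    df_sw <- if (ms_cell == 0) df_subj else {
      (ms_subj + (t_lev - 1) * ms_res)^2 /
        (ms_subj^2 / df_subj + ((t_lev - 1) * ms_res)^2 / df_res)
    }
    se <- sqrt(ms_cell * (2 / n))
  }

  rows <- purrr::map_dfr(d$times, function(tp) {
    yt <- tab |> dplyr::filter(as.character(.data$time) == tp)
    m1 <- mean(yt$.y[yt$group == d$groups[1L]])
    m2 <- mean(yt$.y[yt$group == d$groups[2L]])
    diff <- m2 - m1
    if (error == "per_time") {
      tt <- unpaired_t(yt$.y[yt$group == d$groups[2L]], yt$.y[yt$group == d$groups[1L]])
      tibble::tibble(time = tp, estimate = diff, se = tt$se,
                     statistic = tt$statistic, df = tt$df, p.value = tt$p.value)
    } else {
      stat <- if (se == 0) {
        if (diff == 0) 0 else sign(diff) * Inf
      } else diff / se
      tibble::tibble(
        time = tp, estimate = diff, se = se, statistic = stat, df = df_sw,
        p.value = if (is.infinite(stat)) 0 else 2 * pt(abs(stat), df_sw, lower.tail = FALSE)
      )
    }
  })
  rows$significant <- rows$p.value < alpha
  class(rows) <- c("fisher_lsd", class(rows))
  attr(rows, "alpha") <- alpha
  attr(rows, "groups") <- d$groups
  rows
}

#' Pooled-variance unpaired t-test
#'
#' Two-sided two-sample t-test with pooled variance (the classical test used
#' for per-group endpoint comparisons such as histology). Degenerate inputs
#' are handled explicitly: zero pooled variance with equal means gives
#' p = 1; with unequal means the statistic is infinite, p = 0, and the
#' result is flagged degenerate.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return tibble: `estimate` (mean(a) - mean(b)), `se`, `statistic`, `df`,
#'   `p.value`, `degenerate`.
#' @export
unpaired_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs n >= 2")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2L
  if (sp2 == 0) {
    diff <- mean(a) - mean(b)
    return(tibble::tibble(
      estimate = diff, se = 0,
      statistic = if (diff == 0) 0 else sign(diff) * Inf,
      df = df, p.value = if (diff == 0) 1 else 0,
      degenerate = TRUE
    ))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    estimate = mean(a) - mean(b),
    se = sqrt(sp2 * (1 / length(a) + 1 / length(b))),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    degenerate = FALSE
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @describeIn mixed_anova tidy method: the ANOVA table as a tibble.
#' @param x a `mixed_anova` object.
#' @param ... unused.
#' @export
tidy.mixed_anova <- function(x, ...) x$anova

#' @describeIn mixed_anova glance method: one-row design/F summary.
#' @export
glance.mixed_anova <- function(x, ...) {
  a <- x$anova
  tibble::tibble(
    measure = x$design$measure,
    n_groups = x$design$g, n_subjects = x$design$g * x$design$s,
    n_times = x$design$t,
    F_group = a$statistic[a$effect == "group"],
    p_group = a$p.value[a$effect == "group"],
    F_time = a$statistic[a$effect == "time"],
    p_time = a$p.value[a$effect == "time"],
    F_interaction = a$statistic[a$effect == "group_x_time"],
    p_interaction = a$p.value[a$effect == "group_x_time"]
  )
}

#' Plain-text report of an ANOVA with post-hoc rows
#'
#' Formats each effect as `F(df1,df2) = x, p = y` to three decimals, with
#' one line per post-hoc comparison.
#'
#' @param anova a [mixed_anova()] result.
#' @param posthoc optional [fisher_lsd()] result.
#' @return character vector of report lines (also printed).
#' @export
report_anova <- function(anova, posthoc = NULL) {
  a <- anova$anova
  d <- anova$design
  df2 <- function(eff) if (eff == "group") a$df[a$effect == "subject_within_group"] else
    a$df[a$effect == "residual"]
  lines <- c(
    sprintf("Measure: %s (%d x %d x %d split-plot)", d$measure, d$g, d$s, d$t),
    vapply(c("group", "time", "group_x_time"), function(eff) {
      i <- which(a$effect == eff)
      sprintf("  %s: F(%d,%d) = %.3f, p = %.3f", eff, a$df[i], df2(eff),
              a$statistic[i], a$p.value[i])
    }, character(1))
  )
  if (!is.null(posthoc)) {
    lines <- c(lines, "  post-hoc (Fisher's LSD):",
               sprintf("    %s: diff = %.3f, t(%.1f) = %.3f, p = %.3f%s",
                       posthoc$time, posthoc$estimate, posthoc$df,
                       posthoc$statistic, posthoc$p.value,
                       ifelse(posthoc$significant, " *", "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
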
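#' ROI mask on a parameter-map grid
#'
#' @param voxels integer matrix (n x 3) of 1-based voxel indices, or a
#'   logical 3D array.
#' @param region region name (e.g. `"hippocampus"`, `"internal_capsule"`,
#'   `"cerebellum"`).
#' @param side `"left"`, `"right"` or `"midline"`.
#' @param dim grid dimensions (required when `voxels` is an index matrix).
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, region, side = c("midline", "left", "right"), dim = NULL) {
  side <- match.arg(side)
  if (is.array(voxels) && length(dim(voxels)) == 3L) {
    dim <- dim(voxels)
    voxels <- which(array(as.logical(voxels), dim), arr.ind = TRUE)
  } else {
    voxels <- as.matrix(voxels)
    if (ncol(voxels) != 3L) abort("`voxels` must be an n x 3 index matrix or a 3D logical array")
    if (is.null(dim)) abort("`dim` is required with an index matrix")
  }
  if (nrow(voxels) == 0L) abort("ROI is empty")
  if (any(voxels < 1L) || any(voxels > matrix(dim, nrow(voxels), 3L, byrow = TRUE))) {
    abort("ROI voxels fall outside the volume bounds")
  }
  structure(list(voxels = voxels, region = region, side = side, dim = as.integer(dim)),
            class = "roi_mask")
}

#' Mean parameter value over an ROI
#'
#' Arithmetic mean of a parameter map over the ROI voxels, excluding voxels
#' whose fit failed (non-zero failure code or missing value); the number of
#' voxels actually used is reported.
#'
#' @param maps a [fit_volume()] result (`param_maps`).
#' @param mask an [roi_mask()] on the same grid.
#' @param measure `"MD"`, `"FA"` or `"MK"`.
#' @return tibble with one row: `region`, `side`, `measure`, `value`
#'   (NA with a `reason` if every voxel is unusable), `n_used`, `n_excluded`.
#' @export
extract_roi_mean <- function(maps, mask, measure = c("MK", "MD", "FA")) {
  measure <- match.arg(measure)
  if (!inherits(maps, "param_maps")) abort("`maps` must be a param_maps object")
  if (!inherits(mask, "roi_mask")) abort("`mask` must be an roi_mask")
  if (!identical(mask$dim, dim(maps$md))) abort("mask grid does not match map grid")
  m <- switch(measure, MD = maps$md, FA = maps$fa, MK = maps$mk)
  vals <- m[mask$voxels]
  codes <- maps$codes[mask$voxels]
  ok <- !is.na(vals) & !is.na(codes) & codes %in% c(FIT_OK, FIT_CLAMPED)
  tibble::tibble(
    region = mask$region,
    side = mask$side,
    measure = measure,
    value = if (any(ok)) mean(vals[ok]) else NA_real_,
    n_used = sum(ok),
    n_excluded = sum(!ok),
    reason = if (any(ok)) NA_character_ else "all ROI voxels flagged"
  )
}

#' Average bilateral ROI values
#'
#' The left/right values of a bilaterally placed ROI are averaged into one
#' per-region value (improving sensitivity, since the insult is midline with
#' no lateral preference); when only one side is available it passes through
#' with the unilateral use recorded.
#'
#' @param left,right the two side values (either may be `NA`).
#' @return tibble: `value`, `n_sides`, `unilateral`.
#' @export
bilateral_average <- function(left, right) {
  vals <- c(left, right)
  if (all(is.na(vals))) {
    return(tibble::tibble(value = NA_real_, n_sides = 0L, unilateral = NA))
  }
  tibble::tibble(
    value = mean(vals, na.rm = TRUE),
    n_sides = sum(!is.na(vals)),
    unilateral = sum(!is.na(vals)) == 1L
  )
}

#' Normalize a longitudinal table to each subject's baseline
#'
#' Adds `normalized_value = value / baseline value` within every subject x
#' region x measure series, so baseline rows normalize to exactly 1. Series
#' whose baseline is missing or zero are marked non-normalizable
#' (`normalized_value = NA`).
#'
#' @param table longitudinal tibble with columns `subject`, `group`, `time`,
#'   `region`, `measure`, `value`.
#' @param baseline_label the time label that holds the pre-injury scan.
#' @return the table with `normalized_value` added.
#' @export
normalize_to_baseline <- function(table, baseline_label = "baseline") {
  check_longitudinal(table)
  if (!baseline_label %in% as.character(table$time)) {
    abort(sprintf("no '%s' records in the table", baseline_label))
  }
  table |>
    dplyr::group_by(.data$subject, .data$region, .data$measure) |>
    dplyr::mutate(
      .baseline = {
        b <- .data$value[as.character(.data$time) == baseline_label]
        if (length(b) == 1L && !is.na(b) && b != 0) b else NA_real_
      },
      normalized_value = .data$value / .data$.baseline
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".baseline")
}

#' Keep only subjects observed at every required time point
#'
#' Mirrors the study inclusion rule: a subject is retained only if it has a
#' record at every required time for every measure present in the table.
#' The dropped subjects are attached as the `"dropped"` attribute. The
#' filter is idempotent.
#'
#' @param table longitudinal tibble.
#' @param required_times character vector of time labels that must all be
#'   present; defaults to every level in the table.
#' @return filtered tibble, with attribute `dropped` naming removed subjects.
#' @export
complete_case_filter <- function(table, required_times = NULL) {
  check_longitudinal(table)
  required_times <- required_times %||% unique(as.character(table$time))
  if (length(required_times) == 0L) abort("`required_times` must be non-empty")
  status <- table |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::distinct(.data$subject, .data$measure, time = as.character(.data$time)) |>
    dplyr::filter(.data$time %in% required_times) |>
    dplyr::count(.data$subject, .data$measure) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      complete = dplyr::n() == dplyr::n_distinct(table$measure) &
        all(.data$n == length(required_times)),
      .groups = "drop"
    )
  keep <- status$subject[status$complete]
  dropped <- setdiff(unique(table$subject), keep)
  out <- dplyr::filter(table, .data$subject %in% keep)
  attr(out, "dropped") <- dropped
  out
}

check_longitudinal <- function(table) {
  need <- c("subject", "group", "time", "region", "measure", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(paste0("longitudinal table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- table |>
    dplyr::count(.data$subject, .data$time, .data$region, .data$measure) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) abort("duplicate (subject, time, region, measure) records")
  gmix <- table |>
    dplyr::distinct(.data$subject, .data$group) |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(gmix)) abort("group is not constant within subject")
  invisible(table)
}

#' Build a longitudinal table from parameter maps and ROI masks
#'
#' Applies [extract_roi_mean()] for every mask and measure, averages
#' bilateral regions with [bilateral_average()], and stacks the result into
#' longitudinal-table rows for one subject and time point.
#'
#' @param maps a `param_maps` object.
#' @param masks list of [roi_mask()] objects.
#' @param subject,group,time record labels.
#' @param measures which measures to extract.
#' @return longitudinal tibble rows (one per region x measure).
#' @export
roi_table <- function(maps, masks, subject, group, time,
                      measures = c("MD", "FA", "MK")) {
  raw <- purrr::map_dfr(masks, function(m) {
    purrr::map_dfr(measures, function(meas) extract_roi_mean(maps, m, meas))
  })
  raw |>
    dplyr::group_by(.data$region, .data$measure) |>
    dplyr::summarise(
      value = bilateral_average(
        .data$value[match("left", .data$side)],
        .data$value[match("right", .data$side)]
      )$value %|na|% mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(subject = subject, group = group, time = time) |>
    dplyr::select("subject", "group", "time", "region", "measure", "value")
}

# fall back to rhs when lhs is NA/empty
`%|na|%` <- function(a, b) if (length(a) == 1L && !is.na(a)) a else b
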
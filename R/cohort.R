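#' Specification of a balanced two-group longitudinal cohort
#'
#' Describes the design the cohort generator emulates: two arms (e.g. sham
#' vs injured), a fixed ordered set of imaging time points, and a complete
#' group-by-time table of cell means for one or more measures. Values are
#' drawn as `cell mean + subject random effect + residual`, with the subject
#' effect shared across the subject's records of a measure (compound
#' symmetry) — the covariance structure the split-plot ANOVA assumes.
#'
#' @param n_per_group subjects per arm (>= 2).
#' @param groups two group labels.
#' @param timepoints ordered time labels; the first is the baseline.
#' @param means named list: per measure, a `groups x timepoints` matrix of
#'   cell means (complete, no missing cells). A single matrix is taken as
#'   one measure named `"value"`.
#' @param sd_between between-subject SD (>= 0).
#' @param sd_within within-subject (residual) SD (>= 0).
#' @param region region label stamped on the records.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 6L,
                        groups = c("sham", "injured"),
                        timepoints = c("baseline", "d1", "d7", "d14", "d28"),
                        means = NULL,
                        sd_between = 0.05, sd_within = 0.05,
                        region = "hippocampus", seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) abort("`n_per_group` must be >= 2")
  if (length(groups) != 2L) abort("exactly two group labels are required")
  assert_scalar_num(sd_between, "sd_between", lower = 0)
  assert_scalar_num(sd_within, "sd_within", lower = 0)
  if (is.null(means)) {
    means <- matrix(1, length(groups), length(timepoints))
  }
  if (is.matrix(means)) means <- list(value = means)
  for (nm in names(means)) {
    m <- means[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(length(groups), length(timepoints)))) {
      abort(sprintf("means[['%s']] must be a %d x %d matrix (groups x timepoints)",
                    nm, length(groups), length(timepoints)))
    }
    if (any(!is.finite(m))) abort(sprintf("means[['%s']] has missing cells", nm))
  }
  structure(
    list(
      n_per_group = n_per_group, groups = groups, timepoints = timepoints,
      means = means, sd_between = sd_between, sd_within = sd_within,
      region = region, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a longitudinal cohort table
#'
#' Draws one record per subject x time x measure from the design in a
#' [cohort_spec()]: `value = cell mean + subject effect + residual`, with
#' the subject effect `N(0, sd_between^2)` drawn once per subject x measure
#' and residuals `N(0, sd_within^2)` independent per record. The table is
#' balanced and byte-identical across runs for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `subject`, `group`, `time`, `region`,
#'   `measure`, `value`; `time` is a factor with the spec's level order.
#' @export
make_cohort_table <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  g <- length(spec$groups); s <- spec$n_per_group; t <- length(spec$timepoints)
  subjects <- paste0(
    rep(substr(spec$groups, 1L, 1L), each = s),
    formatC(rep(seq_len(s), times = g), width = 2, flag = "0")
  )
  grid <- tidyr::expand_grid(
    measure = names(spec$means),
    subj_i = seq_len(g * s),
    time_i = seq_len(t)
  )
  with_seed(spec$seed, {
    subj_eff <- matrix(rnorm(g * s * length(spec$means), 0, spec$sd_between),
                       nrow = g * s)
    colnames(subj_eff) <- names(spec$means)
    resid <- rnorm(nrow(grid), 0, spec$sd_within)
    group_i <- rep(seq_len(g), each = s)
    grid |>
      dplyr::mutate(
        subject = subjects[.data$subj_i],
        group = spec$groups[group_i[.data$subj_i]],
        time = factor(spec$timepoints[.data$time_i], levels = spec$timepoints),
        region = spec$region,
        cell_mean = purrr::pmap_dbl(
          list(.data$measure, .data$subj_i, .data$time_i),
          function(m, si, ti) spec$means[[m]][group_i[si], ti]
        ),
        value = .data$cell_mean +
          subj_eff[cbind(.data$subj_i, match(.data$measure, names(spec$means)))] +
          resid
      ) |>
      dplyr::select("subject", "group", "time", "region", "measure", "value")
  })
}

#' Generate a synthetic metabolite table
#'
#' Emits a spectral-fit-style concentration table: one row per metabolite
#' with its concentration (institutional units) and percent Cramer-Rao lower
#' bound. A total-creatine (`tCr`) reference row is always present (appended
#' with the given concentration if not listed). Optional multiplicative
#' jitter emulates fit-to-fit variability.
#'
#' @param metabolites character metabolite names.
#' @param concentrations matching concentrations (> 0).
#' @param crlbs matching CRLB values, percent (>= 0).
#' @param tcr_concentration,tcr_crlb the reference row, used when `"tCr"` is
#'   not among `metabolites`.
#' @param jitter_sd multiplicative log-normal jitter SD (0 = exact values).
#' @param seed integer seed.
#' @return tibble with columns `metabolite`, `concentration`, `crlb_percent`.
#' @export
make_metabolite_table <- function(metabolites, concentrations, crlbs,
                                  tcr_concentration = 8, tcr_crlb = 3,
                                  jitter_sd = 0, seed = 1L) {
  if (length(metabolites) != length(concentrations) ||
      length(metabolites) != length(crlbs)) {
    abort("metabolites, concentrations and crlbs must have equal length")
  }
  if (any(crlbs < 0)) abort("CRLB values must be >= 0")
  if (!"tCr" %in% metabolites) {
    metabolites <- c(metabolites, "tCr")
    concentrations <- c(concentrations, tcr_concentration)
    crlbs <- c(crlbs, tcr_crlb)
  }
  conc <- as.numeric(concentrations)
  if (jitter_sd > 0) {
    conc <- with_seed(seed, conc * exp(rnorm(length(conc), 0, jitter_sd)))
  }
  tibble::tibble(
    metabolite = as.character(metabolites),
    concentration = conc,
    crlb_percent = as.numeric(crlbs)
  )
}

#' Generate a synthetic labeled micrograph
#'
#' Builds a grayscale image with a known labeled-pixel fraction: exactly
#' `round(labeled_fraction * n_pixels)` pixels (seeded random positions) are
#' set to `label_multiple * background_level`, the rest to
#' `background_level`, plus optional additive jitter. The construction makes
#' the downstream percent-area quantification's ground truth exact.
#'
#' @param shape image size in pixels, `c(rows, cols)`.
#' @param background_level background intensity (> 0).
#' @param labeled_fraction fraction of labeled pixels in `[0, 1]`.
#' @param label_multiple labeled intensity as a multiple of background (> 0).
#' @param jitter_sd additive Gaussian jitter SD (kept small relative to the
#'   label contrast; 0 = exact two-level image).
#' @param seed integer seed.
#' @return numeric matrix of intensities.
#' @export
make_histo_image <- function(shape = c(360L, 450L), background_level = 100,
                             labeled_fraction = 0.3, label_multiple = 3,
                             jitter_sd = 0, seed = 1L) {
  assert_scalar_num(labeled_fraction, "labeled_fraction", lower = 0, upper = 1)
  assert_scalar_num(label_multiple, "label_multiple", lower = 1e-12)
  n <- prod(shape)
  n_lab <- round(labeled_fraction * n)
  with_seed(seed, {
    img <- matrix(background_level, shape[1L], shape[2L])
    if (n_lab > 0) {
      img[sample.int(n, n_lab)] <- label_multiple * background_level
    }
    if (jitter_sd > 0) img <- img + rnorm(n, 0, jitter_sd)
    img
  })
}
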
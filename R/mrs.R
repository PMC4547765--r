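# metabolite names the loader recognises without comment
MRS_VOCAB <- c("NAA", "NAAG", "Cho", "tCho", "Ins", "Tau", "Gln", "Glu", "Lac",
               "tCr", "Glx", "GABA", "GSH", "Asp", "Ala", "Glc", "MM")

#' Load a metabolite concentration table
#'
#' Reads the canonical interchange CSV for spectral-fit output: columns
#' `metabolite`, `concentration` (institutional units) and `crlb_percent`
#' (the percent Cramer-Rao lower bound the fit reports for that metabolite).
#' Unknown metabolite names pass through with a warning.
#'
#' @param path CSV file path.
#' @return tibble of validated records.
#' @export
load_metabolite_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("metabolite", "concentration", "crlb_percent")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("metabolite table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(is.na(tab$crlb_percent)) || any(tab$crlb_percent < 0)) {
    abort("crlb_percent must be present and >= 0")
  }
  unknown <- setdiff(tab$metabolite, MRS_VOCAB)
  if (length(unknown)) {
    warn(paste0("unrecognised metabolite name(s): ", paste(unknown, collapse = ", ")))
  }
  tibble::as_tibble(tab[, need])
}

#' Gate metabolites on their Cramer-Rao lower bound
#'
#' Keeps records whose CRLB is strictly below the threshold (the usual
#' reliability gate on spectral fits: only metabolites quantified with CRLB
#' less than 20% are analysed further). The excluded rows are attached as
#' the `"excluded"` attribute. The gate is idempotent and order-preserving.
#'
#' @param records metabolite tibble (see [load_metabolite_table()]).
#' @param threshold_percent strictly positive CRLB threshold (default 20).
#' @return retained records, with attribute `excluded`.
#' @export
filter_crlb <- function(records, threshold_percent = 20) {
  assert_scalar_num(threshold_percent, "threshold_percent", lower = 1e-12)
  keep <- records$crlb_percent < threshold_percent
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded") <- records[!keep, , drop = FALSE]
  out
}

#' Metabolite ratios to total creatine
#'
#' Divides every retained non-tCr concentration by the tCr concentration,
#' the internal reference. The tCr/tCr = 1 row is omitted. If tCr is absent
#' (e.g. it failed the CRLB gate) or non-positive the voxel is unusable and
#' an error is raised.
#'
#' @param records metabolite tibble that already passed [filter_crlb()].
#' @return tibble: `metabolite`, `ratio` (concentration / tCr), named
#'   `"<metabolite>/tCr"` in the `measure` column for longitudinal merging.
#' @export
ratio_to_tcr <- function(records) {
  tcr <- records$concentration[records$metabolite == "tCr"]
  if (length(tcr) != 1L || is.na(tcr) || tcr <= 0) {
    abort("tCr reference missing (or failed the CRLB gate): voxel unusable")
  }
  out <- records[records$metabolite != "tCr", , drop = FALSE]
  tibble::tibble(
    metabolite = out$metabolite,
    ratio = out$concentration / tcr,
    measure = paste0(out$metabolite, "/tCr")
  )
}

#' Merge metabolite ratios into a longitudinal table
#'
#' Applies the CRLB gate and tCr-ratio computation to one spectral-fit table
#' and returns longitudinal rows (measure = `"<metabolite>/tCr"`) for the
#' given subject/time. A metabolite failing the gate at this time point
#' yields no row here (a missing cell downstream), rather than dropping the
#' metabolite across the whole study.
#'
#' @param records metabolite tibble.
#' @param subject,group,time,region record labels.
#' @param crlb_threshold percent CRLB gate.
#' @return longitudinal tibble rows.
#' @export
mrs_longitudinal_rows <- function(records, subject, group, time,
                                  region = "hippocampus", crlb_threshold = 20) {
  gated <- filter_crlb(records, crlb_threshold)
  ratios <- ratio_to_tcr(gated)
  tibble::tibble(
    subject = subject, group = group, time = time, region = region,
    measure = ratios$measure, value = ratios$ratio
  )
}
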
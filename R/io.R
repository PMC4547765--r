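#' Write a DWI series as NIfTI + FSL-style gradient tables
#'
#' Writes the 4D signal array as NIfTI-1 and the scheme as `.bval` / `.bvec`
#' text files (space-separated; one row of b-values; three rows in the
#' `.bvec`, one per axis, one column per volume).
#'
#' @param series a [dwi_series()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec` (and `<prefix>_mask.nii.gz` if the
#'   series carries a mask).
#' @return the NIfTI path, invisibly.
#' @export
write_dwi <- function(series, prefix) {
  if (!inherits(series, "dwi_series")) abort("`series` must be a dwi_series")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, 1)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  writeLines(paste(format(series$scheme$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "),
             paste0(prefix, ".bval"))
  bv <- t(series$scheme$bvecs)
  writeLines(apply(bv, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                             collapse = " ")),
             paste0(prefix, ".bvec"))
  if (!is.null(series$mask)) {
    mimg <- RNifti::asNifti(array(as.integer(series$mask), dim(series$mask)))
    RNifti::pixdim(mimg) <- series$voxel_size
    RNifti::writeNifti(mimg, paste0(prefix, "_mask.nii.gz"))
  }
  invisible(nii)
}

# Rebuild a canonical gradient_scheme from per-volume tables; returns the
# scheme plus the permutation taking canonical volume order to file order.
scheme_from_tables <- function(bvals, bvecs, tol = 1e-3) {
  nv <- length(bvals)
  if (!identical(dim(bvecs), c(nv, 3L))) abort("bvec table must be n_volumes x 3")
  nz <- which(bvals > 0)
  if (length(nz) == 0L) abort("no diffusion-weighted volumes found")
  norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > tol)) {
    abort(sprintf("non-unit gradient vector(s) at volume(s) %s (tolerance %g)",
                  paste(nz[abs(norms - 1) > tol], collapse = ", "), tol))
  }
  b0 <- which(bvals == 0)
  if (length(b0) == 0L) abort("at least one b = 0 volume is required")
  shells <- sort(unique(bvals[nz]))
  key <- apply(round(bvecs[nz, , drop = FALSE], 6L), 1L, paste, collapse = ",")
  dirs_key <- unique(key)
  directions <- normalize_rows(bvecs[nz[match(dirs_key, key)], , drop = FALSE])
  perm_nz <- integer(0)
  for (b in shells) {
    for (i in seq_along(dirs_key)) {
      j <- nz[key == dirs_key[i] & bvals[nz] == b]
      if (length(j) != 1L) {
        abort(sprintf(
          "direction %d appears %d times on shell b = %g (expected once): %s",
          i, length(j), b, "the same direction set must be acquired on every shell"
        ))
      }
      perm_nz <- c(perm_nz, j)
    }
  }
  scheme <- gradient_scheme(directions, shells, n_b0 = length(b0))
  list(scheme = scheme, perm = c(b0, perm_nz))
}

#' Read a DWI series from NIfTI + bval/bvec
#'
#' Loads a 4D NIfTI and FSL-style gradient tables, validates the volume
#' counts and unit norms (zero vectors allowed only where b = 0), and
#' reorders the volumes into the package's canonical layout (b0 block first,
#' then each shell's directions) — so maps are invariant to the on-disk
#' volume order.
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path,bvec_path gradient table text files.
#' @param mask_path optional 3D NIfTI mask (non-zero = include).
#' @return a [dwi_series()].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, mask_path = NULL) {
  img <- RNifti::readNifti(nifti_path)
  if (length(dim(img)) != 4L) abort("expected a 4D NIfTI")
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec_rows) != 3L) abort("bvec file must have 3 rows (x, y, z)")
  bvecs <- t(bvec_rows)
  nv <- dim(img)[4L]
  if (length(bvals) != nv || nrow(bvecs) != nv) {
    abort(sprintf("count mismatch: %d volumes, %d bvals, %d bvec columns",
                  nv, length(bvals), nrow(bvecs)))
  }
  st <- scheme_from_tables(bvals, bvecs)
  vox <- RNifti::pixdim(img)[1:3]
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- RNifti::readNifti(mask_path) != 0
  }
  dwi_series(array(as.numeric(img), dim(img))[, , , st$perm, drop = FALSE],
             st$scheme, voxel_size = vox, mask = mask)
}

#' Write parameter maps as NIfTI files with a JSON sidecar
#'
#' Writes `md.nii.gz`, `fa.nii.gz`, `mk.nii.gz` (float) and `codes.nii.gz`
#' (integer; -1 outside the mask) plus `fit_log.json` recording the fit
#' configuration (including any smoothing FWHM passed through) and the
#' clamp / exclusion counts.
#'
#' @param maps a `param_maps` object.
#' @param out_dir output directory (created if needed).
#' @param extra named list merged into the sidecar (e.g. `fwhm_mm`).
#' @return named character vector of written paths, invisibly.
#' @export
write_param_maps <- function(maps, out_dir, extra = list()) {
  if (!inherits(maps, "param_maps")) abort("`maps` must be a param_maps object")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, name, integer = FALSE) {
    dtype <- "float64"
    if (integer) {
      arr[is.na(arr)] <- -1L
      arr <- array(as.integer(arr), dim(arr))
      dtype <- "int32"
    }
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- maps$voxel_size
    p <- file.path(out_dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(img, p, datatype = dtype)
    p
  }
  paths <- c(
    md = wr(maps$md, "md"), fa = wr(maps$fa, "fa"), mk = wr(maps$mk, "mk"),
    codes = wr(maps$codes, "codes", integer = TRUE)
  )
  sidecar <- c(maps$log, extra)
  sidecar$config_hash <- rlang::hash(sidecar)
  json <- file.path(out_dir, "fit_log.json")
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, log = json))
}

#' Read parameter maps written by [write_param_maps()]
#' @param dir directory holding `md/fa/mk/codes.nii.gz`.
#' @return a `param_maps` object (log restored from the sidecar).
#' @export
read_param_maps <- function(dir) {
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  codes <- rd("codes")
  codes[codes < 0] <- NA
  log <- jsonlite::read_json(file.path(dir, "fit_log.json"), simplifyVector = TRUE)
  md <- rd("md")
  img <- RNifti::readNifti(file.path(dir, "md.nii.gz"))
  new_param_maps(md, rd("fa"), rd("mk"), array(as.integer(codes), dim(codes)),
                 RNifti::pixdim(img)[1:3], log)
}

#' Read ROI masks from a NIfTI label volume
#'
#' @param label_path integer NIfTI label volume.
#' @param mapping tibble/data.frame with columns `label`, `region`, `side`
#'   declaring what each non-zero label means.
#' @return named list of [roi_mask()] objects (`region.side`).
#' @export
read_roi_masks <- function(label_path, mapping) {
  lab <- RNifti::readNifti(label_path)
  arr <- array(as.integer(round(as.numeric(lab))), dim(lab))
  masks <- list()
  for (i in seq_len(nrow(mapping))) {
    m <- mapping[i, ]
    masks[[paste(m$region, m$side, sep = ".")]] <-
      roi_mask(arr == m$label, region = m$region, side = m$side)
  }
  masks
}

#' Write / read a longitudinal table as CSV
#'
#' The canonical table format: columns `subject,group,time,region,measure,value`
#' (plus `normalized_value` when present). The declared time-level order is
#' restored on read.
#'
#' @param table longitudinal tibble.
#' @param path CSV path.
#' @return `path` invisibly ([write_longitudinal()]); a tibble
#'   ([read_longitudinal()]).
#' @export
write_longitudinal <- function(table, path) {
  check_longitudinal(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_longitudinal
#' @param time_levels ordered time labels; defaults to order of appearance.
#' @export
read_longitudinal <- function(path, time_levels = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_longitudinal(tab)
  lv <- time_levels %||% unique(as.character(tab$time))
  tab$time <- factor(as.character(tab$time), levels = lv)
  tibble::as_tibble(tab)
}

#' Import a deposited per-animal spreadsheet into a longitudinal table
#'
#' Layout-configurable importer for study spreadsheets (xls/xlsx via readxl,
#' or CSV): `col_map` renames the file's columns onto the canonical
#' `subject,group,time,region,measure,value` fields for long-format sheets;
#' for wide sheets (one column per time point) give `wide_times`, a named
#' vector mapping file columns to time labels, and the columns are pivoted.
#'
#' @param path spreadsheet path (.xls, .xlsx or .csv).
#' @param col_map named character vector: canonical name -> file column.
#' @param wide_times optional named character vector: file column -> time
#'   label (wide layouts).
#' @param sheet sheet index or name (spreadsheets; default first).
#' @param time_levels ordered time labels for the factor.
#' @return longitudinal tibble.
#' @export
import_s1_table <- function(path, col_map, wide_times = NULL, sheet = 1L,
                            time_levels = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xls", "xlsx")) {
    readxl::read_excel(path, sheet = sheet)
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    abort(sprintf("unsupported spreadsheet format '%s'", ext))
  }
  miss <- setdiff(unname(c(col_map, names(wide_times))), names(raw))
  if (length(miss)) {
    abort(paste0("file lacks mapped column(s): ", paste(miss, collapse = ", ")))
  }
  tab <- raw
  if (!is.null(wide_times)) {
    tab <- tidyr::pivot_longer(tab, cols = dplyr::all_of(names(wide_times)),
                               names_to = ".time_col", values_to = ".value")
    tab$time <- unname(wide_times[tab$.time_col])
    tab$value <- tab$.value
    tab$.time_col <- tab$.value <- NULL
    col_map <- col_map[setdiff(names(col_map), c("time", "value"))]
  }
  for (canon in names(col_map)) tab[[canon]] <- raw_col <- tab[[col_map[[canon]]]]
  if (!"region" %in% names(tab)) tab$region <- "all"
  tab <- tab[, intersect(c("subject", "group", "time", "region", "measure",
                           "value", "normalized_value"), names(tab))]
  lv <- time_levels %||% unique(as.character(tab$time))
  tab$time <- factor(as.character(tab$time), levels = lv)
  check_longitudinal(tab)
  tibble::as_tibble(tab)
}
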
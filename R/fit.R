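#' Per-direction diffusion-kurtosis fit
#'
#' Fits the two-parameter log-signal model
#' `ln(S/S0) = -b * x1 + (b^2 / 6) * x2` by least squares over the shells of
#' one gradient direction, and reports the apparent diffusivity
#' `D_app = x1` and apparent kurtosis `K_app = x2 / x1^2`. A non-positive
#' fitted diffusivity marks the direction degenerate: `(0, 0)` is returned
#' with the failure flagged. K_app is clamped to `k_clamp` (with the clamp
#' recorded), which prevents noise-driven blow-up where `D_app` is tiny.
#'
#' @param log_ratios `ln(S/S0)` at each diffusion-weighted volume of the
#'   direction (finite).
#' @param bvalues matching b-values, s/mm^2 (>= 2 distinct positive values).
#' @param k_clamp length-2 range for K_app.
#' @return a list of class `directional_fit`: `D_app`, `K_app`, `residual`
#'   (log-signal RMS), `clamped`, `degenerate`.
#' @export
fit_direction <- function(log_ratios, bvalues, k_clamp = c(0, 3)) {
  if (length(log_ratios) != length(bvalues)) abort("log_ratios and bvalues differ in length")
  if (!all(is.finite(log_ratios))) abort("log_ratios must be finite")
  b <- as.numeric(bvalues)
  if (length(unique(b[b > 0])) < 2L) {
    abort("need >= 2 distinct positive b-values: the model has 2 unknowns")
  }
  A <- cbind(-b, b^2 / 6)
  coef <- drop(qr.solve(A, log_ratios))
  resid <- sqrt(mean((log_ratios - drop(A %*% coef))^2))
  x1 <- coef[1L]; x2 <- coef[2L]
  if (x1 <= 0) {
    return(structure(
      list(D_app = 0, K_app = 0, residual = resid, clamped = FALSE, degenerate = TRUE),
      class = "directional_fit"
    ))
  }
  k <- x2 / x1^2
  clamped <- k < k_clamp[1L] || k > k_clamp[2L]
  k <- min(max(k, k_clamp[1L]), k_clamp[2L])
  structure(
    list(D_app = x1, K_app = k, residual = resid, clamped = clamped, degenerate = FALSE),
    class = "directional_fit"
  )
}

#' Diffusion tensor from per-direction apparent diffusivities
#'
#' Linear least-squares fit of `D_app(n) = n' D n` to the six unique tensor
#' components, followed by an eigendecomposition with eigenvalues sorted in
#' descending order. Negative eigenvalues are clamped to zero for the
#' scalar-metric computations, with the clamping recorded.
#'
#' @param d_app per-direction apparent diffusivities (mm^2/s).
#' @param directions matching unit direction matrix (n x 3), >= 6 directions
#'   spanning 3-space.
#' @return list of class `dti_tensor_estimate`: `D` (6-vector, xx yy zz xy xz
#'   yz), `evals` (descending, clamped), `evals_raw`, `evecs` (columns),
#'   `clamped`.
#' @export
fit_dti_tensor <- function(d_app, directions) {
  directions <- as.matrix(directions)
  if (nrow(directions) < 6L) abort("need >= 6 directions: the tensor has 6 unknowns")
  if (length(d_app) != nrow(directions)) abort("d_app and directions differ in length")
  B <- dti_design(directions)
  qrB <- qr(B)
  if (qrB$rank < 6L) abort("direction set is rank-deficient: tensor fit underdetermined")
  d6 <- drop(qr.coef(qrB, d_app))
  e <- eigen(d6_to_mat(d6), symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  evals_raw <- e$values[ord]
  evals <- pmax(evals_raw, 0)
  structure(
    list(
      D = d6, evals = evals, evals_raw = evals_raw,
      evecs = e$vectors[, ord, drop = FALSE],
      clamped = any(evals_raw < 0)
    ),
    class = "dti_tensor_estimate"
  )
}

# design matrix rows [n1^2, n2^2, n3^2, 2 n1 n2, 2 n1 n3, 2 n2 n3]
dti_design <- function(directions) {
  cbind(
    directions[, 1L]^2, directions[, 2L]^2, directions[, 3L]^2,
    2 * directions[, 1L] * directions[, 2L],
    2 * directions[, 1L] * directions[, 3L],
    2 * directions[, 2L] * directions[, 3L]
  )
}

#' Scalar metrics of a diffusion tensor
#'
#' Mean diffusivity `MD = (l1 + l2 + l3) / 3` and fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))` from the
#' (clamped) eigenvalues. FA is defined as 0 when all eigenvalues are 0.
#'
#' @param tensor a [fit_dti_tensor()] result, or a numeric 3-vector of
#'   eigenvalues.
#' @return named numeric vector `c(MD = , FA = )`.
#' @export
tensor_metrics <- function(tensor) {
  ev <- if (inherits(tensor, "dti_tensor_estimate")) tensor$evals else as.numeric(tensor)
  stopifnot(length(ev) == 3L)
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else sqrt(1.5) * sqrt(sum((ev - md)^2)) / sqrt(ss)
  c(MD = md, FA = fa)
}

#' Mean kurtosis from directional fits
#'
#' MK is the arithmetic mean of the apparent kurtosis over all measured,
#' non-degenerate directions; the number of excluded (degenerate) directions
#' is reported alongside.
#'
#' @param k_app per-direction apparent kurtosis values.
#' @param degenerate logical flags marking directions to exclude.
#' @return list `MK` (NA if every direction is degenerate), `n_used`,
#'   `n_excluded`.
#' @export
compute_mk <- function(k_app, degenerate = rep(FALSE, length(k_app))) {
  if (length(k_app) < 1L) abort("at least one directional fit is required")
  keep <- !degenerate
  if (!any(keep)) {
    return(list(MK = NA_real_, n_used = 0L, n_excluded = length(k_app)))
  }
  list(
    MK = mean(k_app[keep]),
    n_used = sum(keep),
    n_excluded = sum(!keep)
  )
}

# per-voxel failure codes for the parameter maps
FIT_OK <- 0L
FIT_NEGATIVE_SIGNAL <- 1L
FIT_DEGENERATE <- 2L
FIT_CLAMPED <- 3L

#' Voxelwise DKI parameter maps
#'
#' Runs the full voxelwise estimation over a (typically pre-smoothed) DWI
#' series: the b = 0 volumes are averaged into S0, signals are floored at
#' `epsilon * S0` before the log, every direction is fitted with
#' [fit_direction()] (or jointly, see `fit_mode`), the diffusion tensor is
#' assembled from the per-direction diffusivities, and MD / FA / MK maps are
#' emitted together with an exhaustive per-voxel failure code
#' (0 ok, 1 negative-signal, 2 degenerate, 3 clamped).
#'
#' @param series a [dwi_series()].
#' @param fit_mode `"directional"` (default): per-direction two-parameter
#'   fits, tensor fitted to the kurtosis-corrected per-direction
#'   diffusivities, MK = mean of per-direction K_app. `"joint"`: one 21
#'   parameter linear fit (6 tensor + 15 kurtosis-tensor components) per
#'   voxel; K_app is then evaluated along the measured directions and
#'   averaged, so both modes share the MK definition.
#' @param k_clamp admissible K_app range (clamps recorded per voxel).
#' @param epsilon positivity floor: signals below `epsilon * S0` are raised
#'   to it before the log.
#' @return object of class `param_maps`: 3D arrays `md`, `fa`, `mk`, integer
#'   array `codes`, plus `voxel_size`, `log` (clamp / exclusion counts and
#'   the configuration used).
#' @export
fit_volume <- function(series, fit_mode = c("directional", "joint"),
                       k_clamp = c(0, 3), epsilon = 1e-6) {
  fit_mode <- match.arg(fit_mode)
  if (!inherits(series, "dwi_series")) abort("`series` must be a dwi_series")
  scheme <- series$scheme
  dm <- dim(series$data)[1:3]
  nvox <- prod(dm)
  Y <- matrix(series$data, nrow = nvox)
  mask_v <- if (is.null(series$mask)) rep(TRUE, nvox) else as.vector(series$mask)

  b0_cols <- which(scheme$bvalues == 0)
  S0 <- rowMeans(Y[, b0_cols, drop = FALSE])

  md_map <- array(NA_real_, dm)
  fa_map <- array(NA_real_, dm)
  mk_map <- array(NA_real_, dm)
  codes <- array(FIT_OK, dm)
  codes[!array(mask_v, dm)] <- NA_integer_

  bad_s0 <- mask_v & S0 <= 0
  codes[array(bad_s0, dm)] <- FIT_NEGATIVE_SIGNAL
  vox <- which(mask_v & !bad_s0)
  n_dir <- nrow(scheme$directions)
  log_entry <- list(
    fit_mode = fit_mode, k_clamp = k_clamp, epsilon = epsilon,
    n_voxels = length(vox), n_negative_signal = sum(bad_s0)
  )
  if (length(vox) == 0L) {
    return(new_param_maps(md_map, fa_map, mk_map, codes, series$voxel_size,
                          c(log_entry, n_clamped = 0L, n_degenerate = 0L,
                            n_excluded_direction_fits = 0L)))
  }

  S0v <- S0[vox]
  # log-signal ratios with the positivity floor applied per voxel
  logratio_cols <- function(cols) {
    S <- Y[vox, cols, drop = FALSE]
    S <- pmax(S, epsilon * S0v)
    log(S / S0v)
  }

  if (fit_mode == "directional") {
    b <- scheme$shell_bvalues
    A <- cbind(-b, b^2 / 6)
    pinvA <- solve(crossprod(A), t(A)) # 2 x n_shell
    D_app <- matrix(0, length(vox), n_dir)
    K_app <- matrix(0, length(vox), n_dir)
    degen <- matrix(FALSE, length(vox), n_dir)
    clamp <- matrix(FALSE, length(vox), n_dir)
    for (i in seq_len(n_dir)) {
      cols <- scheme$n_b0 + (seq_along(b) - 1L) * n_dir + i
      coef <- logratio_cols(cols) %*% t(pinvA) # nvox x 2
      x1 <- coef[, 1L]; x2 <- coef[, 2L]
      bad <- x1 <= 0
      k <- ifelse(bad, 0, x2 / pmax(x1, .Machine$double.xmin)^2)
      cl <- !bad & (k < k_clamp[1L] - 1e-12 | k > k_clamp[2L] + 1e-12)
      D_app[, i] <- ifelse(bad, 0, x1)
      K_app[, i] <- pmin(pmax(k, k_clamp[1L]), k_clamp[2L])
      degen[, i] <- bad
      clamp[, i] <- cl
    }
    n_used <- rowSums(!degen)
    mk_v <- ifelse(n_used > 0, rowSums(K_app * !degen) / pmax(n_used, 1L), NA_real_)

    B <- dti_design(scheme$directions)
    pinvB <- solve(crossprod(B), t(B)) # 6 x n_dir
    D6 <- D_app %*% t(pinvB)
    # refit voxels that had degenerate directions, excluding those directions
    refit <- which(n_used > 0 & n_used < n_dir)
    for (r in refit) {
      keep <- !degen[r, ]
      if (sum(keep) >= 6L && qr(B[keep, , drop = FALSE])$rank == 6L) {
        D6[r, ] <- drop(qr.solve(B[keep, , drop = FALSE], D_app[r, keep]))
      }
    }
    ev_clamped <- logical(length(vox))
    md_v <- fa_v <- rep(NA_real_, length(vox))
    for (r in seq_along(vox)) {
      if (n_used[r] == 0L) next
      e <- eigen(d6_to_mat(D6[r, ]), symmetric = TRUE, only.values = TRUE)$values
      ev_clamped[r] <- e[3L] < 0
      m <- tensor_metrics(pmax(sort(e, decreasing = TRUE), 0))
      md_v[r] <- m[["MD"]]; fa_v[r] <- m[["FA"]]
    }
    voxel_degen <- n_used == 0L
    voxel_clamp <- rowSums(clamp) > 0 | ev_clamped
    n_excluded <- sum(degen[!voxel_degen, ])
  } else {
    nz <- which(scheme$bvalues > 0)
    bnz <- scheme$bvalues[nz]
    nn <- scheme$bvecs[nz, , drop = FALSE]
    # variables: 6 D components, then 15 components of Wh = MD^2 * W
    quart <- t(apply(nn, 1L, function(n) W_MULT * apply(W_IDX, 1L, function(ix) prod(n[ix]))))
    Dsg <- cbind(-bnz * dti_design(nn), (bnz^2 / 6) * quart)
    pinvD <- solve(crossprod(Dsg), t(Dsg)) # 21 x n_volumes
    coef <- logratio_cols(nz) %*% t(pinvD) # nvox x 21
    D6 <- coef[, 1:6, drop = FALSE]
    Wh <- coef[, 7:21, drop = FALSE]
    # evaluate K_app on the measured unique directions
    K_app <- matrix(0, length(vox), n_dir)
    degen <- matrix(FALSE, length(vox), n_dir)
    clamp <- matrix(FALSE, length(vox), n_dir)
    for (i in seq_len(n_dir)) {
      n <- scheme$directions[i, ]
      d_app <- quad_form_d(D6, n)
      w_app <- quart_form_w(Wh, n)
      bad <- d_app <= 0
      k <- ifelse(bad, 0, w_app / pmax(d_app, .Machine$double.xmin)^2)
      clamp[, i] <- !bad & (k < k_clamp[1L] - 1e-12 | k > k_clamp[2L] + 1e-12)
      K_app[, i] <- pmin(pmax(k, k_clamp[1L]), k_clamp[2L])
      degen[, i] <- bad
    }
    n_used <- rowSums(!degen)
    mk_v <- ifelse(n_used > 0, rowSums(K_app * !degen) / pmax(n_used, 1L), NA_real_)
    ev_clamped <- logical(length(vox))
    md_v <- fa_v <- rep(NA_real_, length(vox))
    for (r in seq_along(vox)) {
      if (n_used[r] == 0L) next
      e <- eigen(d6_to_mat(D6[r, ]), symmetric = TRUE, only.values = TRUE)$values
      ev_clamped[r] <- e[3L] < 0
      m <- tensor_metrics(pmax(sort(e, decreasing = TRUE), 0))
      md_v[r] <- m[["MD"]]; fa_v[r] <- m[["FA"]]
    }
    voxel_degen <- n_used == 0L
    voxel_clamp <- rowSums(clamp) > 0 | ev_clamped
    n_excluded <- sum(degen[!voxel_degen, ])
  }

  md_map[vox] <- ifelse(voxel_degen, NA_real_, md_v)
  fa_map[vox] <- ifelse(voxel_degen, NA_real_, fa_v)
  mk_map[vox] <- mk_v
  code_v <- rep(FIT_OK, length(vox))
  code_v[voxel_clamp] <- FIT_CLAMPED
  code_v[voxel_degen] <- FIT_DEGENERATE
  codes[vox] <- code_v

  log_entry <- c(log_entry, list(
    n_clamped = sum(voxel_clamp & !voxel_degen),
    n_degenerate = sum(voxel_degen),
    n_excluded_direction_fits = n_excluded
  ))
  new_param_maps(md_map, fa_map, mk_map, codes, series$voxel_size, log_entry)
}

new_param_maps <- function(md, fa, mk, codes, voxel_size, log) {
  structure(
    list(md = md, fa = fa, mk = mk, codes = codes,
         voxel_size = voxel_size, log = log),
    class = "param_maps"
  )
}

#' @export
print.param_maps <- function(x, ...) {
  d <- dim(x$md)
  ok <- sum(x$codes == FIT_OK, na.rm = TRUE)
  cat(sprintf(
    "<param_maps> %d x %d x %d voxels; %d ok, %d clamped, %d degenerate, %d negative-signal\n",
    d[1], d[2], d[3], ok,
    sum(x$codes == FIT_CLAMPED, na.rm = TRUE),
    sum(x$codes == FIT_DEGENERATE, na.rm = TRUE),
    sum(x$codes == FIT_NEGATIVE_SIGNAL, na.rm = TRUE)
  ))
  invisible(x)
}
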
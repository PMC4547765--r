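#' 4D diffusion-weighted series
#'
#' Binds a 4D signal array (x, y, z, volume) to its gradient scheme and voxel
#' geometry. The 4th-dimension length must equal the scheme's volume count.
#'
#' @param data 4D numeric array, signals >= 0.
#' @param scheme a [gradient_scheme()].
#' @param voxel_size mm per axis, length 3.
#' @param mask optional logical 3D array (voxels to analyse).
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(data, scheme, voxel_size = c(1, 1, 1), mask = NULL) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array (x, y, z, volume)")
  if (dim(data)[4L] != n_volumes(scheme)) {
    abort(sprintf(
      "4th dimension (%d) does not match scheme volume count (%d)",
      dim(data)[4L], n_volumes(scheme)
    ))
  }
  if (any(data < 0)) abort("signals must be >= 0")
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 positive lengths (mm)")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:3])) abort("mask grid does not match data grid")
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(
    list(data = data, scheme = scheme, voxel_size = as.numeric(voxel_size), mask = mask),
    class = "dwi_series"
  )
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dwi_series> %d x %d x %d voxels (%s mm), %d volumes%s\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x "), d[4],
    if (is.null(x$mask)) "" else sprintf(", %d masked-in voxels", sum(x$mask))
  ))
  invisible(x)
}

#' Voxelwise ground truth for a DKI phantom
#'
#' Holds per-voxel baseline signal, diffusion tensor and kurtosis ground
#' truth. Kurtosis may be given as a full 15-component W tensor per voxel or
#' as a single isotropic apparent-kurtosis map `K` (converted internally via
#' [iso_k_to_w()] at synthesis time).
#'
#' @param S0 3D array of baseline signals (> 0 inside the mask).
#' @param D array of dim `c(dim(S0), 6)`: tensor components (xx,yy,zz,xy,xz,yz).
#' @param K 3D array (or scalar) of isotropic apparent kurtosis, or `NULL`.
#' @param W array of dim `c(dim(S0), 15)`, or `NULL` (exactly one of K/W).
#' @param mask logical 3D array; defaults to all voxels.
#' @param check verify that D is positive semi-definite inside the mask.
#' @return object of class `ground_truth_field`.
#' @export
ground_truth_field <- function(S0, D, K = NULL, W = NULL, mask = NULL, check = TRUE) {
  dm <- dim(S0)
  if (length(dm) != 3L) abort("`S0` must be a 3D array")
  if (!identical(dim(D), c(dm, 6L))) abort("`D` must have dim c(dim(S0), 6)")
  if (is.null(K) == is.null(W)) abort("give exactly one of `K` (isotropic) or `W` (full tensor)")
  if (!is.null(W) && !identical(dim(W), c(dm, 15L))) abort("`W` must have dim c(dim(S0), 15)")
  if (!is.null(K) && length(K) == 1L) K <- array(K, dm)
  if (!is.null(K) && !identical(dim(K), dm)) abort("`K` must be scalar or match dim(S0)")
  mask <- mask %||% array(TRUE, dm)
  if (!identical(dim(mask), dm)) abort("mask grid does not match S0 grid")
  mask <- array(as.logical(mask), dm)
  if (!any(mask)) abort("mask selects no voxels")
  if (any(S0[mask] <= 0)) abort("S0 must be > 0 inside the mask")
  if (check) {
    Dm <- matrix(D, ncol = 6L)[which(mask), , drop = FALSE]
    if (!all(is.finite(Dm))) abort("D components must be finite inside the mask")
    for (i in seq_len(nrow(Dm))) {
      ev <- eigen(d6_to_mat(Dm[i, ]), symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-12 * max(abs(ev), 1e-30)) {
        abort("D must be positive semi-definite inside the mask")
      }
    }
  }
  structure(
    list(S0 = S0, D = D, K = K, W = W, mask = mask),
    class = "ground_truth_field"
  )
}

#' Ready-made phantom geometries
#'
#' Convenience ground-truth builders covering the cases the test-bench needs:
#' \describe{
#'   \item{`uniform`}{one isotropic compartment filling the grid, diffusivity
#'     `md` and isotropic kurtosis `K1` (0 for a purely Gaussian phantom).}
#'   \item{`two_block`}{the grid split into halves along x with isotropic
#'     kurtosis `K1` on the left and `K2` on the right (distinct MK regions).}
#'   \item{`tract`}{a cigar-shaped anisotropic "tract" along x through the
#'     grid centre (eigenvalues `tract_evals`) embedded in an isotropic
#'     background of diffusivity `md`.}
#' }
#'
#' @param type one of `"uniform"`, `"two_block"`, `"tract"`.
#' @param dim integer 3-vector voxel grid.
#' @param S0 baseline signal.
#' @param md isotropic diffusivity, mm^2/s.
#' @param K1,K2 isotropic apparent kurtosis for the (first) compartment(s).
#' @param tract_evals eigenvalues of the tract tensor (mm^2/s), length 3.
#' @param tract_radius_frac tract radius as a fraction of the y/z grid size.
#' @return a [ground_truth_field()].
#' @export
phantom_geometry <- function(type = c("uniform", "two_block", "tract"),
                             dim = c(8L, 8L, 8L), S0 = 1000,
                             md = 1.0e-3, K1 = 0.6, K2 = 1.2,
                             tract_evals = c(1.7, 0.4, 0.3) * 1e-3,
                             tract_radius_frac = 0.3) {
  type <- match.arg(type)
  dim <- as.integer(dim)
  S0a <- array(S0, dim)
  D <- array(0, c(dim, 6L))
  D[, , , 1L] <- md; D[, , , 2L] <- md; D[, , , 3L] <- md
  switch(type,
    uniform = {
      ground_truth_field(S0a, D, K = K1, check = FALSE)
    },
    two_block = {
      K <- array(K2, dim)
      K[seq_len(dim[1L] %/% 2L), , ] <- K1
      ground_truth_field(S0a, D, K = K, check = FALSE)
    },
    tract = {
      ctr <- (dim[2:3] + 1) / 2
      r2 <- (tract_radius_frac * min(dim[2:3]))^2
      K <- array(K1, dim)
      for (y in seq_len(dim[2L])) {
        for (z in seq_len(dim[3L])) {
          if ((y - ctr[1L])^2 + (z - ctr[2L])^2 <= r2) {
            D[, y, z, 1L] <- tract_evals[1L]
            D[, y, z, 2L] <- tract_evals[2L]
            D[, y, z, 3L] <- tract_evals[3L]
          }
        }
      }
      ground_truth_field(S0a, D, K = K, check = FALSE)
    }
  )
}

#' Synthesize a multi-shell DWI phantom
#'
#' Evaluates the forward DKI signal model voxel-by-voxel for every volume of
#' the scheme (b0 volumes replicated `n_b0` times with independent noise,
#' as acquired) and optionally corrupts it with Rician or Gaussian noise.
#'
#' @param truth a [ground_truth_field()].
#' @param scheme a [gradient_scheme()].
#' @param sigma noise SD in signal units (0 = noise-free).
#' @param seed integer seed for the noise.
#' @param noise_model `"rician"` (default; magnitude MR) or `"gaussian"`.
#' @param voxel_size mm per axis.
#' @return a [dwi_series()] whose `truth` attribute holds the ground truth.
#' @export
make_phantom <- function(truth, scheme, sigma = 0, seed = 1L,
                         noise_model = c("rician", "gaussian"),
                         voxel_size = c(0.234, 0.234, 1)) {
  noise_model <- match.arg(noise_model)
  if (!inherits(truth, "ground_truth_field")) abort("`truth` must be a ground_truth_field")
  if (!inherits(scheme, "gradient_scheme")) abort("`scheme` must be a gradient_scheme")
  dm <- dim(truth$S0)
  nvox <- prod(dm)
  Dm <- matrix(truth$D, nrow = nvox, ncol = 6L)
  Wm <- if (!is.null(truth$W)) {
    matrix(truth$W, nrow = nvox, ncol = 15L)
  } else {
    iso_k_to_w(Dm, as.vector(truth$K))
  }
  md <- rowMeans(Dm[, 1:3, drop = FALSE])
  S0v <- as.vector(truth$S0)

  nv <- n_volumes(scheme)
  out <- matrix(0, nvox, nv)
  for (v in seq_len(nv)) {
    b <- scheme$bvalues[v]
    if (b == 0) {
      out[, v] <- S0v
    } else {
      n <- scheme$bvecs[v, ]
      d_app <- quad_form_d(Dm, n)
      if (any(d_app[as.vector(truth$mask)] <= 0)) {
        abort("ground truth yields non-positive apparent diffusivity inside the mask")
      }
      w_app <- quart_form_w(Wm, n)
      # -b*D_app + (1/6) b^2 D_app^2 K_app with K_app = MD^2/D_app^2 * W_app,
      # so the quadratic term simplifies to (1/6) b^2 MD^2 W_app
      out[, v] <- S0v * exp(-b * d_app + (1 / 6) * b^2 * md^2 * w_app)
    }
  }
  arr <- array(out, c(dm, nv))
  if (sigma > 0) {
    arr <- add_noise(arr, sigma, model = noise_model, seed = seed)
    # magnitude data are non-negative; gaussian test noise is floored at 0
    if (noise_model == "gaussian") arr[arr < 0] <- 0
  }
  series <- dwi_series(arr, scheme, voxel_size = voxel_size, mask = truth$mask)
  attr(series, "truth") <- truth
  series
}
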
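# Tensor component conventions used throughout:
#  - diffusion tensor D: 6 unique components in order (xx, yy, zz, xy, xz, yz)
#  - kurtosis tensor W: 15 unique components of the fully symmetric rank-4
#    tensor, lexicographic over i <= j <= k <= l:
#      1111 1112 1113 1122 1123 1133 1222 1223 1233 1333
#      2222 2223 2233 2333 3333
# W_IDX / W_MULT give the index quadruples and permutation multiplicities, so
# that sum_ijkl n_i n_j n_k n_l W_ijkl = sum_c W_MULT[c] * prod(n[W_IDX[c,]]) * W[c].
W_IDX <- matrix(c(
  1,1,1,1,  1,1,1,2,  1,1,1,3,  1,1,2,2,  1,1,2,3,
  1,1,3,3,  1,2,2,2,  1,2,2,3,  1,2,3,3,  1,3,3,3,
  2,2,2,2,  2,2,2,3,  2,2,3,3,  2,3,3,3,  3,3,3,3
), ncol = 4L, byrow = TRUE)
W_MULT <- c(1, 4, 4, 6, 12, 6, 4, 12, 12, 4, 1, 4, 6, 4, 1)

# quadratic form n' D n for D stored as (xx, yy, zz, xy, xz, yz);
# D may be a vector (one voxel) or an n x 6 matrix (n voxels).
quad_form_d <- function(D, n) {
  D <- if (is.matrix(D)) D else matrix(D, nrow = 1L)
  D[, 1L] * n[1L]^2 + D[, 2L] * n[2L]^2 + D[, 3L] * n[3L]^2 +
    2 * (D[, 4L] * n[1L] * n[2L] + D[, 5L] * n[1L] * n[3L] + D[, 6L] * n[2L] * n[3L])
}

# quartic contraction sum n_i n_j n_k n_l W_ijkl, W as 15-vector or n x 15 matrix
quart_form_w <- function(W, n) {
  W <- if (is.matrix(W)) W else matrix(W, nrow = 1L)
  coef <- W_MULT * apply(W_IDX, 1L, function(ix) prod(n[ix]))
  drop(W %*% coef)
}

# full symmetric 3x3 from the 6-vector
d6_to_mat <- function(d6) {
  matrix(c(
    d6[1L], d6[4L], d6[5L],
    d6[4L], d6[2L], d6[6L],
    d6[5L], d6[6L], d6[3L]
  ), 3L, 3L)
}

mat_to_d6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

#' Convert an isotropic apparent-kurtosis value to a full kurtosis tensor
#'
#' Phantom ground truth rarely needs an anisotropic kurtosis tensor; a single
#' direction-independent apparent kurtosis K is usually enough. Choosing
#' `W = (K / MD^2) * sym(D (x) D)` (the symmetrized outer product of the
#' diffusion tensor with itself) makes the directional apparent kurtosis
#' `K_app(n) = (MD^2 / D_app(n)^2) * sum n n n n W` equal to K exactly, for
#' every direction and any positive-definite D.
#'
#' @param D diffusion tensor, 6-vector (xx, yy, zz, xy, xz, yz) or n x 6 matrix.
#' @param K scalar apparent kurtosis (recycled across voxels).
#' @return 15-component W (vector, or n x 15 matrix if `D` is a matrix).
#' @export
iso_k_to_w <- function(D, K) {
  was_vec <- !is.matrix(D)
  D <- if (was_vec) matrix(D, nrow = 1L) else D
  md <- rowMeans(D[, 1:3, drop = FALSE])
  if (any(md <= 0)) abort("isotropic kurtosis requires MD > 0")
  # index D components by (i, j) pair
  pair_idx <- matrix(c(1L, 4L, 5L, 4L, 2L, 6L, 5L, 6L, 3L), 3L, 3L)
  W <- matrix(0, nrow(D), 15L)
  for (c in seq_len(15L)) {
    i <- W_IDX[c, 1L]; j <- W_IDX[c, 2L]; k <- W_IDX[c, 3L]; l <- W_IDX[c, 4L]
    W[, c] <- (D[, pair_idx[i, j]] * D[, pair_idx[k, l]] +
                 D[, pair_idx[i, k]] * D[, pair_idx[j, l]] +
                 D[, pair_idx[i, l]] * D[, pair_idx[j, k]]) / 3
  }
  W <- W * (K / md^2)
  if (was_vec) drop(W) else W
}

#' Forward DKI signal along one direction
#'
#' Evaluates the diffusion-kurtosis signal model
#' `S = S0 * exp(-b * D_app + (1/6) * b^2 * D_app^2 * K_app)` where
#' `D_app = n' D n` is the apparent diffusivity along unit direction n and
#' `K_app = (MD^2 / D_app^2) * sum_ijkl n_i n_j n_k n_l W_ijkl` the apparent
#' kurtosis, with MD = trace(D)/3. With `W = 0` this reduces to the
#' mono-exponential tensor model `S0 * exp(-b * n' D n)`.
#'
#' @param S0 non-diffusion-weighted signal (> 0).
#' @param D diffusion tensor, 6-vector (xx, yy, zz, xy, xz, yz), mm^2/s.
#' @param W kurtosis tensor, 15-vector (see package conventions), or `NULL`
#'   if `K` is given.
#' @param direction unit 3-vector.
#' @param b b-value(s), s/mm^2 (vectorized).
#' @param K alternative to `W`: a single isotropic apparent-kurtosis value.
#' @return signal value(s), same length as `b`.
#' @export
dki_forward_signal <- function(S0, D, W = NULL, direction, b, K = NULL) {
  stopifnot(length(direction) == 3L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6) {
    abort("`direction` must be unit-norm")
  }
  if (any(b < 0)) abort("`b` must be >= 0")
  if (is.null(W)) {
    if (is.null(K)) abort("provide either `W` (15-vector) or isotropic `K`")
    W <- iso_k_to_w(D, K)
  }
  d_app <- drop(quad_form_d(D, direction))
  if (d_app <= 0 && any(b > 0)) {
    abort("apparent diffusivity n' D n <= 0 along this direction: signal model undefined")
  }
  md <- mean(D[1:3])
  w_app <- drop(quart_form_w(W, direction))
  k_app <- if (d_app > 0) (md^2 / d_app^2) * w_app else 0
  S0 * exp(-b * d_app + (1 / 6) * b^2 * d_app^2 * k_app)
}

#' Add measurement noise to a signal array
#'
#' Rician noise (the default) models magnitude MR data: the output is
#' `sqrt((s + e1)^2 + e2^2)` with `e1`, `e2` independent zero-mean Gaussians
#' of SD `sigma`. Gaussian noise (`s + e1`) is offered for analytic tests.
#'
#' @param x numeric array or vector of noise-free signals.
#' @param sigma noise standard deviation (>= 0).
#' @param model `"rician"` or `"gaussian"`.
#' @param seed integer seed (same seed, same noise).
#' @return array of the same shape as `x`.
#' @export
add_noise <- function(x, sigma, model = c("rician", "gaussian"), seed = 1L) {
  model <- match.arg(model)
  assert_scalar_num(sigma, "sigma", lower = 0)
  if (sigma == 0) return(x)
  with_seed(seed, {
    e1 <- array(rnorm(length(x), 0, sigma), dim = dim(x) %||% length(x))
    if (model == "gaussian") {
      x + e1
    } else {
      e2 <- array(rnorm(length(x), 0, sigma), dim = dim(x) %||% length(x))
      sqrt((x + e1)^2 + e2^2)
    }
  })
}
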
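#' Multi-shell gradient scheme
#'
#' A `gradient_scheme` describes a diffusion acquisition volume-by-volume:
#' the b-value of every volume (0 for the non-diffusion-weighted volumes)
#' and the unit gradient direction of every diffusion-weighted volume. The
#' same direction set is reused on every shell, mirroring the common
#' preclinical protocol in which each of the encoding directions is acquired
#' at each b-value after a block of b = 0 images.
#'
#' @param directions numeric matrix, one unit 3-vector per row; the unique
#'   encoding directions (shared across shells).
#' @param shell_bvalues numeric vector of positive b-values (s/mm^2), one per
#'   shell.
#' @param n_b0 integer, number of b = 0 volumes (>= 1).
#' @param delta_ms,Delta_ms optional gradient-timing metadata: duration and
#'   separation of the diffusion gradients, in ms.
#'
#' @return An object of class `gradient_scheme` with fields `directions`
#'   (unique directions), `shell_bvalues`, `n_b0`, and per-volume vectors
#'   `bvalues` (length `n_volumes`) and `bvecs` (`n_volumes` x 3 matrix, zero
#'   rows for b = 0 volumes). Volume order is: all b0 volumes first, then all
#'   directions of shell 1, shell 2, ...
#' @export
gradient_scheme <- function(directions, shell_bvalues, n_b0 = 1L,
                            delta_ms = NULL, Delta_ms = NULL) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) abort("`directions` must be an n x 3 matrix")
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort("all directions must have unit Euclidean norm (tolerance 1e-6)")
  }
  shell_bvalues <- as.numeric(shell_bvalues)
  if (length(shell_bvalues) < 1L || any(shell_bvalues <= 0)) {
    abort("`shell_bvalues` must all be > 0 (b = 0 volumes are counted by `n_b0`)")
  }
  n_b0 <- as.integer(n_b0)
  if (n_b0 < 1L) abort("at least one b = 0 volume is required (`n_b0` >= 1)")

  n_dir <- nrow(directions)
  bvalues <- c(rep(0, n_b0), rep(shell_bvalues, each = n_dir))
  bvecs <- rbind(
    matrix(0, n_b0, 3L),
    do.call(rbind, replicate(length(shell_bvalues), directions, simplify = FALSE))
  )
  structure(
    list(
      directions = directions,
      shell_bvalues = shell_bvalues,
      n_b0 = n_b0,
      bvalues = bvalues,
      bvecs = bvecs,
      delta_ms = delta_ms,
      Delta_ms = Delta_ms
    ),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "<gradient_scheme> %d volumes: %d b0 + %d directions x %d shells (b = %s s/mm^2)\n",
    n_volumes(x), x$n_b0, nrow(x$directions), length(x$shell_bvalues),
    paste(x$shell_bvalues, collapse = "/")
  ))
  invisible(x)
}

#' Number of volumes in a gradient scheme
#' @param scheme a [gradient_scheme()].
#' @return integer volume count.
#' @export
n_volumes <- function(scheme) {
  length(scheme$bvalues)
}

#' Generate an approximately uniform multi-shell gradient scheme
#'
#' Builds a direction set by electrostatic repulsion on the unit sphere:
#' points are initialized at random (seeded) and iteratively pushed apart by
#' inverse-square forces between every pair of points *and their antipodes*
#' (diffusion encoding is antipodally symmetric), each update projected back
#' to the sphere. The refined set is reused on every shell.
#'
#' @param n_directions number of unique directions (>= 6; fewer leaves the
#'   diffusion-tensor fit underdetermined).
#' @param shell_bvalues positive b-values, one per shell (s/mm^2).
#' @param n_b0 number of b = 0 volumes.
#' @param seed integer seed; the same seed reproduces the same directions.
#' @param n_iter repulsion iterations.
#' @param delta_ms,Delta_ms optional gradient-timing metadata (ms).
#'
#' @return A [gradient_scheme()].
#' @examples
#' sch <- make_scheme(30, c(1000, 1500, 2000), n_b0 = 5, seed = 1)
#' n_volumes(sch) # 95
#' @export
make_scheme <- function(n_directions = 30L,
                        shell_bvalues = c(1000, 1500, 2000),
                        n_b0 = 5L, seed = 1L, n_iter = 200L,
                        delta_ms = 4, Delta_ms = 23) {
  n_directions <- as.integer(n_directions)
  if (n_directions < 6L) {
    abort("`n_directions` must be >= 6: the tensor fit is underdetermined below 6")
  }
  p <- with_seed(seed, {
    m <- matrix(rnorm(3L * n_directions), ncol = 3L)
    normalize_rows(m)
  })
  step <- 0.1
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n_directions, 3L)
    for (i in seq_len(n_directions)) {
      d_minus <- sweep(p[-i, , drop = FALSE], 2L, p[i, ], function(a, b) b - a)
      d_plus <- sweep(p[-i, , drop = FALSE], 2L, p[i, ], `+`)
      r_minus <- sqrt(rowSums(d_minus^2))
      r_plus <- sqrt(rowSums(d_plus^2))
      force[i, ] <- colSums(d_minus / r_minus^3) + colSums(d_plus / r_plus^3)
    }
    # project forces to the tangent plane, take a small step, renormalize
    force <- force - p * rowSums(force * p)
    p <- normalize_rows(p + step * force / max(sqrt(rowSums(force^2)), 1e-12))
    step <- step * 0.985
  }
  gradient_scheme(p, shell_bvalues, n_b0, delta_ms = delta_ms, Delta_ms = Delta_ms)
}
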
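# shared small fixtures, built once per test run

# the acquisition-matched scheme: 30 directions x b = 1000/1500/2000 + 5 b0
study_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_scheme(30, c(1000, 1500, 2000), 5, seed = 1)
    cache
  }
})

# independent evaluation of the signal model, written directly from the
# log-signal expansion with an explicit rank-4 contraction loop (no shared
# code with the package internals)
oracle_forward <- function(S0, D6, W15, n, b) {
  Dm <- matrix(c(D6[1], D6[4], D6[5],
                 D6[4], D6[2], D6[6],
                 D6[5], D6[6], D6[3]), 3, 3)
  d_app <- drop(t(n) %*% Dm %*% n)
  md <- sum(diag(Dm)) / 3
  # expand the 15 unique components into the full 3x3x3x3 tensor
  Wfull <- array(0, c(3, 3, 3, 3))
  idx <- matrix(c(
    1,1,1,1, 1,1,1,2, 1,1,1,3, 1,1,2,2, 1,1,2,3,
    1,1,3,3, 1,2,2,2, 1,2,2,3, 1,2,3,3, 1,3,3,3,
    2,2,2,2, 2,2,2,3, 2,2,3,3, 2,3,3,3, 3,3,3,3
  ), ncol = 4, byrow = TRUE)
  for (c in 1:15) {
    for (p in unique(asplit(perms4(idx[c, ]), 1))) {
      Wfull[p[1], p[2], p[3], p[4]] <- W15[c]
    }
  }
  w_app <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    w_app <- w_app + n[i] * n[j] * n[k] * n[l] * Wfull[i, j, k, l]
  }
  k_app <- (md^2 / d_app^2) * w_app
  S0 * exp(-b * d_app + b^2 * d_app^2 * k_app / 6)
}

# all permutations of a length-4 index vector
perms4 <- function(v) {
  p <- expand.grid(1:4, 1:4, 1:4, 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), ]
  m <- t(apply(p, 1, function(r) v[as.integer(r)]))
  unique(m)
}

# brute-force 2-parameter fit by Nelder-Mead on the squared log-residuals,
# refined from a coarse grid start (independent of the linear-LS path)
oracle_fit_direction <- function(log_ratios, bvalues) {
  obj <- function(par) {
    d <- par[1]; k <- par[2]
    sum((log_ratios - (-bvalues * d + bvalues^2 * d^2 * k / 6))^2)
  }
  grid_d <- seq(1e-4, 3e-3, length.out = 40)
  grid_k <- seq(0, 3, length.out = 40)
  g <- expand.grid(d = grid_d, k = grid_k)
  start <- unlist(g[which.min(apply(g, 1, obj)), ])
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 5000))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 5000))
  list(D_app = fit$par[[1]], K_app = fit$par[[2]])
}

# a small balanced two-measure longitudinal table
toy_cohort <- function(seed = 1, n = 4, sd_b = 0.05, sd_w = 0.05,
                       times = c("baseline", "d1", "d7", "d14", "d28"),
                       means = NULL) {
  make_cohort_table(cohort_spec(
    n_per_group = n, timepoints = times,
    means = means %||% matrix(1, 2, length(times)),
    sd_between = sd_b, sd_within = sd_w, seed = seed
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
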
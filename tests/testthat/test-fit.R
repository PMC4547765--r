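test_that("fit_direction recovers known parameters and flags degeneracy", {
  b <- c(1000, 1500, 2000)
  # exact synthetic ratios from D = 1e-3, K = 1
  y <- -b * 1e-3 + b^2 * (1e-3)^2 * 1 / 6
  fit <- fit_direction(y, b)
  expect_equal(fit$D_app, 1e-3, tolerance = 1e-8)
  expect_equal(fit$K_app, 1, tolerance = 1e-8)
  expect_false(fit$degenerate)
  expect_lt(fit$residual, 1e-12)

  # mono-exponential: K comes back 0
  y0 <- -b * 2e-3
  fit0 <- fit_direction(y0, b)
  expect_equal(fit0$D_app, 2e-3, tolerance = 1e-10)
  expect_equal(fit0$K_app, 0, tolerance = 1e-8)

  # no decay at all: degenerate (0, 0)
  fd <- fit_direction(c(0, 0, 0), b)
  expect_true(fd$degenerate)
  expect_identical(c(fd$D_app, fd$K_app), c(0, 0))

  expect_error(fit_direction(c(-1, -2), c(1000, 1000)), "distinct")
})

test_that("the linear fit agrees with an independent grid/Nelder-Mead optimizer", {
  b <- c(1000, 1500, 2000)
  set.seed(21)
  for (i in 1:100) {
    d <- runif(1, 4e-4, 2.5e-3)
    k <- runif(1, 0.1, 2.5)
    y <- -b * d + b^2 * d^2 * k / 6
    lin <- fit_direction(y, b)
    ora <- oracle_fit_direction(y, b)
    expect_equal(lin$D_app, ora$D_app, tolerance = 1e-6)
    expect_equal(lin$K_app, ora$K_app, tolerance = 1e-6)
  }
})

test_that("K_app clamping is applied and recorded", {
  b <- c(1000, 1500, 2000)
  d <- 1e-3
  y_hi <- -b * d + b^2 * d^2 * 5 / 6 # true K = 5, above the clamp
  fit <- fit_direction(y_hi, b, k_clamp = c(0, 3))
  expect_true(fit$clamped)
  expect_equal(fit$K_app, 3)
})

test_that("the tensor fit round-trips isotropic and anisotropic ground truth", {
  dirs <- study_scheme()$directions
  # isotropy: constant D_app on well-spread directions
  iso <- fit_dti_tensor(rep(8e-4, 30), dirs)
  expect_equal(iso$evals, rep(8e-4, 3), tolerance = 1e-10)
  expect_equal(iso$D, c(8e-4, 8e-4, 8e-4, 0, 0, 0), tolerance = 1e-10)

  # forward n'Dn oracle for diag(1.7, 0.4, 0.3)e-3
  Dm <- diag(c(1.7, 0.4, 0.3)) * 1e-3
  d_app <- rowSums((dirs %*% Dm) * dirs)
  est <- fit_dti_tensor(d_app, dirs)
  expect_equal(est$D, c(diag(Dm), 0, 0, 0), tolerance = 1e-10)
  expect_equal(est$evals, sort(diag(Dm), decreasing = TRUE), tolerance = 1e-10)
  expect_false(est$clamped)

  expect_error(fit_dti_tensor(rep(1e-3, 5), dirs[1:5, ]), ">= 6")
  # 7 coplanar directions: rank-deficient
  ang <- seq(0, pi, length.out = 7)
  flat <- cbind(cos(ang), sin(ang), 0)
  expect_error(fit_dti_tensor(rep(1e-3, 7), flat), "rank-deficient")
})

test_that("tensor metrics match their closed forms", {
  expect_equal(tensor_metrics(c(1, 1, 1) * 1e-3), c(MD = 1e-3, FA = 0))
  expect_equal(tensor_metrics(c(1, 0, 0))[["FA"]], 1)
  expect_equal(tensor_metrics(c(0, 0, 0)), c(MD = 0, FA = 0))
  # hand evaluation for (1.7, 0.4, 0.3)e-3
  ev <- c(1.7, 0.4, 0.3) * 1e-3
  md <- mean(ev)
  fa_hand <- sqrt(3 / 2) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
  m <- tensor_metrics(ev)
  expect_equal(m[["MD"]], 0.8e-3, tolerance = 1e-12)
  expect_equal(m[["FA"]], fa_hand)
  expect_equal(round(m[["FA"]], 4), 0.7634)
})

test_that("MK averages K_app over the retained directions only", {
  expect_equal(compute_mk(rep(0.8, 30))$MK, 0.8)
  expect_equal(compute_mk(c(0.5, 1.0, 1.5))$MK, 1.0)
  k <- runif(30, 0, 2)
  flag <- rep(FALSE, 30); flag[c(3, 17, 25)] <- TRUE
  res <- compute_mk(k, flag)
  expect_equal(res$MK, sum(k[-c(3, 17, 25)]) / 27)
  expect_equal(res$n_excluded, 3L)
  all_bad <- compute_mk(k, rep(TRUE, 30))
  expect_true(is.na(all_bad$MK))
})

test_that("fit_volume handles degenerate input without crashing", {
  sch <- make_scheme(6, c(1000, 2000), 2, seed = 1)
  zero <- dwi_series(array(0, c(3, 3, 2, n_volumes(sch))), sch)
  maps <- fit_volume(zero)
  expect_true(all(maps$codes == 1)) # every voxel flagged negative-signal
  expect_true(all(is.na(maps$mk)))
  expect_true(all(is.na(maps$md)))
})

test_that("directional and joint fit modes agree on noise-free phantoms", {
  tr <- phantom_geometry("tract", dim = c(6, 6, 4), K1 = 0.7)
  ph <- make_phantom(tr, study_scheme(), sigma = 0)
  m_dir <- fit_volume(ph, fit_mode = "directional")
  m_joint <- fit_volume(ph, fit_mode = "joint")
  expect_equal(m_dir$mk, m_joint$mk, tolerance = 1e-6)
  expect_equal(m_dir$md, m_joint$md, tolerance = 1e-9)
  expect_equal(m_dir$fa, m_joint$fa, tolerance = 1e-6)
})

test_that("maps are invariant to volume permutation applied with the scheme", {
  tr <- phantom_geometry("two_block", dim = c(4, 4, 2), K1 = 0.5, K2 = 1.1)
  sch <- make_scheme(8, c(1000, 2000), 2, seed = 3)
  ph <- make_phantom(tr, sch, sigma = 10, seed = 9)
  pre <- withr::local_tempfile()
  write_dwi(ph, pre)
  straight <- read_dwi(paste0(pre, ".nii.gz"), paste0(pre, ".bval"), paste0(pre, ".bvec"))

  set.seed(2)
  perm <- sample(n_volumes(sch))
  img <- RNifti::asNifti(ph$data[, , , perm])
  RNifti::pixdim(img) <- c(ph$voxel_size, 1)
  RNifti::writeNifti(img, paste0(pre, "p.nii.gz"))
  writeLines(paste(sch$bvalues[perm], collapse = " "), paste0(pre, "p.bval"))
  writeLines(apply(t(sch$bvecs[perm, ]), 1, paste, collapse = " "), paste0(pre, "p.bvec"))
  permuted <- read_dwi(paste0(pre, "p.nii.gz"), paste0(pre, "p.bval"), paste0(pre, "p.bvec"))

  m1 <- fit_volume(straight)
  m2 <- fit_volume(permuted)
  expect_equal(m1$mk, m2$mk, tolerance = 1e-9)
  expect_equal(m1$fa, m2$fa, tolerance = 1e-9)
})
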
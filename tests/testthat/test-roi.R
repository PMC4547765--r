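# build a param_maps object directly for ROI tests
fake_maps <- function(mk, codes = NULL) {
  dm <- dim(mk)
  codes <- codes %||% array(0L, dm)
  dkiblast:::new_param_maps(mk, mk, mk, codes, c(1, 1, 1), list())
}

test_that("ROI means respect failure flags and report voxel counts", {
  dm <- c(4, 4, 2)
  mk <- array(0.9, dm)
  maps <- fake_maps(mk)
  m <- roi_mask(array(TRUE, dm), "hippocampus", "left")
  expect_equal(extract_roi_mean(maps, m, "MK")$value, 0.9)

  vals <- array(NA_real_, dm)
  vals[1:4] <- c(0.5, 0.5, 1.0, 1.0)
  sel <- array(FALSE, dm); sel[1:4] <- TRUE
  maps2 <- fake_maps(vals)
  m2 <- roi_mask(sel, "hippocampus", "left")
  expect_equal(extract_roi_mean(maps2, m2, "MK")$value, 0.75)

  # one flagged voxel is excluded from the mean
  codes <- array(0L, dm); codes[1] <- 2L
  vals3 <- array(NA_real_, dm); vals3[1:4] <- c(99, 1, 1, 1)
  res <- extract_roi_mean(fake_maps(vals3, codes), m2, "MK")
  expect_equal(res$value, 1.0)
  expect_equal(res$n_used, 3L)

  all_bad <- extract_roi_mean(fake_maps(vals3, array(2L, dm)), m2, "MK")
  expect_true(is.na(all_bad$value))
  expect_match(all_bad$reason, "flagged")
})

test_that("bilateral averaging is symmetric with single-side passthrough", {
  expect_equal(bilateral_average(0.8, 1.0)$value, 0.9)
  one <- bilateral_average(0.8, NA)
  expect_equal(one$value, 0.8)
  expect_true(one$unilateral)
  expect_true(is.na(bilateral_average(NA, NA)$value))
  set.seed(31)
  for (i in 1:100) {
    l <- runif(1); r <- runif(1)
    expect_equal(bilateral_average(l, r)$value, (l + r) / 2)
    expect_equal(bilateral_average(l, r)$value, bilateral_average(r, l)$value)
  }
})

test_that("baseline normalization divides by each subject's baseline", {
  tab <- toy_cohort(seed = 8)
  norm <- normalize_to_baseline(tab)
  base <- norm[as.character(norm$time) == "baseline", ]
  expect_true(all(base$normalized_value == 1))
  # direct division oracle
  one <- norm[norm$subject == "s01" & as.character(norm$time) == "d7", ]
  b <- tab$value[tab$subject == "s01" & as.character(tab$time) == "baseline"]
  expect_equal(one$normalized_value, one$value / b)
  # scale invariance: multiplying a subject's raw values leaves ratios unchanged
  tab2 <- tab
  tab2$value[tab2$subject == "s01"] <- tab2$value[tab2$subject == "s01"] * 3.7
  norm2 <- normalize_to_baseline(tab2)
  expect_equal(norm2$normalized_value, norm$normalized_value, tolerance = 1e-12)
})

test_that("zero or missing baselines mark the series non-normalizable", {
  tab <- toy_cohort(seed = 9)
  tab$value[tab$subject == "s02" & as.character(tab$time) == "baseline"] <- 0
  norm <- normalize_to_baseline(tab)
  expect_true(all(is.na(norm$normalized_value[norm$subject == "s02"])))
  expect_false(anyNA(norm$normalized_value[norm$subject != "s02"]))
})

test_that("complete-case filtering drops exactly the incomplete subjects", {
  tab <- toy_cohort(seed = 10, n = 6)
  full <- complete_case_filter(tab, levels(tab$time))
  expect_equal(nrow(full), nrow(tab))
  expect_length(attr(full, "dropped"), 0)

  drop1 <- tab[!(tab$subject == "i03" & as.character(tab$time) == "d14"), ]
  filt <- complete_case_filter(drop1, levels(tab$time))
  expect_equal(attr(filt, "dropped"), "i03")
  expect_equal(dplyr::n_distinct(filt$subject), 11)

  # idempotence
  again <- complete_case_filter(filt, levels(tab$time))
  expect_equal(as.data.frame(again), as.data.frame(filt), ignore_attr = TRUE)

  # randomized missingness vs an independent set-intersection oracle
  set.seed(77)
  for (rep in 1:10) {
    holes <- tab[runif(nrow(tab)) > 0.08, ]
    got <- complete_case_filter(holes, levels(tab$time))
    oracle <- Reduce(intersect, lapply(levels(tab$time), function(tp) {
      unique(holes$subject[as.character(holes$time) == tp])
    }))
    expect_setequal(unique(got$subject), oracle)
  }
})

test_that("roi_table assembles per-region longitudinal rows with bilateral averaging", {
  dm <- c(4, 4, 2)
  mk <- array(NA_real_, dm)
  left <- array(FALSE, dm); left[1:2, , ] <- TRUE
  right <- array(FALSE, dm); right[3:4, , ] <- TRUE
  mk[left] <- 0.8; mk[right] <- 1.0
  maps <- fake_maps(mk)
  masks <- list(roi_mask(left, "hippocampus", "left"),
                roi_mask(right, "hippocampus", "right"))
  rows <- roi_table(maps, masks, subject = "r1", group = "sham", time = "d1",
                    measures = "MK")
  expect_equal(nrow(rows), 1)
  expect_equal(rows$value, 0.9)
})
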
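test_that("rank transformation uses midranks and preserves missingness", {
  expect_equal(rank_transform(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_transform(c(1, 1, 2)), c(1.5, 1.5, 3))
  expect_equal(rank_transform(c(2, NA, 1)), c(2, NA, 1))
  expect_error(rank_transform(c(NA_real_, NA_real_)), "finite")
  # invariance under strictly increasing transforms
  set.seed(13)
  for (i in 1:100) {
    x <- rnorm(12)
    expect_equal(rank_transform(x), rank_transform(exp(x)))
    expect_equal(rank_transform(x), rank_transform(2 * x + 5))
  }
})

test_that("the split-plot partition matches a hand-computed toy example", {
  # g1 subjects (1,2) and (2,3); g2 subjects (3,4) and (4,5) across two times:
  # grand = 3; SS_group = 8, SS_subj = 2, SS_time = 2, SS_int = 0, SS_resid = 0
  tab <- tibble::tibble(
    subject = rep(c("a", "b", "c", "d"), each = 2),
    group = rep(c("g1", "g2"), each = 4),
    time = factor(rep(c("t1", "t2"), 4)),
    region = "r", measure = "m",
    value = c(1, 2, 2, 3, 3, 4, 4, 5)
  )
  fit <- tidy(mixed_anova(tab))
  expect_equal(fit$ss, c(8, 2, 2, 0, 0))
  expect_equal(fit$df, c(1L, 2L, 1L, 1L, 2L))
  expect_equal(fit$statistic[1], 8) # MS_group / MS_subj = 8/1
})

test_that("F ratios and SS agree with aov's Error-stratified split-plot fit", {
  shift <- matrix(1, 2, 5); shift[2, 3:4] <- 1.12
  tab <- toy_cohort(seed = 19, n = 6, means = shift)
  fit <- mixed_anova(tab)
  a <- summary(stats::aov(value ~ group * time + Error(subject), data = tab))
  btw <- a[["Error: subject"]][[1]]
  wth <- a[["Error: Within"]][[1]]
  got <- tidy(fit)
  expect_equal(got$ss[got$effect == "group"], btw["group", "Sum Sq"], tolerance = 1e-9)
  expect_equal(got$ss[got$effect == "subject_within_group"], btw["Residuals", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(got$statistic[got$effect == "time"], wth["time", "F value"], tolerance = 1e-9)
  expect_equal(got$statistic[got$effect == "group_x_time"], wth["group:time", "F value"],
               tolerance = 1e-9)
  expect_equal(got$p.value[got$effect == "group"], btw["group", "Pr(>F)"], tolerance = 1e-9)
})

test_that("sums of squares are conserved and location/scale behave classically", {
  tab <- toy_cohort(seed = 23, n = 6)
  fit <- mixed_anova(tab)
  expect_equal(sum(tidy(fit)$ss), fit$ss_total, tolerance = 1e-9 * fit$ss_total)

  shifted <- tab; shifted$value <- shifted$value + 11.3
  scaled <- tab; scaled$value <- scaled$value * 4.2
  f0 <- tidy(fit); f1 <- tidy(mixed_anova(shifted)); f2 <- tidy(mixed_anova(scaled))
  expect_equal(f1$statistic, f0$statistic, tolerance = 1e-9)
  expect_equal(f2$statistic, f0$statistic, tolerance = 1e-9)
  expect_equal(f2$ss, f0$ss * 4.2^2, tolerance = 1e-9)
  expect_equal(f2$p.value, f0$p.value, tolerance = 1e-9)
})

test_that("the between-group F is the squared unpaired t on subject means", {
  tab <- toy_cohort(seed = 29, n = 5)
  fit <- mixed_anova(tab)
  sm <- tapply(tab$value, list(tab$subject, tab$group), mean)
  tt <- unpaired_t(sm[!is.na(sm[, "injured"]), "injured"],
                   sm[!is.na(sm[, "sham"]), "sham"])
  expect_equal(tidy(fit)$statistic[1], tt$statistic^2, tolerance = 1e-9)
})

test_that("unbalanced or incomplete designs are rejected with the offender named", {
  tab <- toy_cohort(seed = 31, n = 4)
  expect_error(mixed_anova(tab[-3, ]), "unbalanced|incomplete")
  expect_error(mixed_anova(tab[-3, ]), "s01")
  lop <- tab[tab$subject != "s04", ]
  expect_error(mixed_anova(lop), "unbalanced|incomplete")
})

test_that("Fisher's LSD matches per-time t-tests in its plain mode and flags shifts", {
  shift <- matrix(1, 2, 5); shift[2, 4] <- 1.4
  tab <- toy_cohort(seed = 37, n = 6, means = shift)
  fit <- mixed_anova(tab)
  ph <- fisher_lsd(fit, error = "per_time")
  d14 <- tab[as.character(tab$time) == "d14", ]
  tt <- unpaired_t(d14$value[d14$group == "injured"], d14$value[d14$group == "sham"])
  row <- ph[ph$time == "d14", ]
  expect_equal(row$statistic, tt$statistic, tolerance = 1e-9)
  expect_equal(row$p.value, tt$p.value, tolerance = 1e-9)
  expect_equal(row$estimate, tt$estimate, tolerance = 1e-9)

  comb <- fisher_lsd(fit)
  expect_true(comb$significant[comb$time == "d14"])
  # identical group means: zero difference, p = 1
  flat <- toy_cohort(seed = 38, n = 4, sd_b = 0, sd_w = 0)
  ph0 <- fisher_lsd(mixed_anova(flat))
  expect_true(all(ph0$estimate == 0))
  expect_true(all(ph0$p.value == 1))
})

test_that("a d14-only shift of 4 SE is detected at d14 and rarely elsewhere", {
  n_rep <- 500
  hit_d14 <- 0
  hit_other <- integer(4)
  # 4 SE of the group-difference at one time: SE ~ sqrt(MS_cell * 2/6)
  for (i in seq_len(n_rep)) {
    shift <- matrix(1, 2, 5)
    se_cell <- sqrt((0.05^2 + 0.05^2) * 2 / 6)
    shift[2, 4] <- 1 + 4 * se_cell
    tab <- toy_cohort(seed = 5000 + i, n = 6, means = shift)
    ph <- fisher_lsd(mixed_anova(tab))
    hit_d14 <- hit_d14 + ph$significant[ph$time == "d14"]
    hit_other <- hit_other + ph$significant[ph$time != "d14"]
  }
  expect_gte(hit_d14 / n_rep, 0.95)
  expect_true(all(hit_other / n_rep < 0.15)) # other times near the nominal rate
})

test_that("the pooled t-test matches its closed form and handles degeneracy", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  tt <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  # pooled SD = 1, SE = sqrt(2/3), t = -3 / sqrt(2/3)
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  rev <- unpaired_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p.value, tt$p.value)

  const <- unpaired_t(c(2, 2, 2), c(5, 5, 5))
  expect_true(const$degenerate)
  expect_equal(const$p.value, 0)
  const2 <- unpaired_t(c(2, 2), c(2, 2))
  expect_equal(const2$p.value, 1)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("rank-transformed ANOVA is invariant to monotone data transforms", {
  shift <- matrix(1, 2, 5); shift[2, ] <- 1.2
  tab <- toy_cohort(seed = 41, n = 4, means = shift)
  f1 <- tidy(mixed_anova(tab, ranked = TRUE))
  tab2 <- tab; tab2$value <- exp(tab2$value)
  f2 <- tidy(mixed_anova(tab2, ranked = TRUE))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
})

test_that("tidy and glance expose the fitted ANOVA in broom style", {
  fit <- mixed_anova(toy_cohort(seed = 43))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("effect", "ss", "df", "ms", "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$F_group, td$statistic[td$effect == "group"])
  rep <- capture.output(report_anova(fit, fisher_lsd(fit)))
  expect_true(any(grepl("F\\(1,6\\)", rep))) # g(s-1) = 6 with 4 subjects/group
})
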
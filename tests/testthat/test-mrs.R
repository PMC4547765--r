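test_that("metabolite tables load with validation and vocabulary warnings", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    metabolite = c("NAA", "Ins", "Tau", "tCr"),
    concentration = c(7.5, 5.2, 6.1, 8.0),
    crlb_percent = c(4, 6, 5, 3)
  ), f)
  tab <- load_metabolite_table(f)
  expect_equal(nrow(tab), 4)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("metabolite,concentration,crlb_percent", g)
  expect_equal(nrow(load_metabolite_table(g)), 0)

  h <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metabolite = "NotAMetab", concentration = 1,
                                  crlb_percent = 5), h)
  expect_warning(load_metabolite_table(h), "unrecognised")

  i <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(metabolite = "NAA", conc = 1), i)
  expect_error(load_metabolite_table(i), "lacks column")
})

test_that("generator output survives a write/read round trip at full precision", {
  tab <- make_metabolite_table(c("NAA", "Gln"), c(pi, exp(1)), c(5.123456789, 12.3456789))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, f)
  back <- load_metabolite_table(f)
  expect_equal(back$concentration, tab$concentration, tolerance = 1e-15)
  expect_equal(back$crlb_percent, tab$crlb_percent, tolerance = 1e-15)
})

test_that("the CRLB gate is strict, idempotent and order-preserving", {
  rec <- tibble::tibble(
    metabolite = c("NAA", "Ins", "Lac"),
    concentration = c(7, 5, 1),
    crlb_percent = c(5, 19, 25)
  )
  kept <- filter_crlb(rec, 20)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$metabolite, c("NAA", "Ins"))
  expect_equal(attr(kept, "excluded")$metabolite, "Lac")

  # boundary: CRLB exactly at the threshold is excluded ("less than")
  atb <- tibble::tibble(metabolite = "Glu", concentration = 3, crlb_percent = 20)
  expect_equal(nrow(filter_crlb(atb, 20)), 0)

  expect_equal(nrow(filter_crlb(rec, 1000)), 3)
  twice <- filter_crlb(filter_crlb(rec, 20), 20)
  expect_equal(twice$metabolite, kept$metabolite)
  expect_error(filter_crlb(rec, 0), "in \\[")
})

test_that("tCr ratios divide by the reference and are scale-invariant", {
  rec <- tibble::tibble(
    metabolite = c("Tau", "tCr"),
    concentration = c(4, 8),
    crlb_percent = c(5, 3)
  )
  r <- ratio_to_tcr(rec)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$measure, "Tau/tCr")
  expect_false("tCr" %in% r$metabolite)

  scaled <- rec; scaled$concentration <- scaled$concentration * 7.3
  expect_equal(ratio_to_tcr(scaled)$ratio, r$ratio, tolerance = 1e-12)

  no_tcr <- rec[rec$metabolite != "tCr", ]
  expect_error(ratio_to_tcr(no_tcr), "unusable")

  # independent division oracle on random tables
  set.seed(53)
  for (i in 1:10) {
    mets <- sprintf("M%02d", 1:6)
    tab <- make_metabolite_table(mets, runif(6, 1, 10), runif(6, 1, 15),
                                 tcr_concentration = runif(1, 5, 10))
    rr <- suppressWarnings(ratio_to_tcr(tab))
    tcr <- tab$concentration[tab$metabolite == "tCr"]
    expect_equal(rr$ratio, tab$concentration[tab$metabolite != "tCr"] / tcr)
  }
})

test_that("gated ratios merge into longitudinal rows, dropping unreliable cells", {
  rec <- make_metabolite_table(c("NAA", "Ins", "Lac"), c(7, 5, 1), c(5, 19, 25))
  rows <- mrs_longitudinal_rows(rec, subject = "r1", group = "sham", time = "d7")
  expect_equal(nrow(rows), 2) # Lac fails the gate; tCr is the reference
  expect_setequal(rows$measure, c("NAA/tCr", "Ins/tCr"))
  expect_equal(rows$time, rep("d7", 2))
})
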
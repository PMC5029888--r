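test_that("decrease rate follows the defining formula and its invariances", {
  expect_equal(decreaseRate(10, 5), 50)
  expect_equal(decreaseRate(12.57, 12.57), 0)
  expect_equal(decreaseRate(8, 2), 75)
  expect_lt(decreaseRate(5, 6), 0)                  # wound grew
  expect_error(decreaseRate(0, 1), "positive")
  # scale invariance
  for (c in c(0.1, 3, 100))
    expect_equal(decreaseRate(10 * c, 4 * c), decreaseRate(10, 4))
})

test_that("half-decrement day interpolates the first threshold crossing", {
  s1 <- woundSeries("a", c(0, 10, 20), c(10, 6, 2))
  expect_equal(halfDecrementDay(s1), 10)            # threshold 6 hit exactly
  s2 <- woundSeries("b", c(0, 14), c(10, 4))
  expect_equal(halfDecrementDay(s2), 7)             # threshold 7, interpolated
  # nearest mode returns a visit day (crossing at 12 -> day 10)
  s2b <- woundSeries("b2", c(0, 10, 20), c(10, 7, 2))
  expect_equal(halfDecrementDay(s2b, mode = "nearest"), 10)
  expect_error(halfDecrementDay(woundSeries("c", 0, 5)),
               "half-decrement undefined")
  expect_error(halfDecrementDay(woundSeries("d", c(0, 10), c(5, 5))),
               "half-decrement undefined")
  # non-monotonic series: the first crossing wins
  s3 <- woundSeries("e", c(0, 5, 10, 15), c(10, 4, 8, 2))
  thr <- 10 - 0.5 * (10 - 2)
  expect_equal(halfDecrementDay(s3), 5 * (10 - thr) / (10 - 4))
  # time dilation scales the crossing day linearly
  s4 <- woundSeries("f", c(0, 28), c(10, 4))
  expect_equal(halfDecrementDay(s4), 2 * halfDecrementDay(s2))
  # strictly monotone series: crossing strictly inside the follow-up
  s5 <- woundSeries("g", c(0, 7, 21), c(9, 5, 1))
  hd <- halfDecrementDay(s5)
  expect_gt(hd, 0); expect_lt(hd, 21)
})

test_that("series summaries compose the component statistics", {
  s <- summarizeSeries(woundSeries("p1", c(0, 30), c(2, 0.5)))
  expect_equal(s@decreaseRatePct, 75)
  expect_equal(s@halfDecrementDay, 15)
  expect_equal(s@followUpDays, 30)
  flat <- summarizeSeries(woundSeries("p2", c(0, 10), c(1, 1)))
  expect_equal(flat@decreaseRatePct, 0)
  expect_true(is.na(flat@halfDecrementDay))
})

test_that("series validity enforces the observation contract", {
  expect_error(woundSeries("x", c(1, 2), c(3, 2)), "day")       # day 0 missing
  expect_error(woundSeries("x", c(0, 5, 5), c(3, 2, 1)), "increasing")
  expect_error(woundSeries("x", c(0, 5), c(3, -1)), "positive")
})

test_that("exponential-decay series recover the analytic half-decrement day", {
  lam <- 0.1; Tf <- 56
  tTrue <- analyticHalfDay(lam, Tf)
  # noiseless weekly sampling interpolates within a day of the closed form
  s0 <- simulateHealingSeries(lambda = lam, followUpDays = Tf, cv = 0)
  expect_lt(abs(halfDecrementDay(s0) - tTrue), 1)
  # decrease rate matches the analytic decrement
  expect_lt(abs(summarizeSeries(s0)@decreaseRatePct -
                100 * (1 - exp(-lam * Tf))), 1e-9)
})

test_that("group tables report n, mean and sample SD per group", {
  mk <- function(id, rate, site) {
    A0 <- 10; Af <- A0 * (1 - rate / 100)
    summarizeSeries(woundSeries(id, c(0, 28, 56),
                                c(A0, (A0 + Af) / 2, Af), site))
  }
  tab <- groupTable(list(mk("a", 50, "facial"), mk("b", 70, "facial")))
  expect_equal(tab$n, 2L)
  expect_equal(tab$mean_decrease_pct, 60)
  expect_equal(tab$sd_decrease_pct, sd(c(50, 70)))
  expect_equal(tab$sd_decrease_pct, 14.1421, tolerance = 1e-4)
  # empty second group yields an NA row, no crash
  tab2 <- groupTable(list(mk("a", 50, "facial")),
                     labels = c("facial"))
  full <- rbind(tab2, data.frame(group = "non_facial", n = 0L,
                                 mean_decrease_pct = NA_real_,
                                 sd_decrease_pct = NA_real_,
                                 mean_half_day = NA_real_,
                                 sd_half_day = NA_real_,
                                 n_half_undefined = NA_integer_))
  expect_equal(nrow(full), 2L)
  # undefined half-days are excluded and counted
  flat <- summarizeSeries(woundSeries("z", c(0, 10), c(1, 1)))
  tab3 <- groupTable(list(mk("a", 50, "facial"), flat),
                     labels = c("g", "g"))
  expect_equal(tab3$n_half_undefined, 1L)
})

test_that("synthetic cohort realizes the generator's group distributions", {
  cohort <- simulateCohort(nPerGroup = 30L, seed = 21)
  summaries <- lapply(cohort, summarizeSeries)
  tab <- groupTable(summaries)
  fac <- tab[tab$group == "facial", ]
  non <- tab[tab$group == "non_facial", ]
  expect_equal(fac$n, 30L)
  expect_lt(abs(fac$mean_decrease_pct - 67), 3)
  expect_lt(abs(non$mean_decrease_pct - 53), 3)
})
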
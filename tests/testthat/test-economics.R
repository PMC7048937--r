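make_trace <- function(pf, pd = rep(0, length(pf)), g12 = 0, g34 = 0,
                       hosp = 0) {
  H <- length(pf)
  tr <- data.frame(cycle = 0:H, pf = c(1, pf), pd = c(0, pd),
                   dead_cancer = 0, dead_ae = 0, dead_other = 0,
                   ae_g12 = c(0, rep(g12, H)), ae_g34 = c(0, rep(g34, H)),
                   discontinued = 0, ae_deaths = 0,
                   hospitalized = c(0, rep(hosp, H)))
  tr$dead_cancer <- 1 - tr$pf - tr$pd
  class(tr) <- c("gc_trace", "data.frame")
  tr
}

test_that("discount factors follow annual compounding per cycle", {
  expect_equal(discount_factor(c(0, 7, 31), 0), rep(1, 3))
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(6, 0.03), 1.03^(-0.5))
  expect_equal(discount_factor(24, 0.03), 1.03^-2)
})

test_that("one treated cycle accrues drug, administration and follow-up", {
  econ0 <- basecase$econ
  econ0$annual_discount <- 0
  tr <- make_trace(pf = 1)  # single cycle, everyone progression-free
  out <- accrue(tr, basecase$arms$pac, econ0)
  # paclitaxel 66.53 + administration 1412 + follow-up 818.74
  expect_equal(out$cost, 66.53 + 1412 + 818.74)
  expect_equal(out$qalys, 0.622 / 12)
  expect_equal(out$life_years, 1 / 12)
})

test_that("an extinct cohort accrues only the one-time test cost", {
  tr <- make_trace(pf = rep(0, 60))
  out <- accrue(tr, basecase$arms$pac, basecase$econ, test_cost = 348.56)
  expect_equal(out$cost, 348.56)
  expect_equal(out$qalys, 0)
})

test_that("discounting only reduces totals; zero utilities give zero QALYs", {
  arm <- basecase$arms$ram_pac
  tr <- run_cohort(arm, basecase$econ, basecase$life_table, basecase$cohort)
  disc <- accrue(tr, arm, basecase$econ)
  econ0 <- basecase$econ; econ0$annual_discount <- 0
  undisc <- accrue(tr, arm, econ0)
  expect_lt(disc$cost, undisc$cost)
  expect_lt(disc$qalys, undisc$qalys)
  expect_equal(disc$life_years, undisc$life_years)

  econz <- basecase$econ
  econz$utility_pf <- 0; econz$utility_pd <- 0
  armz <- arm; armz$ae$disutility_grade12 <- 0; armz$ae$disutility_grade34 <- 0
  expect_equal(suppressWarnings(accrue(tr, armz, econz)$qalys), 0)
})

test_that("total cost is linear in the cost inputs", {
  arm <- basecase$arms$pac
  tr <- run_cohort(arm, basecase$econ, basecase$life_table, basecase$cohort)
  base <- accrue(tr, arm, basecase$econ, test_cost = 100)
  arm2 <- arm
  arm2$drug_cost <- 2 * arm$drug_cost
  arm2$admin_cost <- 2 * arm$admin_cost
  arm2$ae$cost_grade34 <- 2 * arm$ae$cost_grade34
  econ2 <- basecase$econ
  econ2$bsc_cost_pd <- 2 * econ2$bsc_cost_pd
  econ2$followup_cost_pf <- 2 * econ2$followup_cost_pf
  doubled <- accrue(tr, arm2, econ2, test_cost = 200)
  expect_equal(doubled$cost, 2 * base$cost, tolerance = 1e-12)
})

test_that("QALYs never exceed life years for any base-case strategy", {
  res <- evaluate_all(basecase)
  expect_true(all(res$qalys <= res$life_years))
  expect_true(all(res$qalys >= 0))
  expect_true(all(res$cost >= 0))
})

test_that("the ratio and net-benefit arithmetic is as printed", {
  a <- list(cost = 0, qalys = 0)
  b <- list(cost = 100000, qalys = 1)
  expect_equal(icer(a, b), 100000)
  # rounded published base-case entries for supportive care and paclitaxel
  expect_equal(icer(list(cost = 29614, qalys = 0.21),
                    list(cost = 40108, qalys = 0.41)), 52470)
  expect_error(icer(b, b), "dominance")
  expect_equal(net_monetary_benefit(list(cost = 40108, qalys = 0.41), 1e5), 892)
  expect_equal(net_monetary_benefit(list(cost = 500, qalys = 1), 0), -500)
})
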
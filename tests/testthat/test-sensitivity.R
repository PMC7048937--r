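test_that("an inert parameter leaves the comparison's ICER unchanged", {
  # ramucirumab toxicity disutility touches neither compared strategy
  ow <- one_way(basecase, "du12_ram_pac", comparison = c("msi_pem_pac", "pac_all"))
  expect_equal(ow$icer_low, ow$icer_base)
  expect_equal(ow$icer_high, ow$icer_base)
})

test_that("ICER is linear in a linearly entering cost parameter", {
  entry <- basecase$sensitivity$cost_pem
  at <- function(v) {
    one_way(basecase, "cost_pem", low = v, high = v)$icer_low
  }
  v1 <- entry$low; v3 <- entry$high; v2 <- (v1 + v3) / 2
  i1 <- at(v1); i2 <- at(v2); i3 <- at(v3)
  expect_equal(i2, (i1 + i3) / 2, tolerance = 1e-9)
})

test_that("parameter setters round-trip through the model", {
  m <- set_parameter(basecase, "utility_pd", 0.5)
  expect_equal(m$econ$utility_pd, 0.5)
  m <- set_parameter(basecase, "prog_pac", 1.3)
  expect_equal(m$arms$pac$progression$prob,
               pmin(1, basecase$arms$pac$progression$prob * 1.3))
  # schedule shape is preserved: one multiplier for all segments
  expect_equal(m$arms$pac$progression$first, basecase$arms$pac$progression$first)
  m <- set_parameter(basecase, "cost_pem", 10831)
  tot <- m$arms$pem_msi$drug_cost + m$arms$pem_msi$admin_cost +
    m$econ$followup_cost_pf
  expect_equal(tot, 10831)
  expect_error(set_parameter(basecase, "no_such_parameter", 1), "unknown")
})

test_that("degenerate distributions reproduce the base-case ICER in every draw", {
  m <- basecase
  for (id in names(m$sensitivity)) {
    e <- m$sensitivity[[id]]
    base <- if (e$type == "multiplier") 1 else get_parameter(m, id)
    e$distribution <- "uniform"; e$low <- base; e$high <- base
    m$sensitivity[[id]] <- e
  }
  res <- psa(m, c("msi_pem_pac", "pac_all"), n = 20, seed = 5)
  base_icer <- with(res$samples, dcost / dqaly)
  expected <- one_way(basecase, "du12_ram_pac")$icer_base
  expect_equal(base_icer, rep(expected, 20), tolerance = 1e-10)
})

test_that("the PSA is reproducible from its seed", {
  a <- psa(basecase, c("pac_all", "bsc_all"), n = 60, seed = 99)
  b <- psa(basecase, c("pac_all", "bsc_all"), n = 60, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$fraction_ce, b$fraction_ce)
  c <- psa(basecase, c("pac_all", "bsc_all"), n = 60, seed = 100)
  expect_false(identical(a$samples$dcost, c$samples$dcost))
})

test_that("PSA draws respect their distribution domains", {
  set.seed(77)
  res <- psa(basecase, c("pac_all", "bsc_all"), n = 200, seed = 7)
  expect_equal(nrow(res$samples), 200)
  expect_true(all(is.finite(res$samples$dcost)))
  expect_true(all(is.finite(res$samples$dqaly)))
  expect_equal(res$fraction_ce, mean(res$samples$nmb > 0))
})

test_that("the threshold search returns the base price at the base ICER", {
  base_icer <- one_way(basecase, "du12_ram_pac")$icer_base
  thr <- threshold_price(basecase, wtp = base_icer)
  expect_equal(thr$price, basecase$arms$pem_msi$drug_cost, tolerance = 2)
})

test_that("the threshold price puts the ICER at the willingness to pay", {
  thr <- threshold_price(basecase, wtp = 1e5)
  expect_true(thr$converged)
  expect_lt(abs(thr$icer_at_price - 1e5), 1000)
  m <- basecase
  for (a in c("pem_agnostic", "pem_pdl1", "pem_msi")) {
    m$arms[[a]]$drug_cost <- thr$price
  }
  res <- evaluate_strategies(m, c("msi_pem_pac", "pac_all"))
  check <- icer(as.list(res[res$id == "pac_all", ]),
                as.list(res[res$id == "msi_pem_pac", ]))
  expect_lt(abs(check - 1e5), 1000)
})

test_that("an unreachable threshold is reported, not invented", {
  thr <- threshold_price(basecase, wtp = 1e7)
  expect_false(thr$converged)
  expect_equal(thr$price, basecase$arms$pem_msi$drug_cost)
})

test_that("costs and QALYs grow with biomarker prevalence at stable ICERs", {
  sw <- prevalence_sweep(basecase, c(0.02, 0.10, 0.22))
  expect_true(all(diff(sw$cost) > 0))
  expect_true(all(diff(sw$qalys) > 0))
  expect_true(all(diff(sw$life_years) > 0))
  expect_equal(sw$cost[sw$prevalence == 0.10],
               evaluate_strategy("msi_pem_pac", basecase)$cost)
})
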
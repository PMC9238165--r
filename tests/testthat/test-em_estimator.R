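test_that("a single carrier event gives the single-term closed form", {
  bl <- synthetic_baseline()
  cutoffs <- c(60)
  # one non-proband individual, affected at 62, posterior mass 1 on a carrier
  # state with e4 dose 0
  st <- geno_states()
  g <- which(st$apoe == "33" & st$sorl1 == "10")[1]
  ped <- toy_founder_ped(ages = 62, status = 1)
  post <- matrix(0, 1, 36)
  post[1, g] <- 1
  r <- m_step(list(post), list(ped), bl, cutoffs)
  E <- pedpen:::interval_exposures(bl, 62, 0, cutoffs)
  expect_equal(r$beta$values[2], log(1 / E[2]))
  expect_equal(r$events, c(0, 1))
  expect_true(r$zero_events[1])
  expect_identical(r$beta$values[1], -Inf)
  # an interval with no carrier exposure at all is degenerate
  expect_error(m_step(list(post), list(ped), bl, c(60, 70)),
               "coarser cutoffs")
})

test_that("the closed-form M-step maximizes the Q function", {
  set.seed(61)
  bl <- synthetic_baseline()
  for (rep in 1:10) {
    nc <- sample(1:3, 1)
    cutoffs <- sort(sample(seq(50, 80, by = 5), nc))
    n <- 5
    ages <- runif(n, 45, 84)
    status <- rbinom(n, 1, 0.7)
    # make sure every interval has at least some exposure and an event
    ped <- toy_founder_ped(c(ages, 84.5), c(status, 1))
    post <- matrix(rexp(6 * 36), 6, 36)
    post <- post / rowSums(post)
    fit <- m_step(list(post), list(ped), bl, cutoffs)
    if (any(fit$zero_events)) next
    opt <- optim(
      rep(0, nc + 1),
      function(b) -q_function(b, cutoffs, list(post), list(ped), bl),
      method = "BFGS", control = list(reltol = 1e-14, maxit = 500)
    )
    expect_equal(fit$beta$values, opt$par, tolerance = 1e-5)
  }
})

test_that("with full genotypes the EM collapses to one M-step", {
  set.seed(62)
  sc <- sim_scenario("full_data", n_families = 30)
  sim <- simulate_families(sc)
  fit <- fit_penetrance(sim$peds, sc$baseline, c(60, 70))
  expect_lte(fit$n_iterations, 2)
  expect_true(fit$converged)
  # direct closed form from mask-normalized posteriors must agree
  direct <- m_step(
    lapply(sim$peds, function(p) {
      mask <- t(vapply(seq_len(nrow(p)), function(i) {
        compatibility_mask(p$apoe[i], p$sorl1[i])
      }, numeric(36)))
      mask / rowSums(mask)
    }),
    sim$peds, sc$baseline, c(60, 70)
  )
  expect_equal(fit$beta$values, direct$beta$values, tolerance = 1e-12)
  # log-likelihood trace never decreases
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
})

test_that("EM with missing genotypes converges monotonically and counts carriers", {
  set.seed(63)
  sc <- sim_scenario("baseline_mimic", n_families = 8)
  sim <- simulate_families(sc)
  fit <- fit_penetrance(sim$peds, sc$baseline, c(60, 65, 70))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  # posterior rows normalized, zero where masks are zero
  for (f in seq_along(fit$posteriors)) {
    post <- fit$posteriors[[f]]
    expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
    ped <- sim$peds[[f]]
    for (i in seq_len(nrow(ped))) {
      m <- compatibility_mask(ped$apoe[i], ped$sorl1[i])
      expect_true(all(post[i, m == 0] == 0))
    }
  }
  # expected carrier count: recompute independently from the posterior dump
  st <- geno_states()
  ecc <- 0
  for (f in seq_along(fit$posteriors)) {
    ped <- sim$peds[[f]]
    keep <- !is.na(ped$status) & !is.na(ped$age) & ped$age >= 40 & !ped$proband
    ecc <- ecc + sum(fit$posteriors[[f]][keep, st$carrier])
  }
  expect_equal(fit$expected_carrier_count, ecc, tolerance = 1e-9)
  known <- sum(vapply(sim$peds, function(p) {
    sum(!p$proband & !is.na(p$sorl1) & p$sorl1 == 1 &
          !is.na(p$status) & !is.na(p$age) & p$age >= 40)
  }, numeric(1)))
  expect_gte(fit$expected_carrier_count, known - 1e-9)
  expect_lte(fit$expected_carrier_count, fit$n_contributing)
})

test_that("BIC selection returns the single candidate and penalizes J", {
  set.seed(64)
  sc <- sim_scenario("full_data", n_families = 25)
  sim <- simulate_families(sc)
  one <- select_cutoffs_bic(sim$peds, sc$baseline, list(c(65)))
  expect_equal(one$cutoffs, c(65))
  sel <- select_cutoffs_bic(sim$peds, sc$baseline,
                            list(numeric(0), c(65), c(60, 65, 70)))
  expect_equal(nrow(sel$table), 3)
  expect_equal(sel$table$J, c(1, 2, 4))
  expect_equal(min(sel$table$bic, na.rm = TRUE),
               sel$table$bic[sel$table$candidate ==
                               paste(sel$cutoffs, collapse = ",")])
})

test_that("BIC recovers a true change point in simulation", {
  set.seed(65)
  # truth: a single step at 65 (strong contrast), full data for speed
  sc <- sim_scenario("full_data", n_families = 60,
                     true_beta = beta_function(c(65), c(5.5, 2.5)))
  hits <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    sim <- simulate_families(sc)
    sel <- select_cutoffs_bic(
      sim$peds, sc$baseline,
      candidates = list(numeric(0), c(55), c(65), c(75))
    )
    if (65 %in% sel$cutoffs) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("penetrance tables are monotone and null effects collapse classes", {
  set.seed(66)
  sc <- sim_scenario("full_data", n_families = 20)
  sim <- simulate_families(sc)
  fit <- fit_penetrance(sim$peds, sc$baseline, c(60, 65, 70))
  tab <- penetrance_table(fit, c(65, 70, 75, 80, 85))
  expect_equal(names(tab)[1], "age")
  for (k in 2:7) expect_true(all(diff(tab[[k]]) >= 0))
  # carrier curves dominate their stratum's non-carrier curve
  cls <- effect_classes()
  for (d in 0:2) {
    expect_true(all(tab[[cls$label[2 * d + 2]]] >= tab[[cls$label[2 * d + 1]]]))
  }
  # beta == 0 makes carrier columns equal the baseline penetrance
  null_fit <- fit
  null_fit$model <- hazard_model(sc$baseline,
                                 beta_function(c(60, 65, 70), rep(0, 4)))
  tab0 <- penetrance_table(null_fit, c(65, 75, 85))
  for (d in 0:2) {
    expect_equal(tab0[[cls$label[2 * d + 2]]], tab0[[cls$label[2 * d + 1]]])
  }
})
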
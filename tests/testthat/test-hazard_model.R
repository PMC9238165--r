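test_that("cumulative hazard reproduces closed-form rectangles", {
  # single stratum value of interest: constant 0.1/yr on [0, 10), beta = 0
  bl <- baseline_hazard(c(0, 10), matrix(0.1, 1, 3))
  m <- hazard_model(bl, beta_function(numeric(0), 0))
  expect_equal(cum_hazard(m, 10, 0, FALSE), 1.0)
  expect_equal(cum_hazard(m, 10, 0, TRUE), 1.0)
  expect_equal(surv_prob(m, 10, 1, TRUE), exp(-1))
  expect_equal(penetrance(m, 10, 1, TRUE), 1 - exp(-1))
  # zero baseline: no risk anywhere
  m0 <- hazard_model(baseline_hazard(c(40, 85), matrix(0, 1, 3)),
                     beta_function(c(60), c(2, 3)))
  for (t in c(40, 57.3, 85)) {
    expect_equal(cum_hazard(m0, t, 2, TRUE), 0)
  }
  expect_error(cum_hazard(m, 11, 0, FALSE), "outside the model support")
})

test_that("cumulative hazard matches an independent split-grid quadrature", {
  set.seed(41)
  for (r in 1:20) {
    breaks <- sort(c(40, runif(sample(2:6, 1), 41, 84), 85))
    bl <- baseline_hazard(breaks,
                          matrix(rexp((length(breaks) - 1) * 3, 20),
                                 length(breaks) - 1, 3))
    nc <- sample(0:3, 1)
    cuts <- sort(runif(nc, 45, 80))
    beta <- beta_function(cuts, rnorm(nc + 1, 1, 1.5))
    m <- hazard_model(bl, beta)
    t <- runif(1, 41, 85)
    for (d in 0:2) {
      for (ca in c(FALSE, TRUE)) {
        oracle <- step_integral(40, t, c(breaks, cuts),
                                raw_hazard_fun(bl, beta, d, ca))
        expect_equal(cum_hazard(m, t, d, ca), oracle, tolerance = 1e-8)
      }
    }
  }
})

test_that("penetrance is monotone and carriers dominate under beta >= 0", {
  set.seed(42)
  bl <- synthetic_baseline()
  m <- hazard_model(bl, beta_function(c(60, 65, 70), c(3.5, 6.7, 4.7, 3.7)))
  ages <- seq(40, 85, by = 0.5)
  for (d in 0:2) {
    Fc <- penetrance(m, ages, d, TRUE)
    Fn <- penetrance(m, ages, d, FALSE)
    expect_true(all(diff(Fc) >= 0))
    expect_true(all(diff(Fn) >= 0))
    expect_true(all(Fc >= Fn))
    expect_true(all(Fc >= 0 & Fc <= 1))
    expect_true(all(surv_prob(m, ages, d, TRUE) > 0))
  }
  # with a null effect carrier and non-carrier curves coincide per stratum
  m0 <- hazard_model(bl, beta_function(c(60), c(0, 0)))
  expect_equal(penetrance(m0, ages, 1, TRUE), penetrance(m0, ages, 1, FALSE))
  # additivity over adjacent intervals
  expect_equal(cum_hazard(m, 70, 1, TRUE),
               cum_hazard(m, 62, 1, TRUE) +
                 (cum_hazard(m, 70, 1, TRUE) - cum_hazard(m, 62, 1, TRUE)))
})

test_that("evidence is survival for censored and survival x hazard for onset", {
  bl <- synthetic_baseline()
  m <- hazard_model(bl, beta_function(c(60), c(2, 3)))
  # censored with no accrued risk
  m0 <- hazard_model(baseline_hazard(c(40, 85), matrix(0, 1, 3)),
                     beta_function(numeric(0), 1))
  expect_equal(evidence_value(m0, 70, 0, 0, TRUE), 1)
  # affected: density identity S * lambda
  t <- 67.2
  expect_equal(
    evidence_value(m, t, 1, 1, TRUE),
    surv_prob(m, t, 1, TRUE) * hazard_at(m, t, 1, TRUE)
  )
  ce <- class_evidence(m, t, 1)
  cls <- effect_classes()
  expect_length(ce, 6)
  expect_equal(ce[4], evidence_value(m, t, 1, cls$e4_dose[4], cls$carrier[4]))
})

test_that("baseline_from_incidence inverts penetrance exactly at grid ages", {
  # closed form: F = 0.5 at 10 years from 0 gives lambda = ln 2 / 10
  tab <- data.frame(stratum = rep(0:2, each = 1), age_start = 0, age_end = 10,
                    cumulative_incidence = 0.5)
  bl <- baseline_from_incidence(tab)
  expect_equal(unname(bl$hazard[1, ]), rep(log(2) / 10, 3))
  # round-trip on a random nondecreasing table
  set.seed(43)
  grid <- seq(40, 85, by = 5)
  f_by_stratum <- lapply(1:3, function(d) {
    cummax(sort(runif(length(grid) - 1, 0, 0.6)))
  })
  tab <- do.call(rbind, lapply(0:2, function(d) {
    data.frame(stratum = d, age_start = grid[-length(grid)],
               age_end = grid[-1],
               cumulative_incidence = f_by_stratum[[d + 1]])
  }))
  bl <- baseline_from_incidence(tab)
  m <- hazard_model(bl, beta_function(numeric(0), 0))
  for (d in 0:2) {
    expect_equal(penetrance(m, grid[-1], d, FALSE), f_by_stratum[[d + 1]],
                 tolerance = 1e-12)
  }
  # a constant-hazard truth is recovered exactly on any grid
  lam <- 0.02
  f_true <- 1 - exp(-lam * (grid[-1] - 40))
  tab2 <- do.call(rbind, lapply(0:2, function(d) {
    data.frame(stratum = d, age_start = grid[-length(grid)],
               age_end = grid[-1], cumulative_incidence = f_true)
  }))
  expect_equal(unname(baseline_from_incidence(tab2)$hazard[, 1]),
               rep(lam, length(grid) - 1), tolerance = 1e-12)
  bad <- tab
  bad$cumulative_incidence[3] <- 0.99
  expect_error(baseline_from_incidence(bad), "nondecreasing")
})

test_that("read_baseline accepts both hazard and incidence encodings", {
  path <- system.file("extdata", "baseline_synthetic.csv", package = "pedpen")
  bl <- read_baseline(path)
  expect_s3_class(bl, "baseline_hazard")
  expect_equal(bl$support, c(40, 85))
  expect_equal(unname(bl$hazard), unname(synthetic_baseline()$hazard),
               tolerance = 1e-12)
  # incidence encoding round-trips through the file format
  m <- hazard_model(bl, beta_function(numeric(0), 0))
  grid <- bl$breaks
  tab <- do.call(rbind, lapply(0:2, function(d) {
    data.frame(stratum = d, age_start = grid[-length(grid)],
               age_end = grid[-1],
               cumulative_incidence = penetrance(m, grid[-1], d, FALSE))
  }))
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE)
  bl2 <- read_baseline(tmp)
  expect_equal(unname(bl2$hazard), unname(bl$hazard), tolerance = 1e-10)
})
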
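test_that("generation is deterministic and seed-sensitive", {
  cfg <- sim_config(n_locations = 3, seed = 5)
  expect_identical(generate_mortality(cfg), generate_mortality(cfg))
  expect_identical(generate_sdi_haq(cfg), generate_sdi_haq(cfg))
  cfg2 <- sim_config(n_locations = 3, seed = 6)
  expect_false(identical(generate_sdi_haq(cfg)$sdi, generate_sdi_haq(cfg2)$sdi))
})

test_that("the all-cause hazard follows the stated closed form", {
  cfg <- sim_config(n_locations = 2, years = 1990, sex_multiplier = c(`1` = 1, `2` = 1))
  cov <- generate_sdi_haq(cfg)
  mort <- generate_mortality(cfg, cov)
  for (loc in 1:2) {
    sdi <- cov[location_id == loc, sdi]
    got <- mort[location_id == loc & sex == 1,
                .(all_cause = sum(value)), by = age_group_start]
    want <- cfg$gompertz_alpha * exp(cfg$gompertz_beta * got$age_group_start) *
      sdi_multiplier(sdi, cfg$sdi_link_lambda)
    expect_equal(got$all_cause, want, tolerance = 1e-12)
  }
  # closed-form spot value: alpha = 0.005, beta = 0.09 at age 70
  cfg1 <- sim_config(n_locations = 1, years = 1990, gompertz_alpha = 0.005,
                     gompertz_beta = 0.09, sdi_link_lambda = 0,
                     sex_multiplier = c(`1` = 1, `2` = 1))
  m1 <- generate_mortality(cfg1)
  expect_equal(m1[sex == 1 & age_group_start == 70, sum(value)],
               0.005 * exp(6.3), tolerance = 1e-12)
})

test_that("degenerate parameters behave as specified", {
  # zero slope: flat mortality across age
  cfg <- sim_config(n_locations = 1, years = 1990, gompertz_beta = 0)
  m <- generate_mortality(cfg)
  rates <- m[sex == 1, .(v = sum(value)), by = age_group_start]$v
  expect_equal(rates, rep(rates[1], length(rates)))

  # concentration on one cause puts the whole rate on it
  cfg2 <- sim_config(n_locations = 1, years = 1990,
                     cause_dirichlet = c(1e9, 1e-9, 1e-9, 1e-9))
  m2 <- generate_mortality(cfg2)
  frac <- m2[sex == 1 & age_group_start == 70, value / sum(value)]
  expect_equal(frac[1], 1, tolerance = 1e-6)

  expect_error(sim_config(gompertz_alpha = 0), "gompertz_alpha")
  expect_error(sim_config(gompertz_beta = -1), "gompertz_beta")
})

test_that("cause closure and monotone ageing hold in every stratum", {
  cfg <- sim_config(n_locations = 4, seed = 9)
  m <- generate_mortality(cfg)
  strata <- m[, .(all_cause = sum(value)), by = .(location_id, year, sex, age_group_start)]
  # strictly increasing in age within every stratum (beta > 0)
  inc <- strata[order(age_group_start),
                all(diff(all_cause) > 0), by = .(location_id, year, sex)]
  expect_true(all(inc$V1))
  expect_true(all(strata$all_cause > 0))
})

test_that("yld generation follows the linear prevalence model", {
  cfg <- sim_config(
    n_locations = 1, years = 1990, causes = "c1",
    cause_dirichlet = 1, cause_trend = 0,
    disability_params = data.frame(cause = "c1", intercept = 0.1,
                                   slope = 0.004, dw = 0.2))
  m <- generate_mortality(cfg)
  y <- generate_ylds(cfg, m)
  prev75 <- y[measure == "prevalence" & sex == 1 & age_group_start == 75, value]
  expect_equal(prev75, 0.1 + 0.004 * 75)  # 0.4
  expect_equal(y[measure == "yld_rate" & sex == 1 & age_group_start == 75, value],
               prev75 * 0.2)  # 0.08
  # zero prevalence gives zero yld everywhere
  cfg0 <- sim_config(
    n_locations = 1, years = 1990, causes = "c1", cause_dirichlet = 1,
    cause_trend = 0,
    disability_params = data.frame(cause = "c1", intercept = 0, slope = 0, dw = 0.3))
  y0 <- generate_ylds(cfg0, generate_mortality(cfg0))
  expect_true(all(y0[measure == "yld_rate", value] == 0))
  expect_error(sim_config(disability_params = data.frame(
    cause = "c1", intercept = 0, slope = 0, dw = 1.2)), "\\[0, 1\\]")
})

test_that("SDI and HAQ stay in range and the link is invertible", {
  cfg <- sim_config(n_locations = 50, seed = 2)
  cov <- generate_sdi_haq(cfg)
  expect_true(all(cov$sdi >= 0 & cov$sdi <= 1))
  expect_true(all(cov$haq >= 0 & cov$haq <= 100))
  mult <- sdi_multiplier(cov$sdi, cfg$sdi_link_lambda)
  expect_equal(sdi_from_multiplier(mult, cfg$sdi_link_lambda), cov$sdi,
               tolerance = 1e-12)
})

test_that("coverage generation matches an independent RNG replay", {
  cfg <- sim_config(n_locations = 10, seed = 4)
  cov <- generate_coverage(cfg, sparsity = 0.5)
  set.seed(child_seed(cfg$seed, "coverage"))
  replay <- as.integer(runif(nrow(cov)) >= 0.5)
  expect_equal(cov$has_data, replay)

  expect_true(all(generate_coverage(cfg, sparsity = 0)$has_data == 1))
  expect_true(all(generate_coverage(cfg, sparsity = 1)$has_data == 0))
})
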
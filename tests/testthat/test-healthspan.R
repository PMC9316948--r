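ages <- seq(0, 95, by = 5)

test_that("comorbidity adjustment matches exhaustive enumeration", {
  # frozen two-condition worked case: 1 - 0.8*0.7 = 0.44 split 0.176/0.264
  adj <- comorbidity_adjust(c(1, 1), c(0.2, 0.3))
  expect_equal(attr(adj, "combined"), 0.44)
  expect_equal(as.numeric(adj), c(0.176, 0.264))

  # single condition passes through unchanged
  expect_equal(as.numeric(comorbidity_adjust(0.4, 0.25)), 0.1)

  # random configurations against the independent enumeration oracle
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    p <- runif(k); dw <- runif(k)
    adj <- comorbidity_adjust(p, dw)
    oracle <- enumerate_comorbidity(p, dw)
    expect_equal(as.numeric(adj), oracle$attrib, tolerance = 1e-12)
    expect_equal(attr(adj, "combined"), oracle$combined, tolerance = 1e-12)
    # attribution is exhaustive: shares sum to the combined disability
    expect_equal(sum(adj), attr(adj, "combined"), tolerance = 1e-12)
  }
})

test_that("a zero-weight condition is inert", {
  base <- comorbidity_adjust(c(0.3, 0.5), c(0.2, 0.4))
  with_null <- comorbidity_adjust(c(0.3, 0.5, 0.9), c(0.2, 0.4, 0))
  expect_equal(as.numeric(with_null)[1:2], as.numeric(base), tolerance = 1e-12)
  expect_equal(as.numeric(with_null)[3], 0)
})

test_that("microsim mode agrees with analytic mode within 3 SE", {
  set.seed(5)
  p <- runif(4, 0.1, 0.6); dw <- runif(4, 0.05, 0.5)
  exact <- comorbidity_adjust(p, dw)
  sim <- comorbidity_adjust(p, dw, mode = "microsim", n_sim = 1e5, seed = 8)
  expect_true(all(abs(sim - exact) <= 3 * attr(sim, "se")))
  expect_lt(abs(attr(sim, "combined") - attr(exact, "combined")),
            3 * attr(sim, "combined_se"))
})

test_that("analytic enumeration refuses oversized condition lists", {
  expect_error(comorbidity_adjust(rep(0.1, 21), rep(0.1, 21)), "microsim")
})

test_that("yll is the deaths-times-standard-expectancy product", {
  deaths <- matrix(c(0, 10, 3, 7), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  std <- c(14.6, 10)
  y <- yll(deaths, std)
  expect_equal(unname(y[2, "a"]), 100)
  expect_equal(unname(y[1, "b"]), 3 * 14.6)
  expect_equal(yll(deaths * 0, std), deaths * 0)
  # additivity over causes
  expect_equal(rowSums(y), as.numeric(rowSums(deaths) * std), tolerance = 1e-9)
  expect_error(yll(deaths, c(1, 2, 3)), "different age grids")
  expect_error(yll(-deaths, std), "non-negative")
})

test_that("Sullivan HALE limits and constant-rate factorisation", {
  g <- random_gompertz(2)
  lt <- build_lifetable(g$ages, g$mx)
  le70 <- life_expectancy_at(lt, 70)

  h0 <- hale_sullivan(lt, rep(0, length(ages)))
  expect_equal(unname(h0[as.character(ages)]), lt$ex)

  d <- 0.25
  hd <- hale_sullivan(lt, rep(d, length(ages)))
  expect_equal(unname(hd["70"]), (1 - d) * le70, tolerance = 1e-12)

  h1 <- hale_sullivan(lt, rep(1, length(ages)))
  expect_equal(unname(h1["70"]), 0)

  # monotone harm: raising any single age's rate never raises HALE-70
  base_rate <- rep(0.1, length(ages))
  h_base <- hale_sullivan(lt, base_rate)["70"]
  for (i in c(1, 15, 20)) {
    worse <- replace(base_rate, i, 0.3)
    expect_lte(hale_sullivan(lt, worse)["70"], h_base)
  }
  expect_error(hale_sullivan(lt, rep(1.5, length(ages))), "\\[0, 1\\]")
})

test_that("pyih is the exact ill-health fraction with guarded domain", {
  expect_equal(pyih(10, 10), 0)
  expect_equal(pyih(12, 9), 0.25)
  expect_error(pyih(0, 0), "positive")
  expect_error(pyih(10, 11), "\\[0, le70\\]")
})

test_that("daly is a cellwise sum with aligned grids", {
  set.seed(4)
  a <- matrix(rexp(12), 3); b <- matrix(rexp(12), 3)
  expect_equal(daly(a, b), a + b)
  expect_equal(daly(a * 0, b), b)
  expect_error(daly(a, b[1:2, ]), "different grids")
  expect_error(daly(-a, b), "non-negative")
})
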
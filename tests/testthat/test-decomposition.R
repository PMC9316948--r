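ages <- seq(0, 95, by = 5)

random_surface <- function(seed, k = 4, scale = 1) {
  set.seed(seed)
  base <- random_gompertz(seed)$mx * scale
  frac <- matrix(rexp(length(ages) * k), length(ages), k)
  frac <- frac / rowSums(frac)
  mortality_surface(ages, base * frac)
}

test_that("identical surfaces decompose to zero everywhere", {
  s <- random_surface(1)
  d <- decompose_20q70(s, s)
  expect_equal(unname(d$contributions), rep(0, 4))
  expect_equal(d$total_change, 0)
  expect_equal(d$residual, 0)
})

test_that("contributions sum to the total change with zero residual", {
  for (seed in c(2, 5, 9)) {
    s1 <- random_surface(seed)
    s2 <- random_surface(seed + 100, scale = 0.8)
    d <- decompose_20q70(s1, s2)
    expect_lt(abs(d$residual), 1e-10)
    expect_equal(sum(d$contributions), d$total_change, tolerance = 1e-10)
  }
})

test_that("single-cause world attributes the whole change to that cause", {
  m1 <- matrix(random_gompertz(3)$mx, ncol = 1,
               dimnames = list(NULL, "only"))
  m2 <- m1 * 0.7
  d <- decompose_20q70(mortality_surface(ages, m1), mortality_surface(ages, m2))
  expect_equal(unname(d$contributions["only"]), d$total_change)
})

test_that("two-cause case matches hand enumeration of both orderings", {
  s1 <- random_surface(4, k = 2)
  s2 <- random_surface(44, k = 2, scale = 0.75)
  q <- function(m) {
    lt <- build_lifetable(ages, rowSums(m))
    prob_death_window(lt, 70, 20)
  }
  m1 <- s1$mx; m2 <- s2$mx
  # ordering A: switch cause 1 first, then cause 2
  mA <- m1; mA[, 1] <- m2[, 1]
  c1_A <- q(mA) - q(m1); c2_A <- q(m2) - q(mA)
  # ordering B: cause 2 first
  mB <- m1; mB[, 2] <- m2[, 2]
  c2_B <- q(mB) - q(m1); c1_B <- q(m2) - q(mB)
  expected <- c((c1_A + c1_B) / 2, (c2_A + c2_B) / 2)

  d <- decompose_20q70(s1, s2)
  expect_equal(unname(d$contributions), expected, tolerance = 1e-14)
})

test_that("decomposition is antisymmetric and inert for unchanged causes", {
  s1 <- random_surface(6)
  s2 <- random_surface(66, scale = 0.85)
  d12 <- decompose_20q70(s1, s2)
  d21 <- decompose_20q70(s2, s1)
  expect_equal(d12$contributions, -d21$contributions, tolerance = 1e-12)

  # a cause with identical rates at both times contributes nothing
  m2_same <- s2$mx; m2_same[, 2] <- s1$mx[, 2]
  d <- decompose_20q70(s1, mortality_surface(ages, m2_same))
  expect_equal(unname(d$contributions[2]), 0, tolerance = 1e-12)
})

test_that("sampled orderings keep the residual small for many causes", {
  s1 <- random_surface(7, k = 8)
  s2 <- random_surface(77, k = 8, scale = 0.8)
  d <- decompose_20q70(s1, s2, n_orderings = 500, seed = 3)
  expect_lt(abs(d$residual), 1e-3 * abs(d$total_change))
})

test_that("direction_split reconstructs the total and is antisymmetric", {
  s1 <- random_surface(8)
  s2 <- random_surface(88, scale = 0.9)
  d <- decompose_20q70(s1, s2)
  sp <- direction_split(d)
  expect_equal(sp[["negative"]] + sp[["positive"]] + d$residual,
               d$total_change, tolerance = 1e-10)
  expect_equal(sp[["negative"]],
               sum(d$contributions[d$contributions < 0]))
  sp_rev <- direction_split(decompose_20q70(s2, s1))
  expect_equal(sp_rev[["negative"]], -sp[["positive"]], tolerance = 1e-12)
  expect_equal(sp_rev[["positive"]], -sp[["negative"]], tolerance = 1e-12)
})

test_that("mismatched inputs are rejected", {
  s1 <- random_surface(10)
  s2 <- random_surface(10, k = 3)
  expect_error(decompose_20q70(s1, s2), "mismatched cause lists")
  expect_error(mortality_surface(ages, matrix(-1, length(ages), 2)),
               "non-negative")
})
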
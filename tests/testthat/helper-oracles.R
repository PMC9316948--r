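# Independent oracles used across the suite. These never call the
# life-table or comorbidity code paths they are checking.

# Cohort microsimulation with piecewise-constant hazards: simulates
# individual residual lifetimes from `from_age` onward and returns them.
# `age_start`/`mx` describe the full abridged schedule; only intervals at
# or above `from_age` matter.
microsim_residual_life <- function(age_start, mx, from_age, n_agents,
                                   seed = 1L) {
  set.seed(seed)
  keep <- age_start >= from_age
  starts <- age_start[keep]
  haz <- mx[keep]
  widths <- c(diff(starts), Inf)
  t_death <- rep(NA_real_, n_agents)
  alive <- rep(TRUE, n_agents)
  t0 <- 0
  for (i in seq_along(haz)) {
    idx <- which(alive)
    if (!length(idx)) break
    e <- rexp(length(idx), rate = haz[i])
    died <- e < widths[i]
    t_death[idx[died]] <- t0 + e[died]
    alive[idx[died]] <- FALSE
    t0 <- t0 + widths[i]
  }
  t_death
}

# Exhaustive-enumeration oracle for expected comorbid disability and
# its per-condition attribution (proportional-to-weight rule), written
# directly from the joint Bernoulli distribution.
enumerate_comorbidity <- function(p, dw) {
  k <- length(p)
  combined <- 0
  attrib <- numeric(k)
  for (states in asplit(as.matrix(expand.grid(rep(list(0:1), k))), 1)) {
    states <- as.logical(states)
    pr <- prod(ifelse(states, p, 1 - p))
    if (!any(states) || pr == 0) next
    d <- 1 - prod(1 - dw[states])
    combined <- combined + pr * d
    tot <- sum(dw[states])
    if (tot > 0) attrib[states] <- attrib[states] + pr * d * dw[states] / tot
  }
  list(combined = combined, attrib = attrib)
}

# Random Gompertz schedule on the default abridged grid.
random_gompertz <- function(seed) {
  set.seed(seed)
  alpha <- runif(1, 1e-5, 1e-4)
  beta <- runif(1, 0.07, 0.11)
  ages <- seq(0, 95, by = 5)
  list(ages = ages, mx = alpha * exp(beta * ages),
       alpha = alpha, beta = beta)
}
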
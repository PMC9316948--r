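toy_coverage <- function(cells) {
  # cells: data.frame(country, entity, period, age_flag, has_data)
  cells$entity_type <- "cause"
  coverage_matrix(cells)
}

full_grid <- function(countries, entities, periods = "p1",
                      flags = c("all_ages", "aged_70_plus"), value = 1) {
  g <- expand.grid(country = countries, entity = entities, period = periods,
                   age_flag = flags, stringsAsFactors = FALSE)
  g$has_data <- value
  g
}

test_that("all-ones and all-zeros slices give 100% and 0%", {
  m1 <- toy_coverage(full_grid(paste0("c", 1:5), c("x", "y"), value = 1))
  expect_equal(unname(dci_by_cause(m1, "p1", "all_ages")), c(100, 100))
  expect_equal(unname(dci_by_country(m1, "p1", "all_ages")), rep(100, 5))

  m0 <- toy_coverage(full_grid(paste0("c", 1:5), c("x", "y"), value = 0))
  expect_equal(unname(dci_by_cause(m0, "p1", "all_ages")), c(0, 0))
  expect_equal(unname(dci_by_country(m0, "p1", "all_ages")), rep(0, 5))
})

test_that("hand-counted proportions on a toy matrix", {
  g <- full_grid(paste0("c", 1:10), c("x", "y"), value = 0)
  # 3 of 10 countries have data for cause x (all ages)
  g$has_data[g$entity == "x" & g$age_flag == "all_ages" &
               g$country %in% c("c1", "c4", "c9")] <- 1
  m <- toy_coverage(g)
  expect_equal(unname(dci_by_cause(m, "p1", "all_ages")), c(30, 0))
  # country c1: 1 of 2 causes present
  expect_equal(dci_by_country(m, "p1", "all_ages")[["c1"]], 50)
})

test_that("transposition duality: swapping axes swaps the two variants", {
  set.seed(21)
  g <- full_grid(paste0("c", 1:6), paste0("e", 1:4), value = 0)
  g$has_data <- rbinom(nrow(g), 1, 0.4)
  m <- toy_coverage(g)
  g_t <- g
  names(g_t)[names(g_t) == "country"] <- "tmp"
  names(g_t)[names(g_t) == "entity"] <- "country"
  names(g_t)[names(g_t) == "tmp"] <- "entity"
  m_t <- toy_coverage(g_t)
  expect_equal(dci_by_cause(m, "p1", "all_ages"),
               dci_by_country(m_t, "p1", "all_ages"))
})

test_that("adding a data source never decreases any DCI", {
  set.seed(22)
  g <- full_grid(paste0("c", 1:8), paste0("e", 1:5), value = 0)
  g$has_data <- rbinom(nrow(g), 1, 0.3)
  m <- toy_coverage(g)
  before_cause <- dci_by_cause(m, "p1", "all_ages")
  zero_rows <- which(g$has_data == 0 & g$age_flag == "all_ages")
  g2 <- g; g2$has_data[sample(zero_rows, 1)] <- 1
  after_cause <- dci_by_cause(toy_coverage(g2), "p1", "all_ages")
  expect_true(all(after_cause >= before_cause))
  expect_true(all(after_cause >= 0 & after_cause <= 100))
})

test_that("dci_gap compares all-ages with aged-70-plus coverage", {
  g <- full_grid(paste0("c", 1:4), c("x", "y"), value = 1)
  m <- toy_coverage(g)
  expect_equal(unname(dci_gap(m, "p1")), c(0, 0))

  g2 <- g; g2$has_data[g2$age_flag == "aged_70_plus"] <- 0
  expect_equal(unname(dci_gap(toy_coverage(g2), "p1")), c(100, 100))
  expect_equal(unname(dci_gap(toy_coverage(g2), "p1", by = "country")),
               rep(100, 4))

  # a cell present only for the 70+ slice yields a negative gap
  g3 <- full_grid(paste0("c", 1:4), c("x", "y"), value = 0)
  g3$has_data[g3$age_flag == "aged_70_plus" & g3$entity == "x" &
                g3$country == "c2"] <- 1
  gap <- dci_gap(toy_coverage(g3), "p1")
  expect_lt(gap[["x"]], 0)
  expect_equal(gap[["y"]], 0)
})

test_that("invalid slices and cells are rejected", {
  g <- full_grid("c1", "x", flags = "all_ages")
  m <- toy_coverage(g)
  expect_error(dci_by_cause(m, "p2", "all_ages"), "no coverage cells")
  expect_error(dci_gap(m, "p1"), "aged_70_plus")
  g$has_data <- 2
  expect_error(toy_coverage(g), "0 or 1")
})
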
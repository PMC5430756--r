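mk_broods <- function(m, f, wol = "negative", species = "sp") {
  data.frame(species = species,
             brood_id = paste0("b", seq_along(m)),
             n_male = m, n_female = f, mother_wolbachia = wol)
}

test_that("filtering applies Wolbachia then balanced-ratio rules in order", {
  r <- filter_broods(mk_broods(10, 10))
  expect_equal(nrow(r$kept), 0)
  expect_equal(r$discarded$reason, "balanced_sex_ratio")

  # Wolbachia precedence: a balanced, infected brood is a Wolbachia discard
  r <- filter_broods(mk_broods(0, 30, wol = "positive"))
  expect_equal(r$discarded$reason, "wolbachia")
  r <- filter_broods(mk_broods(15, 15, wol = "positive"))
  expect_equal(r$discarded$reason, "wolbachia")

  r <- filter_broods(mk_broods(5, 35))   # chi-square 22.5, p < 1e-5
  expect_equal(nrow(r$kept), 1)
  expect_equal(nrow(r$discarded), 0)
})

test_that("filtering partitions its input and is idempotent on the kept set", {
  broods <- mk_broods(c(10, 5, 0, 12, 3), c(10, 35, 30, 40, 29),
                      wol = c("negative", "negative", "positive",
                              "negative", "negative"))
  r <- filter_broods(broods)
  expect_equal(nrow(r$kept) + nrow(r$discarded), nrow(broods))
  expect_length(intersect(r$kept$brood_id, r$discarded$brood_id), 0)
  expect_setequal(c(r$kept$brood_id, r$discarded$brood_id), broods$brood_id)
  r2 <- filter_broods(r$kept)
  expect_equal(nrow(r2$discarded), 0)
  expect_equal(r2$kept$brood_id, r$kept$brood_id)
})

test_that("untested Wolbachia status warns and follows the configured policy", {
  broods <- mk_broods(5, 35, wol = "untested")
  expect_warning(r <- filter_broods(broods), "untested")
  expect_equal(nrow(r$kept), 1)
  expect_warning(r <- filter_broods(broods, untested = "discard"), "untested")
  expect_equal(r$discarded$reason, "wolbachia")
})

test_that("species classification follows the chi-square decision tree", {
  # 25M:75F at n = 100: ZW but cannot yet reject the 1/3 expectation
  cl <- classify_species(mk_broods(25, 75))
  expect_equal(cl$system, "ZW")
  expect_equal(cl$ww_viability, "indeterminate")
  expect_equal(cl$p_onequarter, 1)
  expect_equal(cl$p_onethird, pchisq(3.125, 1, lower.tail = FALSE))

  # all-female at n = 60: zero-male test passes, both ZW nulls rejected
  cl <- classify_species(mk_broods(0, 60))
  expect_equal(cl$system, "XY")
  expect_equal(cl$ww_viability, "not_applicable")
  expect_equal(cl$p_zero_male, 1)

  # all-male: the unexplained pattern
  cl <- classify_species(mk_broods(30, 0))
  expect_equal(cl$system, "UNDETERMINED")
  expect_true("male_excess" %in% cl$flags)

  # large 3:1 progeny: ZW with viable WW
  cl <- classify_species(mk_broods(72, 228))
  expect_equal(cl$system, "ZW")
  expect_equal(cl$ww_viability, "viable")

  # large 1:2 progeny: ZW with inviable WW
  cl <- classify_species(mk_broods(100, 200))
  expect_equal(cl$system, "ZW")
  expect_equal(cl$ww_viability, "inviable")

  # one small all-female brood: XY candidate with a low-power flag
  cl <- classify_species(mk_broods(0, 8))
  expect_equal(cl$system, "XY")
  expect_true("low_power" %in% cl$flags)
})

test_that("significant heterogeneity blocks pooling", {
  cl <- classify_species(mk_broods(c(40, 2), c(10, 48)))
  expect_equal(cl$system, "UNDETERMINED")
  expect_true("heterogeneous" %in% cl$flags)
  expect_true(cl$heterogeneity_p < 0.05)
})

test_that("all-male multi-brood species tolerate the degenerate heterogeneity table", {
  cl <- classify_species(mk_broods(c(25, 30, 28), c(0, 0, 0)))
  expect_equal(cl$system, "UNDETERMINED")
  expect_true("degenerate_heterogeneity_table" %in% cl$flags)
  expect_true("male_excess" %in% cl$flags)
})

test_that("empty brood input signals no-data", {
  empty <- data.frame(species = character(0), brood_id = character(0),
                      n_male = integer(0), n_female = integer(0),
                      mother_wolbachia = character(0))
  expect_error(classify_species(empty), "no-data")
})

test_that("power of the viability test matches exact binomial enumeration", {
  # exact power: sum Binomial(30, 0.25) over the chi-square rejection
  # region of the 1/3 null
  k <- 0:30
  stat <- (k - 10)^2 / 10 + ((30 - k) - 20)^2 / 20
  exact <- sum(dbinom(k[pchisq(stat, 1, lower.tail = FALSE) < 0.05], 30, 0.25))
  est <- viability_power(30, 0.25, 1 / 3, n_sim = 20000, seed = 11)
  expect_lt(abs(est - exact), 0.02)
  expect_lt(est, 0.30)

  expect_gt(viability_power(10000, 0.25, 1 / 3, n_sim = 500, seed = 2), 0.99)

  # size: true = null gives rejection near the level
  sz <- viability_power(500, 1 / 3, 1 / 3, n_sim = 10000, seed = 3)
  expect_gt(sz, 0.02); expect_lt(sz, 0.08)
})

test_that("power increases with brood size", {
  pw <- vapply(c(30, 100, 300, 1000), function(n)
    viability_power(n, 0.25, 1 / 3, n_sim = 4000, seed = 5), numeric(1))
  expect_true(all(diff(pw) > -0.02))   # non-decreasing within MC noise
  expect_gt(pw[4], pw[1])
})

test_that("power estimates are reproducible given a seed", {
  expect_identical(viability_power(50, 0.3, 0.5, n_sim = 1000, seed = 9),
                   viability_power(50, 0.3, 0.5, n_sim = 1000, seed = 9))
})
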
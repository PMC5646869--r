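test_that("beta_value reduces fractions exactly", {
  expect_equal(unclass(beta_value(2L, 4L)), c(num = 1L, den = 2L))
  expect_equal(unclass(beta_value(0L, 7L)), c(num = 0L, den = 1L))
  expect_equal(unclass(beta_value(3L, 3L)), c(num = 1L, den = 1L))
  expect_equal(as.numeric(beta_value(3L, 5L)), 0.6)
  expect_error(beta_value(5L, 4L), "0 <= M <= T")
  expect_error(beta_value(1L, 0L), "positive")
})

test_that("observed_distribution counts and merges equal fractions", {
  obs <- observed_distribution(toy_sites())
  expect_equal(dist_as_named(obs),
               c("0/1" = 1 / 3, "1/2" = 1 / 3, "1/1" = 1 / 3))
  one <- observed_distribution(methyl_sites("c", 1L, "+", 3L, 5L))
  expect_equal(dist_as_named(one), c("3/5" = 1))
  # 1/2 from depth 2 and 2/4 from depth 4 share one support point
  mrg <- observed_distribution(methyl_sites("c", 1:2, "+", c(1L, 2L),
                                            c(2L, 4L)))
  expect_equal(dist_as_named(mrg), c("1/2" = 1))
  expect_error(observed_distribution(toy_sites()[0, ]), "empty")
})

test_that("mean_methylation implements both estimators", {
  s <- toy_sites()
  expect_equal(mean_methylation(s), 0.5)
  expect_equal(mean_methylation(s, "pooled"), 0.5)
  s2 <- methyl_sites("c", 1:2, "+", c(10L, 0L), c(10L, 2L))
  expect_equal(mean_methylation(s2, "per_site"), 0.5)
  expect_equal(mean_methylation(s2, "pooled"), 10 / 12)
})

test_that("binomial_pmf matches closed forms including degenerate p", {
  expect_equal(binomial_pmf(2L, 1L, 0.5), 0.5)
  expect_equal(binomial_pmf(4L, 2L, 0.5), 0.375)
  expect_equal(binomial_pmf(3L, 0L, 0), 1)
  expect_equal(binomial_pmf(3L, 3L, 1), 1)
  expect_equal(binomial_pmf(3L, 1L, 1), 0)
  expect_error(binomial_pmf(3L, 4L, 0.5), "out of range")
})

test_that("random_distribution is the exact analytic mixture", {
  prof <- depth_profile(c(2L, 2L, 4L))
  ran <- random_distribution(prof, 0.5)
  expect_equal(dist_as_named(ran),
               c("0/1" = 0.1875, "1/4" = 1 / 12, "1/2" = 11 / 24,
                 "3/4" = 1 / 12, "1/1" = 0.1875),
               tolerance = 1e-12)
  # matches the independent exhaustive enumeration oracle
  orc <- oracle_rran(c(2L, 2L, 4L), 0.5)
  got <- dist_as_named(ran)
  expect_equal(got[names(orc)], orc, tolerance = 1e-12)
  # degenerate p
  expect_equal(dist_as_named(random_distribution(depth_profile(rep(2L, 100)), 0)),
               c("0/1" = 1))
  # binomial symmetry at p = 1/2, single depth
  r <- random_distribution(depth_profile(rep(5L, 3L)), 0.5)
  expect_equal(r$mass, rev(r$mass))
})

test_that("random_distribution normalizes and has mean p for random profiles", {
  set.seed(101)
  for (i in 1:40) {
    depths <- sample(1:50, sample(1:12, 1), replace = TRUE)
    counts <- sample(1:30, length(depths), replace = TRUE)
    prof <- depth_profile(data.frame(depth = depths, count = counts))
    for (p in c(0, 0.15, 0.5, 0.85, 1)) {
      r <- random_distribution(prof, p)
      expect_equal(sum(r$mass), 1, tolerance = 1e-12)
      expect_equal(sum(r$beta * r$mass), p, tolerance = 1e-9)
    }
  }
})

test_that("null endpoint mass at single depth is (1-p)^T, decreasing in T", {
  for (p in c(0.2, 0.5, 0.8)) {
    m0 <- vapply(1:50, function(T)
      mass_at(random_distribution(depth_profile(data.frame(depth = T, count = 7L)), p), 0),
      0)
    expect_equal(m0, (1 - p)^(1:50), tolerance = 1e-12)
    expect_true(all(diff(m0) < 0))
  }
})

test_that("restrict_to_depth filters exactly", {
  s <- toy_sites()
  expect_equal(nrow(restrict_to_depth(s, 2L)), 2L)
  expect_equal(nrow(restrict_to_depth(s, 16L)), 0L)
  r4 <- observed_distribution(
    restrict_to_depth(methyl_sites("c", 1:2, "+", c(1L, 3L), c(4L, 4L)), 4L))
  expect_equal(dist_as_named(r4), c("1/4" = 0.5, "3/4" = 0.5))
})

test_that("sample_random_methylome is a deterministic, converging oracle", {
  prof <- depth_profile(rep(2L, 1000))
  a <- sample_random_methylome(prof, 0.5, draws = 1L, seed = 9L)
  b <- sample_random_methylome(prof, 0.5, draws = 1L, seed = 9L)
  expect_identical(a, b)
  want <- c("0/1" = 0.25, "1/2" = 0.5, "1/1" = 0.25)
  got <- dist_as_named(a)[names(want)]
  expect_true(all(abs(got - want) <= 3 * sqrt(want * (1 - want) / 1000)))
  p1 <- sample_random_methylome(prof, 1, draws = 1L, seed = 2L)
  expect_equal(dist_as_named(p1), c("1/1" = 1))
})
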
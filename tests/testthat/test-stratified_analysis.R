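test_that("context stratification partitions sites; tri aggregates tetra", {
  fx <- sim_fixture(seed = 31L)
  tet <- suppressWarnings(analyze_all_contexts(fx$sites, "tetra"))
  tri <- suppressWarnings(analyze_all_contexts(fx$sites, "tri"))
  expect_lte(nrow(tet$rows), 16L)
  expect_lte(nrow(tri$rows), 4L)
  expect_false(anyDuplicated(tet$rows$context) > 0)
  expect_equal(sum(tet$rows$n_sites), nrow(fx$sites))
  expect_equal(sum(tri$rows$n_sites), sum(tet$rows$n_sites))
  # per-trinucleotide counts equal the merged tetra counts
  merged <- tapply(tet$rows$n_sites, substr(tet$rows$context, 1, 3), sum)
  expect_equal(as.vector(merged[tri$rows$context]), tri$rows$n_sites)
  # p was computed within each context class
  one <- tet$rows$context[1]
  sub <- fx$sites[fx$sites$context == one, ]
  expect_equal(tet$rows$p[1], mean_methylation(sub))
})

test_that("single-context input yields a single-row report", {
  s <- methyl_sites("c", c(10L, 20L, 30L), "+", c(0L, 1L, 2L), c(2L, 2L, 2L))
  s$context <- "ACGT"
  rep <- suppressWarnings(analyze_all_contexts(s, "tetra"))
  expect_equal(nrow(rep$rows), 1L)
  expect_equal(rep$rows$context, "ACGT")
  expect_error(analyze_all_contexts(s[0, ], "tetra"), "no annotated sites")
})

test_that("depth stratification restricts correctly", {
  fx <- sim_fixture(seed = 32L, lambda = 5)
  byd <- suppressWarnings(analyze_by_depth(fx$sites, c(4L, 6L), "tri"))
  expect_true(all(byd$rows$depth %in% c(4L, 6L)))
  # a uniform-depth input analyzed at that depth equals the unstratified run
  u <- fx$sites[fx$sites$depth == 6L, ]
  direct <- suppressWarnings(analyze_all_contexts(u, "tri"))
  viadep <- suppressWarnings(analyze_by_depth(u, 6L, "tri"))
  expect_equal(viadep$rows[names(direct$rows)], direct$rows)
  expect_warning(analyze_by_depth(u, c(6L, 999L), "tri"), "no sites at depth")
})

test_that("subset_by_regions uses half-open intervals on the cytosine base", {
  s <- methyl_sites("chr1", c(100L, 55L), c("+", "+"), c(0L, 1L), c(2L, 2L))
  iv <- data.frame(chrom = "chr1", start = 99L, end = 100L)
  expect_equal(subset_by_regions(s, iv, "inside")$position, 100L)
  iv2 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(nrow(subset_by_regions(s[1, ], iv2, "inside")), 0L)
  # overlapping intervals are merged, sites never double-counted
  iv3 <- data.frame(chrom = "chr1", start = c(0L, 40L), end = c(50L, 60L))
  expect_equal(subset_by_regions(s, iv3, "inside")$position, 55L)
  # complement conservation
  ins <- subset_by_regions(s, iv3, "inside")
  outs <- subset_by_regions(s, iv3, "outside")
  expect_equal(nrow(ins) + nrow(outs), nrow(s))
  # different chromosome never matches
  iv4 <- data.frame(chrom = "chr2", start = 0L, end = 1000L)
  expect_equal(nrow(subset_by_regions(s, iv4, "inside")), 0L)
})

test_that("average_methylation_by_context reports per-context Eq-mean levels", {
  s <- methyl_sites("c", 1:4, "+", c(0L, 2L, 1L, 1L), c(2L, 2L, 2L, 2L))
  s$context <- c("ACGT", "ACGT", "GCGA", "GCGA")
  tab <- average_methylation_by_context(s, "tetra")
  expect_equal(tab$mean_beta, c(0.5, 0.5))
  expect_equal(tab$n_sites, c(2L, 2L))
  s1 <- methyl_sites("c", 1L, "+", 3L, 4L)
  s1$context <- "ACGT"
  expect_equal(average_methylation_by_context(s1, "tetra")$mean_beta, 0.75)
})

test_that("context truth means are recovered from simulation", {
  fx <- sim_fixture(seed = 35L, length = 400000L, cpg_rate = 0.05)
  tab <- average_methylation_by_context(fx$sites, "tri")
  expect_true(all(tab$n_sites > 2000))
  # every default mixture has true mean 0.5
  expect_true(all(abs(tab$mean_beta - 0.5) < 0.02))
  # truth-table beta* means agree with the design too
  mt <- tapply(fx$truth$true_beta, trinucleotide_of(fx$truth$context), mean)
  expect_true(all(abs(mt - 0.5) < 0.02))
})

test_that("conserved contexts show larger endpoint KL than variable ones", {
  fx <- sim_fixture(seed = 36L, length = 200000L, cpg_rate = 0.05)
  rep <- suppressWarnings(analyze_all_contexts(fx$sites, "tri"))
  r <- rep$rows
  cons <- r$context %in% c("GCG", "CCG")
  expect_gt(min(r$kl0[cons]), max(r$kl0[!cons]))
  expect_gt(min(r$kl1[cons]), max(r$kl1[!cons]))
})
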
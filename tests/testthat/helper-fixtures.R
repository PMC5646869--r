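# fixtures are always built in code at test time

# the 3-site toy methylome, placed on real CpGs of TOY_REF so the same
# sites drive both the distribution-level and the end-to-end CLI tests
TOY_REF <- c(chrT = "TACGATCGAT")  # CpGs at (3,4) and (7,8)

toy_sites <- function() {
  methyl_sites("chrT", c(3L, 4L, 7L), c("+", "-", "+"),
               c(2L, 0L, 2L), c(2L, 2L, 4L))
}

write_toy_fasta <- function(path = tempfile(fileext = ".fa")) {
  writeLines(c(">chrT toy", unname(TOY_REF)), path)
  path
}

write_toy_cx <- function(path = tempfile(fileext = ".cx")) {
  writeLines(c("chrT\t3\t+\t2\t0\tCG\tCGA",
               "chrT\t4\t-\t0\t2\tCG\tCGT",
               "chrT\t7\t+\t2\t2\tCG\tCGA"), path)
  path
}

# small simulated methylome shared by stratification tests
sim_fixture <- function(seed = 11L, length = 120000L, cpg_rate = 0.05,
                        lambda = 9) {
  ref <- simulate_reference(length, cpg_rate, seed = seed)
  sim <- simulate_methylome(ref, simulation_model(lambda = lambda,
                                                  seed = seed + 1L))
  list(ref = ref, sites = sim$sites, truth = sim$truth)
}
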
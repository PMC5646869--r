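# independent brute-force oracles: deliberately naive enumeration, kept
# separate from the package's analytic code paths.

# reduced-fraction key "n/d" for a vector of counts at one depth
frac_key <- function(n, t) {
  g <- vapply(n, function(a) {
    b <- t
    while (b != 0L) { tmp <- b; b <- a %% b; a <- tmp }
    a
  }, 0L)
  g[g == 0L] <- 1L
  paste(n %/% g, t %/% g, sep = "/")
}

# exhaustive enumeration of the depth-matched binomial null: every joint
# methylated-count outcome of the site multiset, weighted by its
# product-binomial probability; returns named masses keyed "n/d".
oracle_rran <- function(depths, p) {
  k <- length(depths)
  grid <- as.matrix(expand.grid(lapply(depths, function(t) 0:t)))
  w <- exp(rowSums(matrix(
    dbinom(as.integer(grid), rep(depths, each = nrow(grid)), p, log = TRUE),
    nrow = nrow(grid))))
  acc <- new.env(parent = emptyenv())
  for (j in seq_len(k)) {
    lut <- frac_key(0:depths[j], depths[j])
    keys <- lut[grid[, j] + 1L]
    s <- tapply(w / k, keys, sum)
    for (kk in names(s)) {
      old <- if (exists(kk, envir = acc)) get(kk, envir = acc) else 0
      assign(kk, old + s[[kk]], envir = acc)
    }
  }
  unlist(as.list(acc))
}

# named-mass view of a beta_dist for comparison against oracle output
dist_as_named <- function(dist) {
  stats::setNames(dist$mass, paste(dist$num, dist$den, sep = "/"))
}

# frozen values for the 3-site toy methylome {(T,M)} = {(2,2),(2,0),(4,2)},
# computed by oracle_rran + direct arithmetic before the main build:
# p = 0.5, r_ran(0) = r_ran(1) = 0.1875, r_ran(1/2) = 11/24.
TOY_KL0 <- 0.2766916662     # (1/3) log2((1/3)/0.1875)
TOY_D0 <- 7 / 48            # 1/3 - 0.1875 = 0.1458333
TOY_KL_FULL <- 0.4002394595 # 2*TOY_KL0 + (1/3) log2((1/3)/(11/24))
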
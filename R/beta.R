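# ---- exact-fraction support ------------------------------------------------

# vectorized Euclid; gcd(0, d) = d, so 0/T reduces to 0/1
gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (any(b != 0L)) {
    nz <- b != 0L
    t <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b[nz] <- t
  }
  a
}

#' Exact beta value of one cytosine call
#'
#' The per-site methylation level \eqn{\beta = M/T} as an exact reduced
#' fraction, not a floating-point number: equal values arising from different
#' depths (1/2 and 2/4) must be indistinguishable downstream.
#'
#' @param meth_count integer M, `0 <= M <= depth`.
#' @param depth positive integer T.
#' @return A length-2 named integer vector `c(num, den)` of class
#'   `beta_fraction`, fully reduced (`beta_value(0, 7)` is `0/1`).
#' @export
#' @examples
#' beta_value(2L, 4L)  # 1/2
beta_value <- function(meth_count, depth) {
  meth_count <- as.integer(meth_count); depth <- as.integer(depth)
  if (length(meth_count) != 1L || length(depth) != 1L)
    stop("beta_value is scalar; see observed_distribution() for collections",
         call. = FALSE)
  if (is.na(depth) || depth < 1L)
    stop("depth must be a positive integer", call. = FALSE)
  if (is.na(meth_count) || meth_count < 0L || meth_count > depth)
    stop("meth_count must satisfy 0 <= M <= T", call. = FALSE)
  g <- gcd_int(meth_count, depth)
  structure(c(num = meth_count %/% g, den = depth %/% g),
            class = "beta_fraction")
}

#' @export
print.beta_fraction <- function(x, ...) {
  cat(x[["num"]], "/", x[["den"]], " (= ", x[["num"]] / x[["den"]], ")\n",
      sep = "")
  invisible(x)
}

#' @export
as.double.beta_fraction <- function(x, ...) unname(x[["num"]] / x[["den"]])

# internal constructor: reduce fractions, merge equal values, order by beta.
# `mass` is numeric; support points are exact (num, den) pairs.
new_beta_dist <- function(num, den, mass, n_sites) {
  g <- gcd_int(num, den)
  dt <- data.table(num = as.integer(num) %/% g,
                   den = as.integer(den) %/% g,
                   mass = as.numeric(mass))
  dt <- dt[, .(mass = sum(mass)), by = .(num, den)]
  dt <- dt[mass > 0]  # support = values with positive mass
  dt[, beta := num / den]
  setorder(dt, beta)
  structure(list(num = dt$num, den = dt$den, beta = dt$beta, mass = dt$mass,
                 n_sites = as.integer(n_sites)),
            class = "beta_dist")
}

#' @export
print.beta_dist <- function(x, ...) {
  cat("<beta_dist> ", length(x$mass), " support points, N = ", x$n_sites,
      ", total mass = ", format(sum(x$mass), digits = 12), "\n", sep = "")
  k <- min(length(x$mass), 10L)
  for (i in seq_len(k))
    cat(sprintf("  %d/%d\t%.6g\n", x$num[i], x$den[i], x$mass[i]))
  if (length(x$mass) > k) cat("  ...\n")
  invisible(x)
}

#' Probability mass of a beta distribution at a given value
#'
#' @param dist a `beta_dist` (from [observed_distribution()] or
#'   [random_distribution()]).
#' @param beta the value to look up; 0 and 1 are matched exactly as the
#'   endpoint fractions 0/1 and 1/1, other values within 1e-12.
#' @return The mass at `beta` (0 if `beta` is not a support point).
#' @export
mass_at <- function(dist, beta) {
  stopifnot(inherits(dist, "beta_dist"))
  if (identical(beta, 0) || identical(beta, 0L)) {
    i <- which(dist$num == 0L)
  } else if (identical(beta, 1) || identical(beta, 1L)) {
    i <- which(dist$num == dist$den)
  } else {
    i <- which(abs(dist$beta - beta) < 1e-12)
  }
  if (!length(i)) 0 else sum(dist$mass[i])
}

# ---- observed distribution (r_obs) ----------------------------------------

#' Observed methylation-level distribution
#'
#' The empirical distribution of beta values over a site collection: mass
#' 1/N at each site's exact reduced fraction M/T, with equal fractions merged
#' (a 1/2 from depth 2 and a 2/4 from depth 4 share one support point).
#'
#' @param sites site table (see [methyl_sites()]); must be non-empty.
#' @return A `beta_dist`.
#' @export
#' @examples
#' s <- methyl_sites("c", 1:3, "+", c(2L, 0L, 2L), c(2L, 2L, 4L))
#' observed_distribution(s)  # mass 1/3 at each of 0, 1/2, 1
observed_distribution <- function(sites) {
  validate_sites(sites, allow_empty = FALSE)
  n <- nrow(sites)
  new_beta_dist(sites$meth_count, sites$depth, rep(1 / n, n), n)
}

#' Average methylation level
#'
#' The binomial-null success probability p.  The default `per_site` mode is
#' the arithmetic mean of the per-site beta values; the `pooled` mode
#' (sum of M over sum of T) is a depth-weighted diagnostic alternative and is
#' never used implicitly.
#'
#' @param sites non-empty site table.
#' @param mode `"per_site"` (default) or `"pooled"`.
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' s <- methyl_sites("c", 1:2, "+", c(10L, 0L), c(10L, 2L))
#' mean_methylation(s)                   # (1 + 0)/2 = 0.5
#' mean_methylation(s, mode = "pooled")  # 10/12
mean_methylation <- function(sites, mode = c("per_site", "pooled")) {
  mode <- match.arg(mode)
  validate_sites(sites, allow_empty = FALSE)
  if (mode == "per_site") mean(sites$meth_count / sites$depth)
  else sum(as.numeric(sites$meth_count)) / sum(as.numeric(sites$depth))
}

# ---- binomial null (r_ran) -------------------------------------------------

#' Binomial probability of observing n methylated reads at depth T
#'
#' `P(T, n) = choose(T, n) p^n (1-p)^(T-n)`, with the convention 0^0 = 1 so
#' the degenerate rates p = 0 and p = 1 are point masses at n = 0 and n = T.
#'
#' @param depth positive integer T.
#' @param n integer in `0:depth` (vectorized).
#' @param p probability in \[0, 1\].
#' @return Probability (vector).
#' @export
#' @examples
#' binomial_pmf(4L, 2L, 0.5)  # 0.375
binomial_pmf <- function(depth, n, p) {
  depth <- as.integer(depth); n <- as.integer(n)
  if (any(depth < 1L)) stop("depth must be >= 1", call. = FALSE)
  if (any(p < 0) || any(p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (any(n < 0L) || any(n > depth))
    stop("n out of range 0..depth", call. = FALSE)
  dbinom(n, depth, p)
}

#' Depth-matched binomial null distribution
#'
#' The analytic (closed-form, never sampled) distribution of beta values that
#' a random methylome with the given depth profile and a common methylation
#' probability p would produce: for every depth T with c_T sites, mass
#' `c_T * P(T, n) / N` is placed at the reduced fraction n/T for n = 0..T,
#' and equal fractions from different depths merge.
#'
#' @param profile a [depth_profile()] (or anything it accepts).
#' @param p common methylation probability.
#' @return A `beta_dist` with total mass 1 and mean exactly p.
#' @export
#' @examples
#' random_distribution(depth_profile(c(2L, 2L, 4L)), 0.5)
random_distribution <- function(profile, p) {
  if (!inherits(profile, "depth_profile")) profile <- depth_profile(profile)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  n_tot <- sum(profile$count)
  num <- unlist(lapply(profile$depth, function(t) 0:t), use.names = FALSE)
  den <- rep.int(profile$depth, profile$depth + 1L)
  w <- unlist(Map(function(t, c) dbinom(0:t, t, p) * (c / n_tot),
                  profile$depth, profile$count), use.names = FALSE)
  new_beta_dist(num, den, w, n_tot)
}

#' Restrict a site collection to one sequencing depth
#'
#' @param sites site table.
#' @param depth the depth T to keep.
#' @return The sites with exactly that depth; possibly empty.
#' @export
restrict_to_depth <- function(sites, depth) {
  validate_sites(sites)
  # evaluate the filter eagerly: inside `[.data.table` the name `depth`
  # would resolve to the column, not this argument
  sel <- which(sites$depth == as.integer(depth))
  sites[sel, , drop = FALSE]
}

#' Monte-Carlo sample from the binomial null
#'
#' Validation oracle for [random_distribution()]: simulates `draws` replicate
#' methylomes over the profile, sampling each site's methylated count
#' binomially, and returns the empirical beta distribution of the
#' `N * draws` sampled values.  Never used as the primary computation.
#'
#' @param profile a [depth_profile()].
#' @param p methylation probability.
#' @param draws number of replicate methylomes (>= 1).
#' @param seed integer seed; same seed, same output.
#' @return A `beta_dist` (with `n_sites` = number of sites in the profile).
#' @export
sample_random_methylome <- function(profile, p, draws = 1L, seed = 1L) {
  if (!inherits(profile, "depth_profile")) profile <- depth_profile(profile)
  draws <- as.integer(draws)
  if (draws < 1L) stop("draws must be >= 1", call. = FALSE)
  depths <- rep.int(rep.int(profile$depth, profile$count), draws)
  set.seed(as.integer(seed))
  m <- rbinom(length(depths), depths, p)
  new_beta_dist(m, depths, rep(1 / length(depths), length(depths)),
                sum(profile$count))
}
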
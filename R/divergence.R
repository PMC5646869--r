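# relative-entropy statistics comparing r_obs with the depth-matched null

# align the observed support onto the null support; returns null masses in
# the order of obs's support (0 where the null has no mass there)
align_masses <- function(obs, ran) {
  stopifnot(inherits(obs, "beta_dist"), inherits(ran, "beta_dist"))
  if (obs$n_sites != ran$n_sites)
    stop("distributions were built from different site sets (N = ",
         obs$n_sites, " vs ", ran$n_sites, ")", call. = FALSE)
  i <- match(paste(obs$num, obs$den), paste(ran$num, ran$den))
  r <- ran$mass[i]
  r[is.na(r)] <- 0
  r
}

#' Kullback-Leibler divergence of the observed distribution from the null
#'
#' `KL = sum_beta r_obs(beta) * log2(r_obs(beta) / r_ran(beta))` in bits,
#' summed over the support of the observed distribution with the convention
#' `0 log 0 = 0`.  Non-negative by the Gibbs inequality whenever the null is
#' positive on the observed support (always true for p strictly inside
#' (0, 1), since every fraction n/T is then reachable).
#'
#' @param obs,ran `beta_dist` objects built from the same site set (same N
#'   and depth profile): typically [observed_distribution()] and
#'   [random_distribution()].
#' @return Divergence in bits.
#' @export
kl_divergence <- function(obs, ran) {
  r <- align_masses(obs, ran)
  pos <- obs$mass > 0
  if (any(pos & r == 0))
    stop("divergence undefined: observed mass where the null has none ",
         "(degenerate p?)", call. = FALSE)
  sum(obs$mass[pos] * log2(obs$mass[pos] / r[pos]))
}

#' Endpoint relative-entropy terms KL(0) and KL(1)
#'
#' The single-term contribution `r_obs(e) * log2(r_obs(e) / r_ran(e))` at an
#' endpoint e of the beta scale.  KL(0) measures methylation variation
#' (conservation of the unmethylated state), KL(1) demethylation variation.
#' Being single terms these are signed: a negative value means the endpoint
#' is depleted relative to the null.
#'
#' @inheritParams kl_divergence
#' @param endpoint 0 or 1.
#' @return Signed contribution in bits; 0 when `r_obs(endpoint) = 0`.
#' @export
endpoint_kl <- function(obs, ran, endpoint) {
  stopifnot(endpoint %in% c(0, 1))
  if (obs$n_sites != ran$n_sites)
    stop("distributions were built from different site sets", call. = FALSE)
  ro <- mass_at(obs, endpoint)
  rr <- mass_at(ran, endpoint)
  if (ro == 0) return(0)
  if (rr == 0)
    stop("divergence undefined at endpoint ", endpoint,
         ": null mass is zero (degenerate p)", call. = FALSE)
  ro * log2(ro / rr)
}

#' Direct endpoint difference d(beta)
#'
#' The simpler deviation measure `d(e) = r_obs(e) - r_ran(e)`; positive means
#' the observed distribution has excess mass at the endpoint.
#'
#' @inheritParams endpoint_kl
#' @return Signed mass difference.
#' @export
direct_difference <- function(obs, ran, endpoint) {
  stopifnot(endpoint %in% c(0, 1))
  if (obs$n_sites != ran$n_sites)
    stop("distributions were built from different site sets", call. = FALSE)
  mass_at(obs, endpoint) - mass_at(ran, endpoint)
}

#' Full divergence summary for one site collection
#'
#' Estimates p over exactly the sites passed in, builds the observed and
#' depth-matched null distributions, and returns every deviation statistic
#' as one record.  A degenerate p (exactly 0 or 1) makes the null a point
#' mass and the endpoint statistics meaningless; it is raised as an error
#' naming the context.
#'
#' @param sites non-empty site table.
#' @param context label for the record (a tetranucleotide, trinucleotide or
#'   `"ALL"`).
#' @param p_mode passed to [mean_methylation()].
#' @return A one-row `data.frame` with columns `context`, `n_sites`, `p`,
#'   `robs0`, `rran0`, `robs1`, `rran1`, `kl0`, `kl1`, `d0`, `d1`, `kl_full`.
#' @export
#' @examples
#' s <- methyl_sites("c", 1:3, "+", c(2L, 0L, 2L), c(2L, 2L, 4L))
#' summarize_divergence(s)  # kl0 = kl1 = 0.2766917 bits
summarize_divergence <- function(sites, context = "ALL",
                                 p_mode = c("per_site", "pooled")) {
  p_mode <- match.arg(p_mode)
  validate_sites(sites, allow_empty = FALSE)
  p <- mean_methylation(sites, p_mode)
  if (p <= 0 || p >= 1)
    stop("degenerate mean methylation p = ", p, " in context '", context,
         "': the binomial null is a point mass", call. = FALSE)
  obs <- observed_distribution(sites)
  ran <- random_distribution(depth_profile(sites), p)
  data.frame(
    context = context,
    n_sites = nrow(sites),
    p = p,
    robs0 = mass_at(obs, 0), rran0 = mass_at(ran, 0),
    robs1 = mass_at(obs, 1), rran1 = mass_at(ran, 1),
    kl0 = endpoint_kl(obs, ran, 0),
    kl1 = endpoint_kl(obs, ran, 1),
    d0 = direct_difference(obs, ran, 0),
    d1 = direct_difference(obs, ran, 1),
    kl_full = kl_divergence(obs, ran),
    stringsAsFactors = FALSE
  )
}
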
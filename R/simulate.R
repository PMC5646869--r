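# seeded synthetic methylome generator.
#
# The generator states a world with the three statistical features the
# analysis assumes: heterogeneous per-site depth (shifted Poisson, T >= 1),
# bimodal per-site true methylation (a two-component Beta mixture), and
# binomial read sampling.  Endpoint concentration of the truth mixture is
# the single knob distinguishing "conserved" contexts (G/C before the CpG:
# sharply endpoint-concentrated Beta(0.3, 6) / Beta(6, 0.3)) from "variable"
# ones (A/T: flatter Beta(1, 3) / Beta(3, 1)); both classes have true mean
# 0.5, isolating variability from level.

#' Default per-context truth mixtures
#'
#' One row per 5' flanking base N5; applied to every N5CGN3 tetranucleotide
#' sharing that N5.  `w` is the mass of the low-methylation component.
#'
#' @return A `data.table` with columns `n5`, `class`, `w`, `a_low`, `b_low`,
#'   `a_high`, `b_high`.
#' @export
default_context_models <- function() {
  data.table(
    n5 = c("A", "C", "G", "T"),
    class = c("variable", "conserved", "conserved", "variable"),
    w = 0.5,
    a_low = c(1, 0.3, 0.3, 1),
    b_low = c(3, 6, 6, 3),
    a_high = c(3, 6, 6, 3),
    b_high = c(1, 0.3, 0.3, 1)
  )
}

#' Specify a synthetic methylome model
#'
#' @param contexts per-N5 truth mixtures, as [default_context_models()].
#' @param depth_kind `"shifted_poisson"` (T = 1 + Poisson(lambda)) or
#'   `"empirical"` (T drawn uniformly from `depth_values`).
#' @param lambda Poisson rate for the shifted-Poisson depth model; the
#'   default 9 gives mean depth 10x, typical of published whole-genome
#'   bisulfite methylomes.
#' @param depth_values integer vector of depths for the empirical model.
#' @param seed integer seed making every draw reproducible.
#' @return A list of class `simulation_model`.
#' @export
simulation_model <- function(contexts = default_context_models(),
                             depth_kind = c("shifted_poisson", "empirical"),
                             lambda = 9, depth_values = NULL, seed = 1L) {
  depth_kind <- match.arg(depth_kind)
  stopifnot(is.data.frame(contexts),
            all(c("n5", "w", "a_low", "b_low", "a_high", "b_high") %in%
                  names(contexts)))
  if (any(contexts$w < 0 | contexts$w > 1))
    stop("mixture weight w must be in [0, 1]", call. = FALSE)
  if (any(unlist(contexts[, c("a_low", "b_low", "a_high", "b_high")]) <= 0))
    stop("Beta parameters must be > 0", call. = FALSE)
  if (depth_kind == "shifted_poisson" && lambda < 0)
    stop("lambda must be >= 0", call. = FALSE)
  if (depth_kind == "empirical" &&
      (is.null(depth_values) || any(depth_values < 1L)))
    stop("empirical depth model needs depth_values >= 1", call. = FALSE)
  structure(list(contexts = as.data.table(contexts), depth_kind = depth_kind,
                 lambda = lambda, depth_values = depth_values,
                 seed = as.integer(seed)),
            class = "simulation_model")
}

#' Simulate a reference sequence with planted CpGs
#'
#' Generates a CpG-free random background (uniform bases, with any C->G
#' adjacency resolved away) and plants `Binomial(length, cpg_rate)` CpG
#' dinucleotides at even offsets in `[2, length-2]`, so planted CpGs never
#' overlap, always have full flanks, and the total CpG count is exactly the
#' binomial draw.  Flanking bases are (near-)uniform over A/C/G/T, so all 16
#' tetranucleotide contexts occur at comparable frequency.
#'
#' @param length sequence length (>= 10).
#' @param cpg_rate planting probability per base, in (0, 0.5).
#' @param seed integer seed.
#' @return A named character vector of length 1 (a reference map with a
#'   single chromosome `"sim1"`), as from [read_fasta()].
#' @export
simulate_reference <- function(length, cpg_rate, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 10L) stop("length must be >= 10", call. = FALSE)
  if (cpg_rate <= 0 || cpg_rate >= 0.5)
    stop("cpg_rate must be in (0, 0.5)", call. = FALSE)
  set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # remove background CG dinucleotides so the planted count is exact
  repeat {
    bad <- which(bases[-length] == "C" & bases[-1L] == "G")
    if (!base::length(bad)) break
    bases[bad + 1L] <- sample(c("A", "C", "T"), base::length(bad),
                              replace = TRUE)
  }
  ncpg <- rbinom(1L, length, cpg_rate)
  candidates <- seq(2L, length - 2L, by = 2L)
  if (ncpg > base::length(candidates))
    stop("cpg_rate too high for this length", call. = FALSE)
  starts <- sort(sample(candidates, ncpg))
  bases[starts] <- "C"
  bases[starts + 1L] <- "G"
  c(sim1 = paste(bases, collapse = ""))
}

# depth draws under a model (vectorized, consumes the current RNG stream)
draw_depths <- function(model, n) {
  if (model$depth_kind == "shifted_poisson") 1L + rpois(n, model$lambda)
  else sample(as.integer(model$depth_values), n, replace = TRUE)
}

#' Simulate a methylome over a reference
#'
#' For every CpG strand-cytosine with an available context, draws (in
#' coordinate order, plus strand before minus): the site's true methylation
#' level beta* from its context's Beta mixture, its depth T from the depth
#' model, and its methylated count M ~ Binomial(T, beta*).  Each variable is
#' drawn as one vectorized call over all sites (beta* for all sites, then T,
#' then M), so output is bit-reproducible given the seed.
#'
#' @param reference reference map (e.g. from [simulate_reference()]).
#' @param model a [simulation_model()].
#' @return A list with `sites` (annotated site table, including `context`),
#'   `truth` (position, strand, context, true_beta, depth, meth_count) and
#'   `model`.
#' @export
simulate_methylome <- function(reference, model = simulation_model()) {
  stopifnot(inherits(model, "simulation_model"))
  cpgs <- enumerate_cpg_sites(reference)
  if (!nrow(cpgs)) stop("reference contains no CpG", call. = FALSE)
  ctx <- unlist(lapply(split(cpgs, cpgs$chrom)[unique(cpgs$chrom)],
                       function(g) contexts_on_chrom(reference[[g$chrom[1L]]],
                                                     g$position, g$strand)),
                use.names = FALSE)
  keep <- !is.na(ctx)
  cpgs <- cpgs[keep]
  ctx <- ctx[keep]
  n <- nrow(cpgs)
  idx <- match(substr(ctx, 1L, 1L), model$contexts$n5)
  if (anyNA(idx))
    stop("context model missing an N5 base", call. = FALSE)
  cm <- model$contexts[idx]
  set.seed(model$seed)
  low <- runif(n) < cm$w
  bstar <- numeric(n)
  bstar[low] <- rbeta(sum(low), cm$a_low[low], cm$b_low[low])
  bstar[!low] <- rbeta(sum(!low), cm$a_high[!low], cm$b_high[!low])
  depth <- draw_depths(model, n)
  m <- rbinom(n, depth, bstar)
  sites <- data.table(chrom = cpgs$chrom, position = cpgs$position,
                      strand = cpgs$strand, meth_count = as.integer(m),
                      depth = as.integer(depth), context = ctx)
  truth <- data.table(chrom = cpgs$chrom, position = cpgs$position,
                      strand = cpgs$strand, context = ctx, true_beta = bstar,
                      depth = as.integer(depth), meth_count = as.integer(m))
  list(sites = sites, truth = truth, model = model)
}

#' Simulate a methylome from the binomial null itself
#'
#' The generative twin of the analytic null: every site keeps its own depth
#' T and draws M ~ Binomial(T, p) with a common p.  Used for null-recovery
#' calibration: the pipeline's KL(0)/KL(1) on such data converge to 0.
#'
#' @param profile a [depth_profile()].
#' @param p common methylation probability.
#' @param seed integer seed.
#' @return A site table (synthetic coordinates on chromosome `"sim1"`,
#'   plus strand).
#' @export
simulate_null_methylome <- function(profile, p, seed = 1L) {
  if (!inherits(profile, "depth_profile")) profile <- depth_profile(profile)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  depths <- rep.int(profile$depth, profile$count)
  set.seed(as.integer(seed))
  m <- rbinom(length(depths), depths, p)
  methyl_sites("sim1", seq_along(depths) * 2L, "+", m, depths)
}
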
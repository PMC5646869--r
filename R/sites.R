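#' Construct a table of strand-specific cytosine methylation calls
#'
#' The central data container: one row per strand-specific cytosine of a CpG
#' dinucleotide, carrying the methylated read count M and the sequencing
#' depth T.  Positions are 1-based reference coordinates; for minus-strand
#' sites the coordinate is that of the G-paired base carrying the
#' minus-strand C.
#'
#' @param chrom character vector of sequence identifiers.
#' @param position integer vector of 1-based coordinates.
#' @param strand character vector, each element `"+"` or `"-"`.
#' @param meth_count integer vector, methylated read counts (M).
#' @param depth integer vector, total read counts (T), all >= 1.
#' @return A `data.table` with columns `chrom`, `position`, `strand`,
#'   `meth_count`, `depth`.
#' @export
#' @examples
#' methyl_sites("chr1", c(3L, 4L), c("+", "-"), c(5L, 2L), c(8L, 4L))
methyl_sites <- function(chrom, position, strand, meth_count, depth) {
  dt <- data.table(
    chrom = as.character(chrom),
    position = as.integer(position),
    strand = as.character(strand),
    meth_count = as.integer(meth_count),
    depth = as.integer(depth)
  )
  validate_sites(dt)
  dt[]
}

# invariant checks shared by every consumer of a site table
validate_sites <- function(sites, allow_empty = TRUE) {
  if (!is.data.frame(sites))
    stop("sites must be a data.frame / data.table", call. = FALSE)
  need <- c("chrom", "position", "strand", "meth_count", "depth")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("sites table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(sites) == 0L) {
    if (!allow_empty) stop("empty site collection", call. = FALSE)
    return(invisible(sites))
  }
  if (any(!sites$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (any(sites$depth < 1L))
    stop("depth must be >= 1 (zero-coverage rows are never materialized)",
         call. = FALSE)
  if (any(sites$meth_count < 0L) || any(sites$meth_count > sites$depth))
    stop("meth_count must satisfy 0 <= M <= T", call. = FALSE)
  invisible(sites)
}

empty_sites <- function() {
  data.table(chrom = character(), position = integer(), strand = character(),
             meth_count = integer(), depth = integer())
}

#' Depth profile of a site collection
#'
#' The multiset of per-site sequencing depths \{T_i\} that drives the
#' binomial null: a table of (depth, count) pairs.
#'
#' @param x either a site table (as from [methyl_sites()]), an integer vector
#'   of depths (one entry per site), or a two-column data.frame with columns
#'   `depth` and `count`.
#' @return A `data.table` of class `depth_profile` with columns `depth`
#'   (positive integer) and `count` (number of sites at that depth), ordered
#'   by depth.
#' @export
#' @examples
#' depth_profile(c(2L, 2L, 4L))
depth_profile <- function(x) {
  if (is.data.frame(x) && all(c("depth", "count") %in% names(x)) &&
      !"meth_count" %in% names(x)) {
    dp <- data.table(depth = as.integer(x$depth), count = as.integer(x$count))
  } else if (is.data.frame(x)) {
    validate_sites(x, allow_empty = FALSE)
    dp <- as.data.table(x)[, .(count = .N), by = .(depth)]
  } else {
    d <- as.integer(x)
    if (!length(d)) stop("empty depth multiset", call. = FALSE)
    dp <- data.table(depth = d)[, .(count = .N), by = .(depth)]
  }
  if (any(dp$depth < 1L)) stop("all depths must be >= 1", call. = FALSE)
  if (any(dp$count < 0L) || sum(dp$count) < 1L)
    stop("depth profile must contain at least one site", call. = FALSE)
  dp <- dp[count > 0L]
  setorder(dp, depth)
  setattr(dp, "class", c("depth_profile", class(dp)))
  dp[]
}
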
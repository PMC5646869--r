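# orchestration of the context-, depth- and region-stratified analyses

ALL_TETRA <- as.vector(outer(c("A", "C", "G", "T"),
                             c("A", "C", "G", "T"),
                             function(a, b) paste0(a, "CG", b)))
ALL_TRI <- paste0(c("A", "C", "G", "T"), "CG")

new_strat_report <- function(rows, metadata) {
  structure(list(rows = rows, metadata = metadata), class = "strat_report")
}

#' @export
print.strat_report <- function(x, ...) {
  cat("<strat_report> ", nrow(x$rows), " row(s); ",
      paste(names(x$metadata), unlist(lapply(x$metadata, paste, collapse = ",")),
            sep = "=", collapse = "; "), "\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' Divergence statistics per flanking-sequence context
#'
#' Groups annotated sites by tetranucleotide (16 classes) or trinucleotide
#' (4 classes, tetra merged over the 3' base) and runs
#' [summarize_divergence()] within each group.  The binomial-null p is
#' estimated within each context class, i.e. it is the average methylation
#' level of that class.  Contexts with no sites are omitted with a warning.
#'
#' @param annotated site table with a `context` column (from
#'   [annotate_sites()]).
#' @param mode `"tetra"` or `"tri"`.
#' @param p_mode passed to [mean_methylation()].
#' @return A `strat_report`: `$rows` is a data.frame of per-context
#'   divergence records, `$metadata` records totals and settings.
#' @export
analyze_all_contexts <- function(annotated, mode = c("tetra", "tri"),
                                 p_mode = c("per_site", "pooled")) {
  mode <- match.arg(mode)
  p_mode <- match.arg(p_mode)
  if (!"context" %in% names(annotated))
    stop("sites lack a 'context' column; run annotate_sites() first",
         call. = FALSE)
  if (nrow(annotated) == 0L)
    stop("no annotated sites to analyze", call. = FALSE)
  key <- if (mode == "tri") trinucleotide_of(annotated$context)
         else annotated$context
  universe <- if (mode == "tri") ALL_TRI else ALL_TETRA
  groups <- split(seq_len(nrow(annotated)), key)
  absent <- setdiff(universe, names(groups))
  if (length(absent))
    warning("context(s) with zero sites omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  rows <- do.call(rbind, lapply(names(groups), function(ctx)
    tryCatch(
      summarize_divergence(annotated[groups[[ctx]], , drop = FALSE],
                           context = ctx, p_mode = p_mode),
      error = function(e) {
        # a context whose p is exactly 0 or 1 has no usable null; report the
        # gap instead of aborting the whole stratification
        warning("context ", ctx, " omitted: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })))
  if (is.null(rows))
    stop("every context group was degenerate; nothing to report",
         call. = FALSE)
  rows <- rows[order(rows$context), , drop = FALSE]
  rownames(rows) <- NULL
  new_strat_report(rows, list(mode = mode, p_mode = p_mode,
                              n_sites = nrow(annotated),
                              n_contexts = nrow(rows)))
}

#' Depth-stratified context analysis
#'
#' For each requested sequencing depth, restricts to sites with exactly that
#' depth and reruns [analyze_all_contexts()].  Depths with no sites are
#' reported empty with a warning.
#'
#' @inheritParams analyze_all_contexts
#' @param depths vector of positive integer depths (e.g. `c(4, 6, 8)`).
#' @return A `strat_report` whose rows carry an extra `depth` column.
#' @export
analyze_by_depth <- function(annotated, depths, mode = c("tetra", "tri"),
                             p_mode = c("per_site", "pooled")) {
  mode <- match.arg(mode)
  p_mode <- match.arg(p_mode)
  if (!length(depths)) stop("depths must be non-empty", call. = FALSE)
  rows <- list()
  for (d in as.integer(depths)) {
    sub <- restrict_to_depth(annotated, d)
    if (nrow(sub) == 0L) {
      warning("no sites at depth ", d, "; stratum reported empty",
              call. = FALSE)
      next
    }
    r <- tryCatch(analyze_all_contexts(sub, mode = mode, p_mode = p_mode)$rows,
                  error = function(e) {
                    warning("depth ", d, " stratum unusable: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(r)) next
    r$depth <- d
    rows[[as.character(d)]] <- r
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    cbind(summarize_divergence(annotated, "ALL", p_mode)[0, ],
          depth = integer(0))
  rownames(rows) <- NULL
  new_strat_report(rows, list(mode = mode, p_mode = p_mode,
                              depths = as.integer(depths),
                              n_sites = nrow(annotated)))
}

#' Restrict sites to (or exclude them from) a region set
#'
#' Overlapping intervals are merged before testing; a site belongs to a
#' region when its own 1-based cytosine coordinate p satisfies
#' `start < p <= end` for a 0-based half-open interval, i.e. membership is
#' decided by the cytosine base itself, not the CpG dinucleotide span.
#'
#' @param sites site table.
#' @param intervals data.frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), as from [read_bed()].
#' @param keep `"inside"` (default) or `"outside"`.
#' @return The selected sites.
#' @export
subset_by_regions <- function(sites, intervals, keep = c("inside", "outside")) {
  keep <- match.arg(keep)
  validate_sites(sites)
  if (nrow(sites) == 0L) return(sites)
  if (!nrow(intervals))
    return(if (keep == "inside") sites[0L, , drop = FALSE] else sites)
  if (any(intervals$start >= intervals$end) || any(intervals$start < 0L))
    stop("invalid interval (start >= end or negative start)", call. = FALSE)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)))
  ss <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$position,
                                                sites$position))
  # disjoint chromosome sets are a legitimate "no overlap", not a warning
  inside <- suppressWarnings(IRanges::overlapsAny(ss, gr))
  sites[if (keep == "inside") inside else !inside, , drop = FALSE]
}

#' Average methylation level per context
#'
#' Per-context arithmetic mean of the per-site beta values (and site count),
#' the level summary that complements the variability statistics.
#'
#' @inheritParams analyze_all_contexts
#' @return A `data.table` with columns `context`, `mean_beta`, `n_sites`,
#'   ordered by context.
#' @export
average_methylation_by_context <- function(annotated,
                                           mode = c("tetra", "tri")) {
  mode <- match.arg(mode)
  if (!"context" %in% names(annotated) || nrow(annotated) == 0L)
    stop("non-empty annotated sites required", call. = FALSE)
  dt <- copy(as.data.table(annotated))
  dt[, key := if (mode == "tri") trinucleotide_of(context) else context]
  out <- dt[, .(mean_beta = mean(meth_count / depth), n_sites = .N),
            by = .(context = key)]
  setorder(out, context)
  out[]
}
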
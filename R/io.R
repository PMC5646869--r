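# readers/writers for the standard formats touched by the pipeline:
# Bismark-style cytosine (CX) reports, bedGraph coverage, FASTA, BED,
# and TSV result tables.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readLines(path, warn = FALSE)
}

as_int_strict <- function(x) {
  out <- suppressWarnings(as.integer(x))
  out[!grepl("^[0-9]+$", x)] <- NA_integer_
  out
}

#' Read a Bismark-style cytosine (CX) report
#'
#' Expected tab-separated columns: chrom, 1-based position, strand,
#' methylated count, unmethylated count, optional context class (e.g. "CG"),
#' optional trinucleotide.  Depth is the sum of the two counts; zero-depth
#' rows are skipped (with a reported count), never materialized.
#'
#' @param path file path.
#' @param min_depth minimum depth T to keep (default 1: no cutoff beyond
#'   requiring coverage).
#' @param max_depth optional maximum depth.
#' @param cpg_only if `TRUE`, rows whose context-class column is present and
#'   not `"CG"` are skipped.
#' @return A site table (see [methyl_sites()]); possibly empty.
#' @export
read_cx_report <- function(path, min_depth = 1L, max_depth = NULL,
                           cpg_only = FALSE) {
  min_depth <- as.integer(min_depth)
  if (min_depth < 1L) stop("min_depth must be >= 1", call. = FALSE)
  if (!is.null(max_depth) && as.integer(max_depth) < min_depth)
    stop("max_depth must be >= min_depth", call. = FALSE)
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_sites())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 5L))
    stop("malformed CX row at line ", which(ncol < 5L)[1L],
         ": fewer than 5 columns", call. = FALSE)
  chrom <- vapply(f, `[[`, "", 1L)
  pos <- as_int_strict(vapply(f, `[[`, "", 2L))
  strand <- vapply(f, `[[`, "", 3L)
  m <- as_int_strict(vapply(f, `[[`, "", 4L))
  u <- as_int_strict(vapply(f, `[[`, "", 5L))
  bad <- is.na(pos) | is.na(m) | is.na(u) | !strand %in% c("+", "-")
  if (any(bad))
    stop("malformed CX row at line ", which(bad)[1L],
         ": non-integer counts or bad strand symbol", call. = FALSE)
  ctx_class <- ifelse(ncol >= 6L, vapply(f, function(x) x[min(6L, length(x))], ""), NA)
  depth <- m + u
  skip_zero <- depth == 0L
  skip_ctx <- cpg_only & !is.na(ctx_class) & nzchar(ctx_class) &
    ctx_class != "CG" & !skip_zero
  over_max <- if (is.null(max_depth)) FALSE else depth > as.integer(max_depth)
  skip_depth <- !skip_zero & !skip_ctx & (depth < min_depth | over_max)
  keep <- !(skip_zero | skip_ctx | skip_depth)
  message(sprintf(
    "read_cx_report: %d rows; kept %d; skipped %d zero-depth, %d non-CpG, %d depth-filtered",
    length(lines), sum(keep), sum(skip_zero), sum(skip_ctx), sum(skip_depth)))
  out <- methyl_sites(chrom[keep], pos[keep], strand[keep], m[keep],
                      depth[keep])
  setattr(out, "skipped",
          list(zero_depth = sum(skip_zero), non_cpg = sum(skip_ctx),
               depth_filtered = sum(skip_depth)))
  out
}

#' Write a site table as a 7-column CX report
#'
#' Columns: chrom, 1-based position, strand, methylated count, unmethylated
#' count, context class (`"CG"`), trinucleotide (from `context` or `"."`).
#'
#' @param sites site table.
#' @param path output file path.
#' @param context optional character vector of per-site tetranucleotide or
#'   trinucleotide contexts; the first three bases are written.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sites, path, context = NULL) {
  validate_sites(sites)
  tri <- if (is.null(context)) rep(".", nrow(sites)) else substr(context, 1L, 3L)
  dt <- data.table(sites$chrom, sites$position, sites$strand,
                   sites$meth_count, sites$depth - sites$meth_count,
                   "CG", tri)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read bedGraph-style methylation coverage rows
#'
#' Expected columns: chrom, 0-based start, end, methylation percentage,
#' methylated count, unmethylated count, optional strand (default `"+"`).
#' Positions are converted to 1-based (`start + 1`); the percentage column is
#' always recomputed from the counts, which are the source of truth.  Rows
#' whose stated percentage differs from `100 * M / (M + U)` by more than 0.5
#' trigger one summary warning.
#'
#' @inheritParams read_cx_report
#' @return A site table; possibly empty.
#' @export
read_bedgraph_cov <- function(path, min_depth = 1L) {
  min_depth <- as.integer(min_depth)
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(empty_sites())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 6L))
    stop("malformed bedGraph row at line ", which(ncol < 6L)[1L], call. = FALSE)
  chrom <- vapply(f, `[[`, "", 1L)
  start <- as_int_strict(vapply(f, `[[`, "", 2L))
  pct <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 4L)))
  m <- as_int_strict(vapply(f, `[[`, "", 5L))
  u <- as_int_strict(vapply(f, `[[`, "", 6L))
  strand <- ifelse(ncol >= 7L,
                   vapply(f, function(x) x[min(7L, length(x))], ""), "+")
  bad <- is.na(start) | is.na(m) | is.na(u) | is.na(pct) |
    !strand %in% c("+", "-")
  if (any(bad))
    stop("malformed bedGraph row at line ", which(bad)[1L], call. = FALSE)
  depth <- m + u
  covered <- depth > 0L
  recomputed <- ifelse(covered, 100 * m / pmax(depth, 1L), NA_real_)
  inconsistent <- covered & abs(recomputed - pct) > 0.5
  if (any(inconsistent))
    warning(sum(inconsistent), " row(s) whose percentage column disagrees ",
            "with the counts by > 0.5; counts win", call. = FALSE)
  keep <- covered & depth >= min_depth
  methyl_sites(chrom[keep], start[keep] + 1L, strand[keep], m[keep],
               depth[keep])
}

#' Read a FASTA reference into an uppercase base-string map
#'
#' @param path FASTA file path (soft-masked lowercase accepted; uppercased).
#' @return Named character vector: first whitespace-delimited header token ->
#'   uppercase sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("invalid FASTA (non-IUPAC character?): ",
                                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in FASTA: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  seqs
}

# write a reference map back out as FASTA (used by the simulator CLI)
write_fasta <- function(reference, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(reference)) {
    writeLines(paste0(">", id), con)
    s <- reference[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED3+ region file
#'
#' @param path BED file; `track`/`browser`/`#` header lines are skipped.
#' @return A `data.table` of intervals with columns `chrom`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), in file order; extra
#'   columns are ignored.
#' @export
read_bed <- function(path) {
  lines <- read_tsv_lines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(data.table(chrom = character(), start = integer(), end = integer()))
  f <- strsplit(lines, "[\t ]+")
  if (any(lengths(f) < 3L))
    stop("BED row with fewer than 3 columns at line ",
         lineno[which(lengths(f) < 3L)[1L]], call. = FALSE)
  chrom <- vapply(f, `[[`, "", 1L)
  start <- as_int_strict(vapply(f, `[[`, "", 2L))
  end <- as_int_strict(vapply(f, `[[`, "", 3L))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("non-integer BED coordinates at line ", lineno[which(bad)[1L]],
         call. = FALSE)
  if (any(start >= end))
    stop("empty or inverted BED interval (start >= end) at line ",
         lineno[which(start >= end)[1L]], call. = FALSE)
  data.table(chrom = chrom, start = start, end = end)
}

#' Write divergence results as a TSV table
#'
#' One header row plus one row per result; floating-point values are printed
#' with 6 significant digits.  Optional `header` lines are written first as
#' `# `-prefixed comments.
#'
#' @param results a `data.frame` of [summarize_divergence()] rows, or a
#'   stratification report (its rows are used).
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path, header = NULL) {
  if (inherits(results, "strat_report")) results <- results$rows
  cols <- c("context", "n_sites", "p", "robs0", "rran0", "robs1", "rran1",
            "kl0", "kl1", "d0", "d1", "kl_full")
  extra <- setdiff(names(results), cols)
  out <- as.data.frame(results)[, c(intersect(cols, names(results)), extra),
                                drop = FALSE]
  num <- vapply(out, is.numeric, TRUE) & !vapply(out, is.integer, TRUE)
  out[num] <- lapply(out[num], function(x) format(signif(x, 6), trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a beta distribution as TSV
#'
#' Columns: the exact fraction as `"n/d"`, its decimal value, and the mass
#' with 9 significant digits.
#'
#' @param dist a `beta_dist`.
#' @param path output path.
#' @inheritParams write_results_tsv
#' @return `path`, invisibly.
#' @export
export_distribution <- function(dist, path, header = NULL) {
  stopifnot(inherits(dist, "beta_dist"))
  dt <- data.table(beta_fraction = paste(dist$num, dist$den, sep = "/"),
                   beta = dist$beta,
                   mass = format(signif(dist$mass, 9), trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
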
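# strand-aware flanking-sequence context of CpG cytosines.
# A CpG dinucleotide carries one cytosine per strand; the two strands are
# always treated as separate sites, each with its own tetranucleotide
# N5-C-G-N3 read 5'->3' on that strand.  The minus-strand context is the
# reverse complement of the plus-strand window.

# vectorized reverse complement of fixed-width-4 windows
revcomp4 <- function(x) {
  y <- chartr("ACGTN", "TGCAN", x)
  paste0(substr(y, 4L, 4L), substr(y, 3L, 3L), substr(y, 2L, 2L),
         substr(y, 1L, 1L))
}

# vectorized context extraction over one chromosome string.
# Returns NA_character_ for boundary or ambiguous-base windows; stops on a
# strand/coordinate mismatch (no CG at the expected offsets).
contexts_on_chrom <- function(seq, position, strand) {
  L <- nchar(seq)
  n <- length(position)
  out <- rep(NA_character_, n)
  plus <- strand == "+"

  # coordinate sanity: the site must sit on a CpG of the reference
  chk_plus <- plus & (position + 1L <= L)
  mid_plus <- substring(seq, position, position + 1L)
  if (any(plus & (position + 1L > L | (chk_plus & mid_plus != "CG"))))
    stop("strand/coordinate mismatch: no CG at a plus-strand site",
         call. = FALSE)
  minus <- !plus
  chk_minus <- minus & (position - 1L >= 1L) & (position <= L)
  mid_minus <- substring(seq, pmax(position - 1L, 1L), position)
  if (any(minus & (position - 1L < 1L | position > L |
                   (chk_minus & mid_minus != "CG"))))
    stop("strand/coordinate mismatch: no CG at a minus-strand site",
         call. = FALSE)

  ok_p <- plus & position - 1L >= 1L & position + 2L <= L
  if (any(ok_p))
    out[ok_p] <- substring(seq, position[ok_p] - 1L, position[ok_p] + 2L)
  ok_m <- minus & position - 2L >= 1L & position + 1L <= L
  if (any(ok_m))
    out[ok_m] <- revcomp4(substring(seq, position[ok_m] - 2L,
                                    position[ok_m] + 1L))
  out[!is.na(out) & !grepl("^[ACGT]{4}$", out)] <- NA_character_
  out
}

#' Extract the tetranucleotide context of one CpG cytosine
#'
#' For a plus-strand site at 1-based position i (reference has C at i, G at
#' i+1) the context is the reference window `[i-1, i+2]`; for a minus-strand
#' site at position i (reference has G at i, C at i-1 pairing with the
#' minus-strand C) it is the reverse complement of the window `[i-2, i+1]`,
#' so the result always reads N5-C-G-N3 5'->3' on the strand of the site.
#'
#' @param reference named character vector from [read_fasta()].
#' @param chrom sequence id.
#' @param position 1-based coordinate of the strand-cytosine.
#' @param strand `"+"` or `"-"`.
#' @return A 4-base string, or `NA_character_` when the context is
#'   unavailable (flank beyond the sequence boundary, or an ambiguous base in
#'   the window).  A reference without CG at the expected offsets is an
#'   error, not an NA.
#' @export
#' @examples
#' ref <- c(chrT = "TACGGA")
#' extract_context(ref, "chrT", 3L, "+")  # "ACGG"
#' extract_context(ref, "chrT", 4L, "-")  # "CCGT"
extract_context <- function(reference, chrom, position, strand) {
  if (!chrom %in% names(reference))
    stop("chrom '", chrom, "' absent from reference", call. = FALSE)
  stopifnot(strand %in% c("+", "-"))
  contexts_on_chrom(reference[[chrom]], as.integer(position), strand)
}

#' Trinucleotide (N5-C-G) of a tetranucleotide context
#'
#' @param context tetranucleotide context string(s) (vectorized).
#' @return The first three bases.
#' @export
#' @examples
#' trinucleotide_of("ACGG")  # "ACG"
trinucleotide_of <- function(context) {
  stopifnot(all(is.na(context) | nchar(context) == 4L))
  substr(context, 1L, 3L)
}

#' Annotate sites with their tetranucleotide context
#'
#' Pairs every site with its strand-aware N5CGN3 context from the reference.
#' Sites whose context is unavailable (sequence boundary or ambiguous flank)
#' are dropped and counted; input order is preserved.
#'
#' @param sites site table; every chrom must exist in the reference.
#' @param reference named character vector from [read_fasta()].
#' @return The site table with an added `context` column; attribute
#'   `n_dropped` carries the number of excluded sites.
#' @export
annotate_sites <- function(sites, reference) {
  validate_sites(sites)
  if (nrow(sites) == 0L) {
    out <- copy(as.data.table(sites))
    out[, context := character(0)]
    setattr(out, "n_dropped", 0L)
    return(out[])
  }
  missing_chrom <- setdiff(unique(sites$chrom), names(reference))
  if (length(missing_chrom))
    stop("chrom '", missing_chrom[1L], "' absent from reference",
         call. = FALSE)
  dt <- copy(as.data.table(sites))
  dt[, context := contexts_on_chrom(reference[[chrom[1L]]], position, strand),
     by = chrom]
  n_dropped <- sum(is.na(dt$context))
  if (n_dropped > 0L)
    message("annotate_sites: dropped ", n_dropped,
            " site(s) with unavailable context (boundary or ambiguous flank)")
  out <- dt[!is.na(context)]
  setattr(out, "n_dropped", n_dropped)
  out[]
}

#' Enumerate all CpG strand-cytosines of a reference
#'
#' Every plus-strand occurrence of "CG" at positions (i, i+1) yields the two
#' strand-sites (i, +) and (i+1, -).
#'
#' @param reference named character vector from [read_fasta()].
#' @return A `data.table` with columns `chrom`, `position`, `strand`, in
#'   coordinate order with the plus site before the minus site of each CpG.
#' @export
#' @examples
#' enumerate_cpg_sites(c(chrT = "TACGGA"))
enumerate_cpg_sites <- function(reference) {
  out <- lapply(names(reference), function(id) {
    hits <- gregexpr("CG", reference[[id]], fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(NULL)
    starts <- as.integer(hits)
    data.table(chrom = id,
               position = as.integer(rbind(starts, starts + 1L)),
               strand = rep(c("+", "-"), length(starts)))
  })
  out <- rbindlist(out)
  if (!nrow(out))
    return(data.table(chrom = character(), position = integer(),
                      strand = character()))
  out[]
}
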
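# Splice-junction quantification from spliced alignments against the
# full plasmid reference. SAM parsing and CIGAR arithmetic are delegated
# to Rsamtools/GenomicAlignments; this module owns the junction-counting
# rules and the spliced-fraction statistic.
#
# Coordinates in all outputs are 0-based half-open: a junction's intron
# is [donor_end, acceptor_start), where donor_end is the first intronic
# base and acceptor_start is one past the last.

#' Read spliced alignments from a SAM file
#'
#' Loads a plain-text SAM file (headers required), excluding unmapped,
#' secondary, and supplementary records. Aligned reference blocks are
#' derived from the CIGAR: M/=/X consume reference and read, D consumes
#' reference within a block, N splits blocks (a junction gap), I/S
#' consume the read only.
#'
#' @param sam_path Path to a SAM file.
#' @return An object of class `aligned_reads`: a list with `reads` (data
#'   frame of `qname`, `rname`, `start` (0-based), `cigar`, `n_blocks`)
#'   and `blocks` (a list of 1-based IRanges of aligned reference
#'   blocks, parallel to `reads`).
#' @export
read_alignments <- function(sam_path) {
  if (!file.exists(sam_path)) stop("file not found: ", sam_path)
  lines <- readLines(sam_path, warn = FALSE)
  if (!any(startsWith(lines, "@SQ")))
    stop("SAM file has no @SQ header (reference lengths required): ",
         sam_path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body)) {
    cig_field <- vapply(strsplit(body, "\t", fixed = TRUE), function(f) {
      if (length(f) < 11L) NA_character_ else f[6]
    }, "")
    bad <- is.na(cig_field) |
      !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", cig_field)
    if (any(bad))
      stop(sprintf("malformed SAM record or CIGAR (record %d) in %s",
                   which(bad)[1], sam_path))
  }
  bam <- tryCatch(
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("malformed SAM record or CIGAR in ", sam_path,
                             ": ", conditionMessage(e)))
  on.exit(unlink(bam))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags, what = "qname"))
  cig <- GenomicAlignments::cigar(gal)
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    cig, BiocGenerics::start(gal), drop.D.ranges = FALSE)
  reads <- data.frame(
    qname = S4Vectors::mcols(gal)$qname,
    rname = as.character(GenomeInfoDb::seqnames(gal)),
    start = BiocGenerics::start(gal) - 1L,
    cigar = cig,
    n_blocks = S4Vectors::elementNROWS(blocks),
    stringsAsFactors = FALSE)
  structure(list(reads = reads, blocks = as.list(blocks)),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("<aligned_reads> %d mapped primary alignments on %d reference(s)\n",
              nrow(x$reads), length(unique(x$reads$rname))))
  invisible(x)
}

# per-read junction gaps as a data.frame (0-based [donor_end,
# acceptor_start)), with flanking anchor lengths
.read_gaps <- function(ar) {
  idx <- which(ar$reads$n_blocks >= 2L)
  if (length(idx) == 0L) {
    return(data.frame(read = integer(), rname = character(),
                      donor_end = integer(), acceptor_start = integer(),
                      left_anchor = integer(), right_anchor = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(idx, function(i) {
    b <- ar$blocks[[i]]
    k <- length(b)
    data.frame(read = i, rname = ar$reads$rname[i],
               donor_end = BiocGenerics::end(b)[-k],      # 0-based first intronic
               acceptor_start = BiocGenerics::start(b)[-1] - 1L,
               left_anchor = BiocGenerics::width(b)[-k],
               right_anchor = BiocGenerics::width(b)[-1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count splice junctions
#'
#' Each N gap flanked by aligned blocks of at least `min_anchor` bases
#' on both sides contributes one read count to the junction keyed by its
#' exact coordinates. Reads failing the anchor rule are tallied but not
#' counted.
#'
#' @param reads An [read_alignments()] object (or a SAM path).
#' @param min_anchor Minimum aligned bases on each side of the gap
#'   (default 6).
#' @return Data frame of class `junction_counts` with columns `rname`,
#'   `donor_end`, `acceptor_start`, `read_count`, sorted by coordinates;
#'   attribute `n_unanchored` counts gaps that failed the anchor rule.
#' @export
count_junctions <- function(reads, min_anchor = 6L) {
  if (is.character(reads)) reads <- read_alignments(reads)
  stopifnot(inherits(reads, "aligned_reads"), min_anchor >= 1L)
  gaps <- .read_gaps(reads)
  ok <- gaps$left_anchor >= min_anchor & gaps$right_anchor >= min_anchor
  n_unanchored <- sum(!ok)
  gaps <- gaps[ok, , drop = FALSE]
  if (nrow(gaps) == 0L) {
    out <- data.frame(rname = character(), donor_end = integer(),
                      acceptor_start = integer(), read_count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(gaps$rname, gaps$donor_end, gaps$acceptor_start, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(
      rname = vapply(parts, `[`, "", 1L),
      donor_end = as.integer(vapply(parts, `[`, "", 2L)),
      acceptor_start = as.integer(vapply(parts, `[`, "", 3L)),
      read_count = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(out$rname, out$donor_end, out$acceptor_start), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_unanchored") <- n_unanchored
  attr(out, "min_anchor") <- as.integer(min_anchor)
  class(out) <- c("junction_counts", "data.frame")
  out
}

#' Spliced fraction at a junction
#'
#' For a junction with intron `[donor_end, acceptor_start)`, computes
#' J / (J + I) where J is the number of junction-spanning reads (exact
#' gap, anchors of at least `min_anchor` on both sides) and I the number
#' of reads with at least `min_anchor` aligned bases strictly inside the
#' intron and no gap equal to the junction. Returns 0 when J = 0 and
#' I > 0, and `NA` (missing) when no read is informative.
#'
#' @param junction One row of [count_junctions()] output, or a list with
#'   `rname`, `donor_end`, `acceptor_start`.
#' @param reads An [read_alignments()] object.
#' @param min_anchor Anchor rule, applied to both J and I (default 6).
#' @return A proportion in `[0, 1]`, or `NA` if no informative reads.
#' @export
spliced_fraction <- function(junction, reads, min_anchor = 6L) {
  stopifnot(inherits(reads, "aligned_reads"))
  gaps <- .read_gaps(reads)
  anchored <- gaps[gaps$left_anchor >= min_anchor &
                   gaps$right_anchor >= min_anchor, , drop = FALSE]
  d0 <- as.integer(junction$donor_end)
  a0 <- as.integer(junction$acceptor_start)
  rn <- as.character(junction$rname)
  J <- sum(anchored$rname == rn & anchored$donor_end == d0 &
             anchored$acceptor_start == a0)
  # reads carrying this exact junction (any anchor) never count in I
  has_junction <- unique(gaps$read[gaps$rname == rn & gaps$donor_end == d0 &
                                     gaps$acceptor_start == a0])
  intron <- IRanges::IRanges(start = d0 + 1L, end = a0)  # 1-based closed
  idx <- which(reads$reads$rname == rn)
  idx <- setdiff(idx, has_junction)
  I <- 0L
  for (i in idx) {
    ov <- BiocGenerics::intersect(reads$blocks[[i]], intron)
    if (sum(BiocGenerics::width(ov)) >= min_anchor) I <- I + 1L
  }
  if (J + I == 0L) return(NA_real_)
  J / (J + I)
}

#' Quantify splicing across all junctions in a SAM file
#'
#' Combines [count_junctions()] and [spliced_fraction()] into a report:
#' one row per junction with its read count and spliced fraction.
#'
#' @param reads An [read_alignments()] object or a SAM path.
#' @param min_anchor Anchor rule (default 6).
#' @return An object of class `splice_quant` with fields `junctions`
#'   (data frame: `rname`, `donor_end`, `acceptor_start`, `read_count`,
#'   `spliced_fraction`), `params`, and `n_reads`.
#' @export
quantify_splicing <- function(reads, min_anchor = 6L) {
  if (is.character(reads)) reads <- read_alignments(reads)
  jc <- count_junctions(reads, min_anchor)
  sf <- vapply(seq_len(nrow(jc)), function(i) {
    spliced_fraction(jc[i, ], reads, min_anchor)
  }, numeric(1))
  jdf <- as.data.frame(jc)
  jdf$spliced_fraction <- if (nrow(jdf)) sf else numeric(0)
  structure(list(junctions = jdf,
                 params = list(min_anchor = as.integer(min_anchor),
                               junction_tolerance = 0L),
                 n_reads = nrow(reads$reads),
                 n_unanchored = attr(jc, "n_unanchored")),
            class = "splice_quant")
}

#' @export
print.splice_quant <- function(x, ...) {
  cat(sprintf("<splice_quant> %d reads, %d junction(s), min_anchor=%d\n",
              x$n_reads, nrow(x$junctions), x$params$min_anchor))
  if (nrow(x$junctions)) print(x$junctions)
  invisible(x)
}

#' Write a splicing quantification report as TSV
#'
#' @param quant A [quantify_splicing()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_splice_quant <- function(quant, path) {
  stopifnot(inherits(quant, "splice_quant"))
  write_tsv_report(quant$junctions, path,
                   list(min_anchor = quant$params$min_anchor,
                        junction_tolerance = quant$params$junction_tolerance,
                        n_reads = quant$n_reads))
  invisible(path)
}

#' Per-base coverage of aligned blocks
#'
#' Sashimi-style coverage track: depth of aligned (non-gap) bases at
#' each reference position, suitable for plotting next to junction arcs.
#'
#' @param reads An [read_alignments()] object.
#' @param rname Reference name; defaults to the first one present.
#' @return Data frame with 0-based `pos` and `depth`.
#' @export
junction_coverage <- function(reads, rname = NULL) {
  stopifnot(inherits(reads, "aligned_reads"))
  if (is.null(rname)) rname <- reads$reads$rname[1]
  idx <- which(reads$reads$rname == rname)
  if (length(idx) == 0L)
    return(data.frame(pos = integer(), depth = integer()))
  all_blocks <- do.call(c, reads$blocks[idx])
  cov <- IRanges::coverage(all_blocks)
  data.frame(pos = seq_len(length(cov)) - 1L,
             depth = as.integer(cov))
}
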
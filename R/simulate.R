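# Read simulator for a split-reporter plasmid: a reference carrying one
# intron that is spliced out in a known fraction (psi) of transcripts.
# Emits error-free single-end reads as FASTQ plus a matching SAM with
# exact CIGARs, so the junction-quantification module can be validated
# end to end without an external spliced aligner.

#' Build a synthetic split-reporter reference
#'
#' A random reporter sequence in which an intron (with canonical GT...AG
#' termini) splits the coding region, emulating a fluorescent reporter
#' interrupted by a weakly spliced intron. A test element (e.g. a tag
#' encoding) can be inserted inside the intron to assess its splicing
#' potential.
#'
#' @param exon1_len,intron_len,exon2_len Segment lengths in nt.
#' @param insert Optional DNA string placed at the center of the intron.
#' @param seed Integer seed for the random background sequence.
#' @param name Reference name.
#' @return A list with `reference` (a [nuc_sequence()]) and `intron`
#'   (0-based half-open interval `c(start, end)`).
#' @export
make_reporter <- function(exon1_len = 300L, intron_len = 150L,
                          exon2_len = 300L, insert = NULL, seed = 1L,
                          name = "reporter") {
  stopifnot(exon1_len > 0L, exon2_len > 0L, intron_len >= 10L)
  set.seed(seed)
  rnd <- function(k) paste(sample(.BASES, k, replace = TRUE), collapse = "")
  intron_core <- rnd(intron_len - 4L)
  if (!is.null(insert)) {
    insert <- normalize_sequence(insert)
    mid <- nchar(intron_core) %/% 2L
    intron_core <- paste0(substr(intron_core, 1L, mid), insert,
                          substr(intron_core, mid + 1L, nchar(intron_core)))
  }
  intron <- paste0("GT", intron_core, "AG")
  bases <- paste0(rnd(exon1_len), intron, rnd(exon2_len))
  list(reference = nuc_sequence(name, bases),
       intron = c(exon1_len, exon1_len + nchar(intron)))
}

#' Simulate reads from a reporter spliced at a known fraction
#'
#' Each read derives from the spliced transcript (intron removed) with
#' probability `psi` and from the unspliced transcript otherwise. Read
#' starts are uniform over valid positions, or, with
#' `span_junction = TRUE`, constrained so every read overlaps the
#' donor-boundary region with at least `min_anchor` bases on each side
#' (the informative reads for the spliced-fraction statistic; with equal
#' numbers of eligible start positions for both transcript forms, the
#' statistic is an unbiased binomial estimate of `psi`). Reads are
#' error-free by default; `error_rate` introduces uniform substitutions.
#'
#' @param reference A [nuc_sequence()] (e.g. from [make_reporter()]).
#' @param intron 0-based half-open interval `c(start, end)` of the
#'   intron in the reference.
#' @param psi True spliced fraction in `[0, 1]`.
#' @param n_reads Number of reads.
#' @param read_length Read length in nt.
#' @param seed Integer seed.
#' @param out_dir Directory for output files (created if needed).
#' @param span_junction Constrain reads to span the donor boundary.
#' @param min_anchor Anchor margin used when `span_junction = TRUE`.
#' @param error_rate Per-base substitution probability (default 0).
#' @param prefix Basename for the FASTQ/SAM/truth files.
#' @return An object of class `sim_result`: a list with `truth`
#'   (reference name, intron, psi, n_reads, read_length, seed), `reads`
#'   (per-read data frame), and the paths `fastq`, `sam`, `truth_tsv`.
#' @export
simulate_reads <- function(reference, intron, psi, n_reads = 5000L,
                           read_length = 100L, seed = 1L,
                           out_dir = tempfile("simreads"),
                           span_junction = FALSE, min_anchor = 6L,
                           error_rate = 0, prefix = "sim") {
  reference <- as_nuc_sequence(reference)
  L <- nchar(reference$bases)
  stopifnot(length(intron) == 2L, intron[1] >= 0L, intron[2] <= L,
            intron[1] < intron[2])
  stopifnot(psi >= 0, psi <= 1, n_reads >= 1L, read_length >= 2L * min_anchor)
  istart <- as.integer(intron[1]); iend <- as.integer(intron[2])
  ilen <- iend - istart
  spliced_tx <- paste0(substr(reference$bases, 1L, istart),
                       substr(reference$bases, iend + 1L, L))
  unspliced_tx <- reference$bases
  if (read_length > nchar(spliced_tx))
    stop("read_length exceeds the spliced transcript length")
  if (span_junction &&
      (istart < read_length || nchar(spliced_tx) - istart < read_length))
    stop("exons too short for junction-spanning reads of this length")
  set.seed(seed)
  is_spliced <- stats::runif(n_reads) < psi
  if (span_junction) {
    # offset of the boundary inside the read, uniform with >= min_anchor
    # bases on each side; same eligible positions for both forms
    d <- sample(seq.int(min_anchor, read_length - min_anchor), n_reads,
                replace = TRUE)
    start_t <- istart - d  # 0-based start in transcript coords
  } else {
    start_t <- integer(n_reads)
    n_sp <- sum(is_spliced)
    start_t[is_spliced] <- sample.int(nchar(spliced_tx) - read_length + 1L,
                                      n_sp, replace = TRUE) - 1L
    start_t[!is_spliced] <- sample.int(nchar(unspliced_tx) - read_length + 1L,
                                       n_reads - n_sp, replace = TRUE) - 1L
  }
  tx <- ifelse(is_spliced, spliced_tx, unspliced_tx)
  seqs <- substring(tx, start_t + 1L, start_t + read_length)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(ch)) < error_rate
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(.BASES, b), 1L),
                        "")
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  # reference-space alignment
  pos0 <- integer(n_reads)   # 0-based alignment start on the reference
  cig <- character(n_reads)
  for (i in seq_len(n_reads)) {
    st <- start_t[i]
    if (!is_spliced[i]) {
      pos0[i] <- st
      cig[i] <- sprintf("%dM", read_length)
    } else if (st + read_length <= istart) {
      pos0[i] <- st
      cig[i] <- sprintf("%dM", read_length)
    } else if (st >= istart) {
      pos0[i] <- st + ilen
      cig[i] <- sprintf("%dM", read_length)
    } else {
      left <- istart - st
      pos0[i] <- st
      cig[i] <- sprintf("%dM%dN%dM", left, ilen, read_length - left)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fastq <- file.path(out_dir, paste0(prefix, ".fastq"))
  sam <- file.path(out_dir, paste0(prefix, ".sam"))
  truth_tsv <- file.path(out_dir, paste0(prefix, ".truth.tsv"))
  qname <- sprintf("%s_read%06d", prefix, seq_len(n_reads))
  qual <- strrep("I", read_length)
  writeLines(paste0("@", qname, "\n", seqs, "\n+\n", qual), fastq)
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$name, L),
    sprintf("@PG\tID:spliceaudit\tPN:spliceaudit\tVN:%s", .sa_version()),
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            qname, reference$name, pos0 + 1L, cig, seqs, qual))
  writeLines(sam_lines, sam)
  truth <- data.frame(reference = reference$name, intron_start = istart,
                      intron_end = iend, psi = psi, n_reads = n_reads,
                      read_length = read_length, seed = seed,
                      span_junction = span_junction,
                      error_rate = error_rate)
  write_tsv_report(truth, truth_tsv, list(seed = seed))
  structure(list(
    truth = truth,
    reads = data.frame(qname = qname, spliced = is_spliced, pos = pos0,
                       cigar = cig, stringsAsFactors = FALSE),
    fastq = fastq, sam = sam, truth_tsv = truth_tsv), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d reads from %s (psi=%g, seed=%d)\n  SAM: %s\n",
              x$truth$n_reads, x$truth$reference, x$truth$psi, x$truth$seed,
              x$sam))
  invisible(x)
}
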
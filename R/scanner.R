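# Whole-sequence auditing: enumerate candidate splice windows and simple
# hazard motifs. Coordinates are 0-based, half-open, on the forward
# strand of the stored sequence; minus-strand windows are reported with
# the forward interval they occupy. Circular sequences are scanned with
# a virtual extension of width-1 bases across the origin and start
# positions are reported modulo the sequence length (so `end` may exceed
# the length for origin-spanning windows; `end - start` always equals
# the window width).

.default_motifs <- c(KpnI = "GGTACC", NheI = "GCTAGC",
                     polyA_AATAAA = "AATAAA", polyA_ATTAAA = "ATTAAA")

#' Default hazard motif set
#'
#' Restriction sites known to create splice signals in transcribed
#' contexts (KpnI `GGTACC`, which forms a donor site in most contexts;
#' NheI `GCTAGC`, which can supply a 3' AG), plus the two canonical
#' polyadenylation hexamers.
#'
#' @return Named character vector of IUPAC patterns.
#' @export
default_motifs <- function() .default_motifs

# candidate window start positions (1-based, in the possibly extended
# string) for one strand of one kind
.window_candidates <- function(s, L, circular, geom, require_canonical) {
  W <- geom$width
  ext <- if (circular && L > 1L) {
    paste0(s, substr(s, 1L, W - 1L))
  } else s
  if (require_canonical) {
    dinuc <- paste(geom$dinucleotide, collapse = "")
    hits <- gregexpr(dinuc, ext, fixed = TRUE)[[1]]
    hits <- hits[hits > 0L]
    starts <- hits - (geom$obligate[1] - 1L)
  } else {
    starts <- seq_len(max(nchar(ext) - W + 1L, 0L))
  }
  starts <- starts[starts >= 1L & starts + W - 1L <= nchar(ext)]
  if (circular) starts <- starts[starts <= L]
  list(ext = ext, starts = starts)
}

#' Find high-scoring splice windows in a sequence
#'
#' Enumerates candidate donor/acceptor windows on the requested strands,
#' scores them, and returns every window with score at least `tau`.
#' With `require_canonical` (the default) only windows with GT (donor)
#' or AG (acceptor) at the obligate positions are considered, matching
#' how putative sites are reported in practice. Windows containing N are
#' skipped and tallied in the `n_skipped` attribute.
#'
#' @param seq A [nuc_sequence()] (or a plain DNA string).
#' @param model A [load_splice_model()] object.
#' @param tau Score threshold in bits (default 0).
#' @param kinds Subset of `c("donor", "acceptor")`.
#' @param strands Subset of `c("+", "-")`.
#' @param require_canonical Keep only GT/AG-anchored windows.
#' @return A data frame of class `splice_windows` with columns `seq`,
#'   `kind`, `start`, `end`, `strand`, `boundary` (forward-strand
#'   coordinate of the exon|intron or intron|exon junction),
#'   `window_seq`, `score`, sorted by `start` then `kind`.
#' @examples
#' m <- load_splice_model()
#' find_splice_windows("AAACAGGTAAGTAAA", m, kinds = "donor", strands = "+")
#' @export
find_splice_windows <- function(seq, model = load_splice_model(), tau = 0,
                                kinds = c("donor", "acceptor"),
                                strands = c("+", "-"),
                                require_canonical = TRUE) {
  seq <- as_nuc_sequence(seq)
  kinds <- match.arg(kinds, several.ok = TRUE)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  L <- nchar(seq$bases)
  circular <- seq$topology == "circular"
  n_skipped <- 0L
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq$bases else reverse_complement(seq$bases)
    for (kind in kinds) {
      geom <- splice_geometry(kind)
      W <- geom$width
      if (!circular && L < W) next
      cand <- .window_candidates(s, L, circular, geom, require_canonical)
      if (length(cand$starts) == 0L) next
      win <- substring(cand$ext, cand$starts, cand$starts + W - 1L)
      has_n <- grepl("N", win, fixed = TRUE)
      n_skipped <- n_skipped + sum(has_n)
      win <- win[!has_n]
      starts <- cand$starts[!has_n]
      if (length(win) == 0L) next
      score <- .score_codes(.code_matrix(win, W), kind, model)
      keep <- score >= tau
      if (!any(keep)) next
      win <- win[keep]; starts <- starts[keep]; score <- score[keep]
      if (strand == "+") {
        start0 <- starts - 1L
      } else {
        # 0-based start in the reverse-complement view -> forward interval
        r0 <- starts - 1L
        start0 <- if (circular) (L - r0 - W) %% L else L - r0 - W
      }
      boff <- if (strand == "+") geom$boundary_offset else W - geom$boundary_offset
      boundary <- start0 + boff
      if (circular) boundary <- boundary %% L
      rows[[length(rows) + 1L]] <- data.frame(
        seq = seq$name, kind = kind, start = start0, end = start0 + W,
        strand = strand, boundary = boundary, window_seq = win,
        score = score, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(), kind = character(), start = integer(),
               end = integer(), strand = character(), boundary = integer(),
               window_seq = character(), score = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$kind, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("splice_windows", "data.frame")
  out
}

#' Scan a sequence for named IUPAC motifs
#'
#' Matches each pattern (IUPAC ambiguity codes allowed) on the requested
#' strands; minus-strand hits are reported with the forward-strand
#' interval they occupy. Circular topology is honored.
#'
#' @inheritParams find_splice_windows
#' @param motifs Named character vector of IUPAC patterns; defaults to
#'   [default_motifs()].
#' @return Data frame with columns `seq`, `motif_name`, `pattern`,
#'   `start`, `end`, `strand`.
#' @examples
#' scan_motifs("AAGGTACCTT", strands = "+")
#' @export
scan_motifs <- function(seq, motifs = default_motifs(),
                        strands = c("+", "-")) {
  seq <- as_nuc_sequence(seq)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  if (length(motifs) == 0L) {
    return(data.frame(seq = character(), motif_name = character(),
                      pattern = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    stop("motifs must be a named character vector")
  bad <- !vapply(strsplit(toupper(motifs), "", fixed = TRUE),
                 function(ch) all(ch %in% names(Biostrings::IUPAC_CODE_MAP)),
                 logical(1))
  if (any(bad)) stop("invalid IUPAC letter in motif: ", motifs[which(bad)[1]])
  L <- nchar(seq$bases)
  circular <- seq$topology == "circular"
  maxw <- max(nchar(motifs))
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq$bases else reverse_complement(seq$bases)
    ext <- if (circular && L > 1L && maxw > 1L) {
      paste0(s, substr(s, 1L, maxw - 1L))
    } else s
    subject <- Biostrings::DNAString(ext)
    for (i in seq_along(motifs)) {
      w <- nchar(motifs[i])
      if (nchar(ext) < w) next
      m <- Biostrings::matchPattern(toupper(motifs[[i]]), subject,
                                    fixed = FALSE)
      starts <- BiocGenerics::start(m)
      starts <- starts[starts + w - 1L <= nchar(ext)]
      if (circular) starts <- starts[starts <= L]
      if (length(starts) == 0L) next
      start0 <- if (strand == "+") starts - 1L else {
        r0 <- starts - 1L
        if (circular) (L - r0 - w) %% L else L - r0 - w
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq = seq$name, motif_name = names(motifs)[i],
        pattern = toupper(motifs[[i]]), start = as.integer(start0),
        end = as.integer(start0 + w), strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(), motif_name = character(),
               pattern = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif_name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Audit a sequence for splice windows and hazard motifs
#'
#' The first-pass computational screen recommended before synthesizing
#' or transfecting a construct: combines [find_splice_windows()] and
#' [scan_motifs()] into a single report carrying all parameters and the
#' model checksum.
#'
#' @inheritParams find_splice_windows
#' @param motifs Named IUPAC patterns for [scan_motifs()].
#' @return An object of class `audit_report` with fields `seq_name`,
#'   `params`, `windows`, `motifs`, `summary` (window counts per kind
#'   and strand), and `n_skipped`.
#' @export
audit_sequence <- function(seq, model = load_splice_model(), tau = 0,
                           kinds = c("donor", "acceptor"),
                           strands = c("+", "-"), require_canonical = TRUE,
                           motifs = default_motifs()) {
  seq <- as_nuc_sequence(seq)
  windows <- find_splice_windows(seq, model, tau, kinds, strands,
                                 require_canonical)
  hits <- scan_motifs(seq, motifs, strands)
  summary <- as.data.frame(table(
    kind = factor(windows$kind, levels = c("donor", "acceptor")),
    strand = factor(windows$strand, levels = c("+", "-"))),
    stringsAsFactors = FALSE)
  names(summary)[names(summary) == "Freq"] <- "n_windows"
  structure(list(
    seq_name = seq$name,
    params = list(tau = tau, kinds = kinds, strands = strands,
                  topology = seq$topology,
                  require_canonical = require_canonical,
                  model_checksum = model$checksum),
    windows = windows, motifs = hits, summary = summary,
    n_skipped = attr(windows, "n_skipped")), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %s (topology %s, tau=%g)\n", x$seq_name,
              x$params$topology, x$params$tau))
  cat(sprintf("  %d splice window(s) >= tau, %d motif hit(s), %d window(s) skipped for N\n",
              nrow(x$windows), nrow(x$motifs), x$n_skipped))
  if (nrow(x$windows)) print(utils::head(as.data.frame(x$windows), 10))
  invisible(x)
}

#' Write an audit report as TSV
#'
#' Writes the splice-window table (and optionally the motif table) with
#' `#` metadata lines recording the tool version, parameters, and model
#' checksum.
#'
#' @param report An [audit_sequence()] result.
#' @param path Output TSV path for windows.
#' @param motif_path Optional output path for motif hits.
#' @return `path`, invisibly.
#' @export
write_audit <- function(report, path, motif_path = NULL) {
  stopifnot(inherits(report, "audit_report"))
  meta <- list(seq = report$seq_name, tau = report$params$tau,
               strands = report$params$strands,
               topology = report$params$topology,
               require_canonical = report$params$require_canonical,
               model_checksum = report$params$model_checksum,
               n_windows_skipped_for_N = report$n_skipped)
  write_tsv_report(as.data.frame(report$windows), path, meta)
  if (!is.null(motif_path)) {
    write_tsv_report(report$motifs, motif_path, meta)
  }
  invisible(path)
}

#' Export splice windows as BED6
#'
#' BED intervals are 0-based half-open on the forward strand; the name
#' column is the window kind and the score column is the MaxEnt score in
#' bits clamped to the BED range 0-1000.
#'
#' @param windows A `splice_windows` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$seq, start = windows$start,
                    end = windows$end, name = windows$kind,
                    score = pmin(pmax(windows$score, 0), 1000),
                    strand = windows$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
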
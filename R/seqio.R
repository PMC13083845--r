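#' Normalize a raw DNA string
#'
#' Uppercases, converts RNA U to T, strips whitespace and digits (as
#' found in GenBank ORIGIN blocks), and verifies that only the bases
#' A, C, G, T, N remain.
#'
#' @param raw A non-empty character scalar.
#' @return The normalized DNA string.
#' @examples
#' normalize_sequence("acgu")        # "ACGT"
#' normalize_sequence("AC GT\n12")   # "ACGT"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("empty sequence")
  x <- toupper(raw)
  x <- gsub("[[:space:][:digit:]]", "", x)
  x <- chartr("U", "T", x)
  if (!nzchar(x)) stop("empty sequence after normalization")
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    stop(sprintf("invalid base '%s' at position %d",
                 substr(x, bad, bad), bad))
  }
  x
}

#' DNA sequence with name and topology
#'
#' Container for a validated DNA sequence. Plasmids are circular;
#' scanning functions honor the topology by virtually extending the
#' sequence across the origin.
#'
#' @param name Identifier string.
#' @param bases DNA string; normalized via [normalize_sequence()].
#' @param topology `"linear"` (default) or `"circular"`.
#' @return An object of class `nuc_sequence` with fields `name`,
#'   `bases`, and `topology`.
#' @examples
#' p <- nuc_sequence("plasmid", "acgtacgt", topology = "circular")
#' nchar(p$bases)
#' @export
nuc_sequence <- function(name, bases, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, bases = normalize_sequence(bases),
                 topology = topology),
            class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat(sprintf("<nuc_sequence> %s: %d bp, %s\n", x$name, nchar(x$bases),
              x$topology))
  invisible(x)
}

as_nuc_sequence <- function(x, name = "seq") {
  if (inherits(x, "nuc_sequence")) return(x)
  nuc_sequence(name, x)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Peptide sequence
#'
#' A validated one-letter amino-acid string over the 20 standard
#' residues (no stop symbol).
#'
#' @param name Identifier string.
#' @param residues One-letter amino-acid string.
#' @return An object of class `peptide`.
#' @examples
#' peptide("V5", "GKPIPNPLLGLDST")
#' @export
peptide <- function(name, residues) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("empty peptide")
  bad <- regexpr(sprintf("[^%s]", paste(.AA20, collapse = "")), residues)
  if (bad > 0L) {
    stop(sprintf("invalid residue '%s' at position %d",
                 substr(residues, bad, bad), bad))
  }
  structure(list(name = name, residues = residues), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s: %s (%d aa)\n", x$name, x$residues,
              nchar(x$residues)))
  invisible(x)
}

as_peptide <- function(x, name = "peptide") {
  if (inherits(x, "peptide")) return(x)
  peptide(name, x)
}

#' Read DNA sequences from FASTA or GenBank
#'
#' Every record is normalized via [normalize_sequence()]; records with
#' bases outside A, C, G, T, N are rejected. For GenBank input the
#' LOCUS circular/linear flag sets the topology.
#'
#' @param path Input file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return A list of [nuc_sequence()] objects.
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("malformed FASTA in ", path,
                                             ": ", conditionMessage(e)))
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    nm <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i) {
      nuc_sequence(nm[i], as.character(set[[i]]))
    })
  } else {
    read_genbank(path)
  }
}

# Minimal GenBank flat-file reader: LOCUS name/topology plus the ORIGIN
# block. No installed R package parses GenBank, and the scanner only
# needs the sequence and its topology, so the parser is deliberately
# restricted to those fields.
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) stop("malformed GenBank file (no LOCUS): ", path)
  ends <- grep("^//", lines)
  if (length(ends) < length(locus_idx))
    stop("malformed GenBank file (unterminated record): ", path)
  out <- vector("list", length(locus_idx))
  for (i in seq_along(locus_idx)) {
    from <- locus_idx[i]
    to <- ends[ends > from][1]
    rec <- lines[from:to]
    locus <- strsplit(trimws(rec[1]), "[[:space:]]+")[[1]]
    if (length(locus) < 2L) stop("malformed LOCUS line in ", path)
    name <- locus[2]
    topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
    ori <- grep("^ORIGIN", rec)
    if (length(ori) == 0L) stop("malformed GenBank record (no ORIGIN): ", path)
    seq_lines <- rec[(ori[1] + 1L):(length(rec) - 1L)]
    bases <- paste(seq_lines, collapse = "")
    out[[i]] <- nuc_sequence(name, bases, topology)
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs A list of [nuc_sequence()] objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "nuc_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$name), con)
    n <- nchar(s$bases)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$bases, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; N maps to N. Supports scanning the
#' antisense strand of plasmids, where reverse-oriented promoters can
#' drive transcription.
#'
#' @param bases Normalized DNA string.
#' @return The reverse complement.
#' @examples
#' reverse_complement("GGTACC") # palindrome: "GGTACC"
#' reverse_complement("AAGT")   # "ACTT"
#' @export
reverse_complement <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
}

# TSV report writer: '#'-prefixed metadata lines, then a header row and
# tab-separated columns.
write_tsv_report <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(tool = paste0("spliceaudit ", .sa_version())), metadata)
  for (k in names(meta)) {
    writeLines(sprintf("#%s=%s", k, paste(meta[[k]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# read back a TSV report, skipping '#' metadata
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
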
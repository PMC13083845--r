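# Shared fixtures and an independent re-implementation of the scorer.
#
# oracle_score() computes window scores straight from the packaged
# frequency tables with a plain per-position loop (read.delim + log2),
# sharing no code with the package's consensus-odds x table-decomposition
# path. Agreement between the two is a genuine dual-route check.

.fixture_dir <- system.file("extdata", "splice_model_synthetic",
                            package = "spliceaudit")

.oracle_tables <- local({
  bg <- read.delim(file.path(.fixture_dir, "background.tsv"))
  bgd <- setNames(bg$freq, bg$base)
  don <- read.delim(file.path(.fixture_dir, "donor_frequencies.tsv"))
  acc <- read.delim(file.path(.fixture_dir, "acceptor_frequencies.tsv"))
  list(bgd = bgd, donor = don, acceptor = acc)
})

oracle_score <- function(window, kind) {
  tab <- .oracle_tables[[kind]]
  bases <- strsplit(toupper(window), "")[[1]]
  stopifnot(length(bases) == nrow(tab))
  total <- 0
  for (p in seq_along(bases)) {
    f <- tab[p, bases[p]]
    total <- total + log2(f / .oracle_tables$bgd[[bases[p]]])
  }
  total
}

random_windows <- function(n, width, seed) {
  set.seed(seed)
  apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
               ncol = width), 1, paste, collapse = "")
}

random_dna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(records), function(nm) {
    c(paste0(">", nm), records[[nm]])
  }))
  writeLines(lines, path)
  path
}

tmp_genbank <- function(name, bases, circular = FALSE,
                        path = tempfile(fileext = ".gb")) {
  topo <- if (circular) "circular" else "linear"
  body <- paste0("        1 ", tolower(bases))
  writeLines(c(
    sprintf("LOCUS       %s %d bp    DNA     %s   SYN", name, nchar(bases),
            topo),
    "DEFINITION  synthetic construct.",
    "ORIGIN", body, "//"), path)
  path
}

tmp_sam <- function(records, ref = "plas", len = 1000L,
                    path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref, len),
               records), path)
  path
}

sam_record <- function(qname, pos1, cigar, ref = "plas", flag = 0L,
                       seq = "*") {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
          qname, flag, ref, pos1, cigar, seq)
}

# naive forward-strand window enumeration for scanner cross-checks
naive_find_windows <- function(bases, kind, tau) {
  geom <- spliceaudit::splice_geometry(kind)
  W <- geom$width
  dinuc <- paste(geom$dinucleotide, collapse = "")
  out <- data.frame(start = integer(), score = numeric())
  if (nchar(bases) < W) return(out)
  for (s in seq_len(nchar(bases) - W + 1L)) {
    win <- substr(bases, s, s + W - 1L)
    if (substr(win, geom$obligate[1], geom$obligate[2]) != dinuc) next
    sc <- oracle_score(win, kind)
    if (sc >= tau) {
      out <- rbind(out, data.frame(start = s - 1L, score = sc))
    }
  }
  out
}

test_model <- spliceaudit::load_splice_model()
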
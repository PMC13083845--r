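# Maximum-entropy splice-site scoring.
#
# The scorer follows the classic MaxEntScan decomposition: a window's
# score is the log2 of (consensus-position odds at the obligate
# dinucleotide) x (odds of the remaining positions under a
# maximum-entropy table). For donors the remaining 7 positions are
# scored by one 4^7 table; for acceptors the remaining 21 positions are
# scored by the nine-overlapping-subsequence product/quotient:
#   t1(1:7) t2(8:14) t3(15:21) t4(5:11) t5(12:18)
#   / t6(5:7) t7(8:11) t8(12:14) t9(15:18)
# (positions in the 21-mer left after removing the AG). Each of the 21
# positions enters the product net exactly once.
#
# Two model sources are supported: the packaged synthetic first-order
# tables (position frequencies -> independent products; see
# inst/extdata/splice_model_synthetic/README.md) and a directory holding
# the genuine MaxEntScan `me2x5` / `me2x3acc1..9` files.

.ACC_SEGMENTS <- list(1:7, 8:14, 15:21, 5:11, 12:18, 5:7, 8:11, 12:14, 15:18)
.ACC_SEGMENT_SIGN <- c(1, 1, 1, 1, 1, -1, -1, -1, -1)
.DONOR_REST <- c(1:3, 6:9)     # window positions scored by the 7-mer table
.ACC_REST <- c(1:18, 21:23)    # window positions forming the 21-mer

# Reference scorer constants (background composition and obligate-
# dinucleotide consensus frequencies) used when loading a raw
# MaxEntScan-format table directory that carries no frequency files.
.REF_BGD <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
.REF_DONOR_CONS <- rbind(c(A = 0.0040, C = 0.0032, G = 0.9896, T = 0.0032),
                         c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9885))
.REF_ACC_CONS <- rbind(c(A = 0.9903, C = 0.0032, G = 0.0035, T = 0.0030),
                       c(A = 0.0027, C = 0.0037, G = 0.9906, T = 0.0030))

# expand a per-position log2-odds matrix (4 x k) into the 4^k vector of
# position-sum scores, indexed with the first position most significant
# (A=0 C=1 G=2 T=3 digits, matching .table_index)
.expand_order1_msfirst <- function(lo) {
  v <- 0
  for (j in rev(seq_len(ncol(lo)))) v <- as.vector(outer(v, lo[, j], "+"))
  v
}

.read_freq_table <- function(path, width) {
  if (!file.exists(path)) stop("missing model table file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pos", "role", "A", "C", "G", "T")
  if (!all(need %in% names(df)) || nrow(df) != width ||
      !identical(as.integer(df$pos), seq_len(width)))
    stop("corrupt model table (unexpected layout): ", path)
  m <- t(as.matrix(df[, c("A", "C", "G", "T")]))
  if (any(!is.finite(m)) || any(m <= 0))
    stop("corrupt model table (non-positive frequency): ", path)
  sums <- colSums(m)
  if (any(abs(sums - 1) > 0.02))
    stop("corrupt model table (columns do not sum to 1): ", path)
  list(freq = m, role = df$role)
}

.read_maxent_table <- function(path, expect_len) {
  if (!file.exists(path)) stop("missing model table file: ", path)
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != expect_len)
    stop(sprintf("corrupt model table %s: expected %d values, found %d",
                 path, expect_len, length(v)))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("corrupt model table (non-positive odds): ", path)
  v
}

.dir_checksum <- function(files) {
  sums <- tools::md5sum(files)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(basename(names(sums)), unname(sums)), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a splice-site scoring model
#'
#' By default loads the packaged synthetic first-order maximum-entropy
#' model (see the fixture README for its provenance and limitations).
#' If `path` contains the native MaxEntScan files `me2x5` and
#' `me2x3acc1` ... `me2x3acc9`, those published second-order tables are
#' loaded instead and scoring is bit-compatible with the reference
#' `score5`/`score3` scripts.
#'
#' @param path Directory holding model tables; `NULL` for the packaged
#'   synthetic model.
#' @return An immutable object of class `splice_model`. Its `checksum`
#'   field (an md5 over the table files) is recorded in all reports.
#' @export
load_splice_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "splice_model_synthetic",
                        package = "spliceaudit")
  }
  if (!dir.exists(path)) stop("model directory not found: ", path)

  if (file.exists(file.path(path, "me2x5"))) {
    files <- file.path(path, c("me2x5", paste0("me2x3acc", 1:9)))
    me2x5 <- .read_maxent_table(files[1], 4^7)
    acc_lens <- c(4^7, 4^7, 4^7, 4^7, 4^7, 4^3, 4^4, 4^3, 4^4)
    acc <- lapply(seq_len(9), function(k) {
      log2(.read_maxent_table(files[k + 1], acc_lens[k]))
    })
    model <- list(
      type = "maxentscan", source = path, checksum = .dir_checksum(files),
      bgd = .REF_BGD,
      donor = list(cons = .REF_DONOR_CONS, log2_table = log2(me2x5)),
      acceptor = list(cons = .REF_ACC_CONS, log2_tables = acc),
      order1 = NULL)
  } else {
    files <- file.path(path, c("background.tsv", "donor_frequencies.tsv",
                               "acceptor_frequencies.tsv"))
    if (!file.exists(files[1])) stop("missing model table file: ", files[1])
    bg <- utils::read.delim(files[1], stringsAsFactors = FALSE)
    if (!all(c("base", "freq") %in% names(bg)) ||
        !setequal(bg$base, .BASES) || any(bg$freq <= 0))
      stop("corrupt model table: ", files[1])
    bgd <- setNames(bg$freq, bg$base)[.BASES]
    don <- .read_freq_table(files[2], 9L)
    acc <- .read_freq_table(files[3], 23L)
    # full per-position log2-odds, consensus odds folded in
    lo_d <- log2(don$freq / bgd)
    lo_a <- log2(acc$freq / bgd)
    order1 <- list(donor = rbind(lo_d, N = apply(lo_d, 2, max)),
                   acceptor = rbind(lo_a, N = apply(lo_a, 2, max)))
    acc_tables <- lapply(seq_along(.ACC_SEGMENTS), function(k) {
      seg <- .ACC_REST[.ACC_SEGMENTS[[k]]]
      .expand_order1_msfirst(lo_a[, seg, drop = FALSE])
    })
    model <- list(
      type = "order1", source = path, checksum = .dir_checksum(files),
      bgd = bgd,
      donor = list(cons = don$freq[, 4:5, drop = FALSE] |> t(),
                   log2_table = .expand_order1_msfirst(
                     lo_d[, .DONOR_REST, drop = FALSE])),
      acceptor = list(cons = acc$freq[, 19:20, drop = FALSE] |> t(),
                      log2_tables = acc_tables),
      order1 = order1)
  }
  model$cons_log2 <- list(
    donor = rbind(log2(model$donor$cons[1, ] / model$bgd),
                  log2(model$donor$cons[2, ] / model$bgd)),
    acceptor = rbind(log2(model$acceptor$cons[1, ] / model$bgd),
                     log2(model$acceptor$cons[2, ] / model$bgd)))
  structure(model, class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("<splice_model> type=%s checksum=%s\n  source: %s\n",
              x$type, x$checksum, x$source))
  invisible(x)
}

.normalize_windows <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# horner index (first position most significant) from a code matrix
.table_index <- function(codes, positions) {
  idx <- 0L
  for (p in positions) idx <- idx * 4L + (codes[, p] - 1L)
  idx + 1L
}

.score_codes <- function(codes, kind, model) {
  geom <- splice_geometry(kind)
  tabs <- model[[kind]]
  cons <- model$cons_log2[[kind]]
  ob <- geom$obligate
  sc <- cons[1, codes[, ob[1]]] + cons[2, codes[, ob[2]]]
  if (kind == "donor") {
    sc <- sc + tabs$log2_table[.table_index(codes, .DONOR_REST)]
  } else {
    for (k in seq_along(.ACC_SEGMENTS)) {
      pos <- .ACC_REST[.ACC_SEGMENTS[[k]]]
      sc <- sc + .ACC_SEGMENT_SIGN[k] *
        tabs$log2_tables[[k]][.table_index(codes, pos)]
    }
  }
  unname(sc)
}

.score_chr <- function(x, kind, model) {
  geom <- splice_geometry(kind)
  x <- .normalize_windows(x)
  codes <- .code_matrix(x, geom$width)
  if (any(codes == 5L))
    stop("windows may not contain N; expand ambiguity with summarize_ambiguous()")
  .score_codes(codes, kind, model)
}

#' Score 5' (donor) splice-site windows
#'
#' Scores 9-mer windows (3 exonic bases | GT + 4 intronic bases) in
#' log2-odds bits: positive scores indicate resemblance to authentic
#' human donor sites; `>= 0` is the conventional threshold for a
#' putative site. Case and RNA U are normalized first. Windows without
#' GT at positions 4-5 are scoreable (the consensus-odds term penalizes
#' them heavily) but scanners filter them by default.
#'
#' @param window Character vector of 9-mers over A, C, G, T.
#' @param model A [load_splice_model()] object.
#' @return Numeric vector of MaxEnt-style scores in bits.
#' @examples
#' m <- load_splice_model()
#' score_donor("CAGGTAAGT", m) > 0
#' @export
score_donor <- function(window, model = load_splice_model()) {
  .score_chr(window, "donor", model)
}

#' Score 3' (acceptor) splice-site windows
#'
#' Scores 23-mer windows (18 intronic bases | AG | 3 exonic bases) in
#' log2-odds bits via the nine-subsequence product/quotient
#' decomposition. See [score_donor()] for conventions.
#'
#' @inheritParams score_donor
#' @param window Character vector of 23-mers over A, C, G, T.
#' @return Numeric vector of MaxEnt-style scores in bits.
#' @examples
#' m <- load_splice_model()
#' score_acceptor("CTCTCTCTCTCTCTCTCCAGGCT", m)
#' @export
score_acceptor <- function(window, model = load_splice_model()) {
  .score_chr(window, "acceptor", model)
}

#' Score every expansion of an IUPAC-ambiguous window
#'
#' Expands all ambiguity combinations of `pattern` (e.g. `NNGGTACCN`,
#' the KpnI site in arbitrary context), scores each literal window, and
#' summarizes the minimum, maximum, and the fraction of expansions
#' scoring at least `tau`.
#'
#' @param pattern IUPAC DNA string whose length matches the window kind.
#' @param kind `"donor"` or `"acceptor"`.
#' @param tau Threshold in bits (default 0, the conventional cutoff for
#'   a putative site).
#' @param model A [load_splice_model()] object.
#' @param max_expansions Cap on the number of expansions (default 65536).
#' @return An `ambiguous_summary` object with fields `pattern`, `kind`,
#'   `tau`, `n_expansions`, `min_score`, `max_score`, `fraction_ge_tau`,
#'   and the named per-expansion `scores`.
#' @examples
#' m <- load_splice_model()
#' summarize_ambiguous("NNGGTACCN", "donor", tau = 0, model = m)
#' @export
summarize_ambiguous <- function(pattern, kind = c("donor", "acceptor"),
                                tau = 0, model = load_splice_model(),
                                max_expansions = 65536L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  geom <- splice_geometry(kind)
  pattern <- .normalize_windows(pattern)
  if (nchar(pattern) != geom$width)
    stop(sprintf("pattern length %d does not match %s window length %d",
                 nchar(pattern), kind, geom$width))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(Biostrings::IUPAC_CODE_MAP)
  if (any(bad))
    stop("invalid IUPAC letter: ", chars[which(bad)[1]])
  choices <- lapply(chars, function(ch) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "", fixed = TRUE)[[1]]
  })
  n_exp <- prod(lengths(choices))
  if (n_exp > max_expansions)
    stop(sprintf("pattern expands to %.0f windows (cap %d)",
                 n_exp, max_expansions))
  expansions <- ""
  for (ch in choices) {
    expansions <- as.vector(t(outer(expansions, ch, paste0)))
  }
  scores <- .score_codes(.code_matrix(expansions, geom$width), kind, model)
  structure(list(pattern = pattern, kind = kind, tau = tau,
                 n_expansions = as.integer(n_exp),
                 min_score = min(scores), max_score = max(scores),
                 fraction_ge_tau = mean(scores >= tau),
                 scores = setNames(scores, expansions)),
            class = "ambiguous_summary")
}

#' @export
print.ambiguous_summary <- function(x, ...) {
  cat(sprintf(
    "<ambiguous_summary> %s (%s): %d expansions\n  score range [%.2f, %.2f]; fraction >= %.2g bits: %.3f\n",
    x$pattern, x$kind, x$n_expansions, x$min_score, x$max_score, x$tau,
    x$fraction_ge_tau))
  invisible(x)
}
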
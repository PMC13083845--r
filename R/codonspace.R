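# Synonymous codon-space enumeration and splice-risk profiling.
#
# A peptide of length L has prod(degeneracy) synonymous DNA encodings.
# For short tags the space is enumerable exhaustively; for longer ones
# it is sampled by drawing each residue's codon independently and
# uniformly. The risk profile asks, per encoding, for the maximum donor
# and acceptor window score and classifies the encoding as
# splicing-prone when that maximum reaches the threshold (0 bits by
# convention).

#' Standard codon table keyed by residue
#'
#' Built from the standard genetic code; stop codons are excluded and
#' codons are sorted alphabetically per residue (the enumeration order
#' of [generate_encodings()]).
#'
#' @return Named list mapping each of the 20 one-letter residues to its
#'   DNA codons.
#' @examples
#' lengths(codon_table())[c("M", "W", "L", "S")] # 1 1 6 6
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(sort(names(gc)), gc[sort(names(gc))])
}

#' Common epitope tag peptides
#'
#' @return Named character vector of one-letter amino-acid sequences for
#'   FLAG, HA, Myc, V5, and 6xHis.
#' @export
epitope_tags <- function() {
  c(FLAG = "DYKDDDDK", HA = "YPYDVPDYA", Myc = "EQKLISEEDL",
    V5 = "GKPIPNPLLGLDST", His6 = "HHHHHH")
}

#' Widely circulated tag encodings
#'
#' The V5 and HA nucleotide encodings found in common cloning software
#' and repository plasmids. Both are known to carry splice signals: the
#' V5 encoding harbors a strong donor motif (`GGTAAG...`) and the HA
#' encoding a moderate acceptor motif (`...CCAGAT`), which is why they
#' are packaged here as audit examples rather than recommended designs.
#'
#' @return Named character vector of DNA encodings.
#' @export
published_tag_encodings <- function() {
  c(V5 = "GGTAAGCCTATCCCTAACCCTCTCCTCGGTCTCGATTCTACG",
    HA = "TACCCATACGATGTTCCAGATTACGCT")
}

.residue_codons <- function(pep, table) {
  res <- strsplit(pep$residues, "", fixed = TRUE)[[1]]
  bad <- !res %in% names(table)
  if (any(bad)) stop("unknown residue: ", res[which(bad)[1]])
  lapply(res, function(r) table[[r]])
}

#' Count the synonymous encodings of a peptide
#'
#' Product of per-residue codon degeneracies. Counts are exact as long
#' as they stay below 2^53 (double-precision integer range), which
#' covers peptides far beyond the enumerable regime.
#'
#' @param pep A [peptide()] or amino-acid string.
#' @param table A [codon_table()].
#' @return The number of encodings, as a double.
#' @examples
#' count_encodings("HHHHHH")   # 64
#' count_encodings("DYKDDDDK") # 256
#' @export
count_encodings <- function(pep, table = codon_table()) {
  pep <- as_peptide(pep)
  prod(lengths(.residue_codons(pep, table)))
}

#' Generate synonymous encodings
#'
#' Exhaustive mode yields every encoding exactly once, in lexicographic
#' codon order (first residue most significant). Sampled mode draws each
#' residue's codon independently and uniformly; duplicates are retained
#' so that downstream fractions are unbiased Monte-Carlo estimates over
#' the codon space under uniform draws.
#'
#' @param pep A [peptide()] or amino-acid string.
#' @param table A [codon_table()].
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n Number of draws (sampled mode).
#' @param seed Integer seed (required in sampled mode).
#' @param exhaustive_cap Refuse exhaustive enumeration beyond this many
#'   encodings (default 1e6).
#' @return Character vector of DNA encodings.
#' @examples
#' generate_encodings("HH", mode = "exhaustive")
#' @export
generate_encodings <- function(pep, table = codon_table(),
                               mode = c("exhaustive", "sampled"),
                               n = NULL, seed = NULL,
                               exhaustive_cap = 1e6) {
  pep <- as_peptide(pep)
  mode <- match.arg(mode)
  codons <- .residue_codons(pep, table)
  if (mode == "exhaustive") {
    total <- prod(lengths(codons))
    if (total > exhaustive_cap)
      stop(sprintf("peptide has %.3g encodings, above the exhaustive cap %.3g",
                   total, exhaustive_cap))
    enc <- ""
    for (cc in codons) enc <- as.vector(t(outer(enc, cc, paste0)))
    enc
  } else {
    if (is.null(n) || n < 1) stop("sampled mode requires n >= 1")
    if (is.null(seed)) stop("sampled mode requires a seed")
    set.seed(seed)
    cols <- lapply(codons, function(cc) cc[sample.int(length(cc), n,
                                                      replace = TRUE)])
    do.call(paste0, cols)
  }
}

# integer code matrix (n x 3L) of sampled encodings; same draw order as
# generate_encodings(mode = "sampled") under the same seed
.sample_encoding_codes <- function(pep, table, n, seed) {
  codons <- .residue_codons(pep, table)
  set.seed(seed)
  m <- matrix(0L, nrow = n, ncol = 3L * length(codons))
  for (i in seq_along(codons)) {
    cc <- codons[[i]]
    kc <- .code_matrix(cc, 3L)
    draw <- sample.int(length(cc), n, replace = TRUE)
    m[, (3L * i - 2L):(3L * i)] <- kc[draw, , drop = FALSE]
  }
  m
}

# expand_N / fixed_flanks padding amounts: enough context that any
# window whose obligate dinucleotide lies inside the real sequence fits
.flank_pad <- function(geom) {
  c(left = geom$obligate[1] - 1L, right = geom$width - geom$obligate[2])
}

# maximum canonical window score per row of an encoding code matrix.
# flank policy:
#   internal_only - windows fully inside the encoding
#   expand_N      - pad with N and score N positions at their per-position
#                   maximum (worst case over flanking context; exact for
#                   the first-order model, where positions are independent)
#   fixed_flanks  - pad with user-supplied context
.max_window_scores <- function(codes, kind, model,
                               flank_policy = "internal_only",
                               flanks = NULL) {
  geom <- splice_geometry(kind)
  W <- geom$width
  n <- nrow(codes)
  if (flank_policy != "internal_only") {
    pad <- .flank_pad(geom)
    left <- right <- NULL
    if (flank_policy == "expand_N") {
      left <- matrix(5L, n, pad["left"])
      right <- matrix(5L, n, pad["right"])
    } else {
      if (is.null(flanks) || length(flanks) != 2L)
        stop("fixed_flanks requires flanks = c(left, right)")
      lf <- .normalize_windows(flanks[1]); rf <- .normalize_windows(flanks[2])
      if (nchar(lf) < pad["left"] || nchar(rf) < pad["right"])
        stop(sprintf("fixed flanks must provide >= %d left and >= %d right bases",
                     pad["left"], pad["right"]))
      lf <- substr(lf, nchar(lf) - pad["left"] + 1L, nchar(lf))
      rf <- substr(rf, 1L, pad["right"])
      left <- matrix(rep(.base_codes(lf), each = n), n, pad["left"])
      right <- matrix(rep(.base_codes(rf), each = n), n, pad["right"])
    }
    codes <- cbind(left, codes, right)
  }
  m <- ncol(codes)
  if (m < W) return(rep(NA_real_, n))
  use_order1 <- !is.null(model$order1)
  if (!use_order1 && any(codes == 5L))
    stop("expand_N profiling requires a model with per-position tables")
  LO <- if (use_order1) model$order1[[kind]]
  d1 <- match(geom$dinucleotide[1], .BASES)
  d2 <- match(geom$dinucleotide[2], .BASES)
  ob <- geom$obligate
  best <- rep(-Inf, n)
  for (o in seq_len(m - W + 1L)) {
    canonical <- codes[, o + ob[1] - 1L] == d1 & codes[, o + ob[2] - 1L] == d2
    if (!any(canonical)) next
    if (use_order1) {
      sc <- numeric(n)
      for (j in seq_len(W)) sc <- sc + LO[codes[, o + j - 1L], j]
    } else {
      sc <- .score_codes(codes[, o:(o + W - 1L), drop = FALSE], kind, model)
    }
    sc[!canonical] <- -Inf
    best <- pmax(best, sc)
  }
  best[is.infinite(best) & best < 0] <- NA_real_
  best
}

#' Splice-risk profile of a peptide's codon space
#'
#' Generates (or exhaustively enumerates) synonymous encodings of a
#' peptide and, for each encoding, computes the maximum 5' donor score
#' over all canonical GT-anchored windows and the maximum 3' acceptor
#' score over all canonical AG-anchored windows. An encoding is
#' splicing-prone on a side when that maximum reaches `tau`.
#'
#' Window placement is governed by `flank_policy`: `"internal_only"`
#' (default) scores only windows fully inside the encoding, treating the
#' tag as a standalone unit; `"expand_N"` also scores windows whose
#' obligate GT/AG lies inside the encoding but whose flanks extend into
#' unknown context, taking the worst case over that context;
#' `"fixed_flanks"` scores the encoding in a user-supplied context.
#' Encodings too short to host a window of a kind get `NA` for that kind
#' and count as not prone.
#'
#' @inheritParams generate_encodings
#' @param model A [load_splice_model()] object.
#' @param mode `"auto"` (exhaustive when the space has at most
#'   `exhaustive_cap` encodings and `n` is `NULL`, sampled otherwise),
#'   `"exhaustive"`, or `"sampled"`.
#' @param n Number of sampled encodings (default 1e6, the conventional
#'   ensemble size for tag profiling).
#' @param tau Prone threshold in bits (default 0).
#' @param flank_policy `"internal_only"`, `"expand_N"`, or
#'   `"fixed_flanks"`.
#' @param flanks For `"fixed_flanks"`: `c(left, right)` context strings.
#' @param keep_records Also return the per-encoding table (only sensible
#'   for modest `n`).
#' @return A `risk_profile` object with aggregate fields
#'   `prone5_fraction`, `prone3_fraction`, `prone_both_fraction`,
#'   `n_evaluated`, `mode`, `seed`, `tau`, `flank_policy`, and (when
#'   `keep_records`) a `records` data frame of encodings with
#'   `max_donor`/`max_acceptor`.
#' @examples
#' m <- load_splice_model()
#' risk_profile("HHHHHH", m, mode = "exhaustive")$prone5_fraction # 0
#' @export
risk_profile <- function(pep, model = load_splice_model(),
                         table = codon_table(),
                         mode = c("auto", "exhaustive", "sampled"),
                         n = NULL, seed = NULL, tau = 0,
                         flank_policy = c("internal_only", "expand_N",
                                          "fixed_flanks"),
                         flanks = NULL, exhaustive_cap = 1e6,
                         keep_records = FALSE) {
  pep <- as_peptide(pep)
  mode <- match.arg(mode)
  flank_policy <- match.arg(flank_policy)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  total <- count_encodings(pep, table)
  if (mode == "auto") {
    mode <- if (is.null(n) && total <= exhaustive_cap) "exhaustive" else "sampled"
  }
  if (mode == "exhaustive") {
    enc <- generate_encodings(pep, table, "exhaustive",
                              exhaustive_cap = exhaustive_cap)
    codes <- .code_matrix(enc, 3L * nchar(pep$residues))
    seed <- NA_integer_
  } else {
    if (is.null(n)) n <- 1e6
    if (is.null(seed)) stop("sampled mode requires a seed")
    codes <- .sample_encoding_codes(pep, table, n, seed)
    enc <- NULL
  }
  max_donor <- .max_window_scores(codes, "donor", model, flank_policy, flanks)
  max_acceptor <- .max_window_scores(codes, "acceptor", model, flank_policy,
                                     flanks)
  prone5 <- !is.na(max_donor) & max_donor >= tau
  prone3 <- !is.na(max_acceptor) & max_acceptor >= tau
  records <- NULL
  if (keep_records) {
    if (is.null(enc)) {
      chars <- c("A", "C", "G", "T", "N")
      enc <- do.call(paste0, lapply(seq_len(ncol(codes)),
                                    function(j) chars[codes[, j]]))
    }
    records <- data.frame(encoding = enc, max_donor = max_donor,
                          max_acceptor = max_acceptor,
                          stringsAsFactors = FALSE)
  }
  structure(list(
    peptide = pep, n_evaluated = nrow(codes), n_encodings_total = total,
    mode = mode, seed = seed, tau = tau, flank_policy = flank_policy,
    prone5_fraction = mean(prone5), prone3_fraction = mean(prone3),
    prone_both_fraction = mean(prone5 & prone3),
    records = records, model_checksum = model$checksum),
    class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("<risk_profile> %s (%s), %d encodings (%s, tau=%g, %s)\n",
              x$peptide$name, x$peptide$residues, x$n_evaluated, x$mode,
              x$tau, x$flank_policy))
  cat(sprintf("  prone 5': %.4f  prone 3': %.4f  prone both: %.4f\n",
              x$prone5_fraction, x$prone3_fraction, x$prone_both_fraction))
  invisible(x)
}

#' Splicing-prone fraction of Gly-Ser linkers by length
#'
#' For each repeat count, profiles codon-randomized encodings of the
#' repeated linker unit and reports the fraction containing at least one
#' donor window scoring `tau` or more ("splicing-prone"). Gly and Ser
#' codons are rich in GT dinucleotides, so the prone fraction grows with
#' linker length.
#'
#' @inheritParams risk_profile
#' @param unit Peptide repeat unit (default `"GGGGS"`).
#' @param repeats Integer vector of repeat counts.
#' @param n Encodings sampled per length (default 1e6).
#' @param seed Integer seed; each length uses a sub-seed derived from it.
#' @return Data frame with columns `repeats`, `peptide`, `length_nt`,
#'   `n`, `prone5_fraction`.
#' @export
linker_prone_curve <- function(unit = "GGGGS", repeats = 1:6,
                               model = load_splice_model(),
                               table = codon_table(), n = 1e6, seed = NULL,
                               tau = 0, flank_policy = "internal_only") {
  unit <- as_peptide(unit, name = "linker_unit")
  if (is.null(n) || n < 1) stop("n must be >= 1")
  if (is.null(seed)) stop("linker_prone_curve requires a seed")
  stopifnot(all(repeats >= 1))
  out <- lapply(seq_along(repeats), function(i) {
    k <- repeats[i]
    pep <- peptide(sprintf("%sx%d", unit$residues, k),
                   strrep(unit$residues, k))
    rp <- risk_profile(pep, model, table, mode = "sampled", n = n,
                       seed = seed + i, tau = tau,
                       flank_policy = flank_policy)
    data.frame(repeats = k, peptide = pep$residues,
               length_nt = 3L * nchar(pep$residues), n = rp$n_evaluated,
               prone5_fraction = rp$prone5_fraction)
  })
  do.call(rbind, out)
}

#' Translate a DNA encoding with the standard genetic code
#'
#' @param encoding DNA string with length a multiple of 3.
#' @return One-letter amino-acid string (stop codons appear as `*`).
#' @export
translate_encoding <- function(encoding) {
  encoding <- .normalize_windows(encoding)
  if (nchar(encoding) %% 3L != 0L)
    stop("encoding length must be a multiple of 3")
  codons <- substring(encoding, seq(1L, nchar(encoding), 3L),
                      seq(3L, nchar(encoding), 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("encoding contains an untranslatable codon")
  paste(aa, collapse = "")
}
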
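#' Splice window geometry
#'
#' Fixed window layouts used throughout the package. A donor (5' splice
#' site) window is a 9-mer: 3 exonic bases, the obligate GT dinucleotide
#' at positions 4-5, then 4 further intronic bases. An acceptor (3'
#' splice site) window is a 23-mer: 18 intronic bases (branch-distal
#' pyrimidine tract), the obligate AG at positions 19-20, then 3 exonic
#' bases. All positions are 1-based within the window.
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @return A list with elements `kind`, `width`, `obligate` (positions of
#'   the obligate dinucleotide), `dinucleotide` (its canonical bases),
#'   `exon_prefix`/`exon_suffix` (number of exonic bases at each end),
#'   and `boundary_offset` (0-based offset of the exon|intron or
#'   intron|exon junction from the window start on the forward strand).
#' @examples
#' splice_geometry("donor")$width    # 9
#' splice_geometry("acceptor")$width # 23
#' @export
splice_geometry <- function(kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  if (kind == "donor") {
    list(kind = "donor", width = 9L, obligate = c(4L, 5L),
         dinucleotide = c("G", "T"), exon_prefix = 3L, exon_suffix = 0L,
         boundary_offset = 3L)
  } else {
    list(kind = "acceptor", width = 23L, obligate = c(19L, 20L),
         dinucleotide = c("A", "G"), exon_prefix = 0L, exon_suffix = 3L,
         boundary_offset = 20L)
  }
}

.BASES <- c("A", "C", "G", "T")

# map a DNA string (ACGTN) to integer codes A=1 C=2 G=3 T=4 N=5
.base_codes <- function(x) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T,N}")
  codes
}

# matrix of codes for a character vector of equal-length windows
# (rows = windows, cols = positions)
.code_matrix <- function(x, width) {
  n <- length(x)
  flat <- match(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                c("A", "C", "G", "T", "N"))
  if (length(flat) != n * width)
    stop("all windows must have length ", width)
  if (anyNA(flat)) stop("windows contain characters outside {A,C,G,T,N}")
  matrix(flat, nrow = n, ncol = width, byrow = TRUE)
}
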
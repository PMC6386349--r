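#' Scoring scheme for local alignment
#'
#' Defaults mimic blastn's +2/-3 nucleotide scheme with gap open 5 / extend 2
#' and the published Karlin-Altschul parameters for that scheme
#' (lambda = 0.625 nats per score unit, K = 0.41). No claim of bit-exact BLAST
#' parity is made; downstream rules use E-value ratios and thresholds.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0); `N` against anything is a mismatch.
#' @param gap_open,gap_extend affine gap penalties (> 0); a gap of length L
#'   costs `gap_open + gap_extend * L`.
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters (> 0).
#' @return list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, karlin_lambda = 0.625,
                           karlin_K = 0.41) {
  if (!(match > 0 && mismatch < 0)) stop_invalid("need match > 0 > mismatch")
  if (!(gap_open > 0 && gap_extend > 0)) stop_invalid("gap penalties must be > 0")
  if (!(karlin_lambda > 0 && karlin_K > 0)) stop_invalid("Karlin parameters must be > 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_K = karlin_K), class = "scoring_scheme")
}

# {A,C,G,T,N} substitution matrix; N scores as mismatch, including N vs N.
scheme_submat <- function(scheme) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m)[1:4] <- scheme$match
  m["N", "N"] <- scheme$mismatch
  m
}

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || any(!nzchar(x))) stop_invalid(what, " must be nonempty")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop_invalid(what, " contains characters outside {A,C,G,T,N}")
  invisible(x)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman optimal local alignment under affine gaps (via Biostrings).
#' Percent identity is computed over the optimal local alignment's columns,
#' gaps included.
#'
#' @param query,subject nonempty strings over `{A,C,G,T,N}`.
#' @param scheme a [scoring_scheme()].
#' @return list with `raw_score`, `percent_identity`, `aln_length`.
#' @examples
#' align_local("ACGT", "ACGT")  # raw_score 8, identity 100, length 4
#' @export
align_local <- function(query, subject, scheme = scoring_scheme()) {
  check_dna(query, "query"); check_dna(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = scheme_submat(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(raw_score = 0, percent_identity = NA_real_, aln_length = 0L))
  }
  list(raw_score = sc,
       percent_identity = Biostrings::pid(pa, type = "PID1"),
       aln_length = Biostrings::nchar(pa))
}

#' Bit score and E-value
#'
#' `bit = (lambda * S - ln K) / ln 2`; `E = m * n * 2^(-bit)` with search
#' space query length x total database length (no edge-effect correction).
#'
#' @param raw_score raw alignment score.
#' @param scheme a [scoring_scheme()].
#' @return bits (numeric).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$karlin_lambda * raw_score - log(scheme$karlin_K)) / log(2)
}

#' @rdname bit_score
#' @param bits bit score.
#' @param m query length (bases, >= 1).
#' @param n database length (bases, >= 1).
#' @return expected number of chance alignments (numeric >= 0).
#' @examples
#' evalue(20, 100, 1000)  # 1e5 * 2^-20 ~= 0.0954
#' @export
evalue <- function(bits, m, n) {
  if (any(m < 1) || any(n < 1)) stop_invalid("m and n must be >= 1")
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}
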
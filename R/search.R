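BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                "taxon_id", "locus")

#' Search queries against a reference database
#'
#' Aligns every query against every reference sequence (optimal local
#' alignment, no heuristic seeding) and returns a ranked hit table in extended
#' BLAST tabular form. Hits are sorted, per query, by ascending E-value, then
#' descending percent identity, then accession — a total order, so the output
#' is byte-reproducible. Alignments with non-positive raw score yield no hit.
#'
#' @param queries data.frame (query_id, sequence) or named character vector.
#' @param db a `ref_db` (see [generate_reference_db()] /
#'   [read_reference_fasta()]).
#' @param scheme a [scoring_scheme()].
#' @param max_hits hits retained per query.
#' @return data.frame with columns `r BLAST_COLS` (1-based inclusive
#'   coordinates as in the BLAST dialect).
#' @export
search <- function(queries, db, scheme = scoring_scheme(), max_hits = 100L) {
  if (is.character(queries)) {
    queries <- data.frame(query_id = names(queries) %||% paste0("q", seq_along(queries)),
                          sequence = unname(queries), stringsAsFactors = FALSE)
  }
  if (nrow(db$sequences) == 0 || db$total_length == 0) {
    stop_invalid("reference database is empty")
  }
  if (nrow(queries) == 0) return(empty_hits())
  check_dna(queries$sequence, "query")
  check_dna(db$sequences$sequence, "reference")
  submat <- scheme_submat(scheme)
  refs <- Biostrings::DNAStringSet(db$sequences$sequence)
  out <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries$sequence[qi]
    m <- nchar(q)
    pa <- Biostrings::pairwiseAlignment(
      pattern = refs, subject = Biostrings::DNAString(q), type = "local",
      substitutionMatrix = submat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend)
    raw <- Biostrings::score(pa)
    keep <- which(raw > 0)
    if (!length(keep)) { out[[qi]] <- empty_hits(); next }
    bits <- bit_score(raw[keep], scheme)
    ev <- evalue(bits, m, db$total_length)
    indel <- Biostrings::nindel(pa)
    gapopens <- Biostrings::insertion(indel)[keep, "Length"] +
      Biostrings::deletion(indel)[keep, "Length"]
    hit <- data.frame(
      qseqid = queries$query_id[qi],
      sseqid = db$sequences$accession[keep],
      pident = round(Biostrings::pid(pa, type = "PID1")[keep], 3),
      length = Biostrings::nchar(pa)[keep],
      mismatch = Biostrings::nmismatch(pa)[keep],
      gapopen = gapopens,
      qstart = BiocGenerics::start(Biostrings::subject(pa))[keep],
      qend = BiocGenerics::end(Biostrings::subject(pa))[keep],
      sstart = BiocGenerics::start(Biostrings::pattern(pa))[keep],
      send = BiocGenerics::end(Biostrings::pattern(pa))[keep],
      evalue = ev,
      bitscore = round(bits, 2),
      taxon_id = db$sequences$taxon_id[keep],
      locus = db$sequences$locus[keep],
      stringsAsFactors = FALSE
    )
    ord <- order(hit$evalue, -hit$pident, hit$sseqid)
    hit <- hit[ord, , drop = FALSE]
    out[[qi]] <- utils::head(hit, max_hits)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  df <- data.frame(qseqid = character(0), sseqid = character(0),
                   pident = numeric(0), length = integer(0),
                   mismatch = integer(0), gapopen = integer(0),
                   qstart = integer(0), qend = integer(0),
                   sstart = integer(0), send = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   taxon_id = character(0), locus = character(0),
                   stringsAsFactors = FALSE)
  df
}

#' Read / write extended BLAST tabular hit files
#'
#' 12 standard outfmt-6 columns plus `taxon_id` and `locus` extension columns.
#' Files written by external BLAST runs (with the two extension columns
#' appended) are accepted in place of the internal engine's output.
#'
#' @param hits hit table data.frame.
#' @param path file path.
#' @param header logical; internal files carry a header line, raw BLAST
#'   outfmt 6 does not (auto-detected on read).
#' @return the path (write) / hit table (read).
#' @export
write_blast_tab <- function(hits, path, header = TRUE) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' @rdname write_blast_tab
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop_invalid("hit file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("qseqid", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 12) stop_invalid("expected >= 12 BLAST tabular columns, got ", ncol(df))
    names(df)[seq_len(min(ncol(df), 14))] <- BLAST_COLS[seq_len(min(ncol(df), 14))]
    if (ncol(df) == 12) { df$taxon_id <- NA_character_; df$locus <- NA_character_ }
  }
  miss <- setdiff(BLAST_COLS, names(df))
  if (length(miss)) stop_invalid("hit table missing columns: ", paste(miss, collapse = ", "))
  df[, BLAST_COLS]
}

# Re-apply the search module's total order (evalue asc, identity desc,
# accession asc) within each query; external tables may not be sorted.
sort_hits <- function(hits) {
  hits[order(hits$qseqid, hits$evalue, -hits$pident, hits$sseqid), ,
       drop = FALSE]
}
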
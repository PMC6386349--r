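#' Default column map for S1-style sample tables
#'
#' Maps the package's canonical record fields to file column names. Adjust any
#' entry to absorb a differently-labelled table.
#' @return named list canonical -> file column.
#' @export
default_column_map <- function() {
  list(sample_id = "sample_id", region = "country",
       preservation = "preservation",
       species_12s = "best_match_12s", evalue_12s = "evalue_12s",
       pident_12s = "pident_12s",
       species_16s = "best_match_16s", evalue_16s = "evalue_16s",
       pident_16s = "pident_16s")
}

normalize_preservation <- function(x) {
  out <- rep("unknown", length(x))
  lx <- tolower(trimws(ifelse(is.na(x), "", x)))
  out[grepl("rnalater", lx)] <- "RNAlater"
  out[grepl("etoh|ethanol", lx)] <- "ethanol"
  odd <- nzchar(lx) & out == "unknown"
  if (any(odd)) {
    warning("unknown preservation value(s): ",
            paste(unique(x[odd]), collapse = ", "), " -> 'unknown'",
            call. = FALSE)
  }
  out
}

#' Read an S1-style per-sample best-match table
#'
#' One row per leech sample: country, preservation medium, and the best-match
#' species / E-value / percent identity at 12S and 16S. Missing locus cells
#' become `NA`; no rows are silently dropped (the row count is reported).
#'
#' @param path TSV path (spreadsheet-converted tables welcome).
#' @param column_map named list mapping canonical fields to file columns; see
#'   [default_column_map()]. Mapped columns that are genuinely absent from
#'   the study design may be mapped to `NA` to skip them, except `sample_id`.
#' @return data.frame of sample records with canonical column names.
#' @export
read_sample_table <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop_invalid("sample table not found: ", path)
  raw <- read_tsv_plain(path)
  cmap <- utils::modifyList(default_column_map(), as.list(column_map))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(cmap)) {
    col <- cmap[[canon]]
    if (is.null(col) || (length(col) == 1 && is.na(col))) {
      out[[canon]] <- NA
      next
    }
    if (!col %in% names(raw)) {
      stop_invalid("sample table is missing mapped column '", col,
                   "' (for field '", canon, "')")
    }
    out[[canon]] <- raw[[col]]
  }
  for (f in c("evalue_12s", "pident_12s", "evalue_16s", "pident_16s")) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  for (f in c("species_12s", "species_16s")) {
    v <- as.character(out[[f]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    out[[f]] <- v
  }
  out$preservation <- normalize_preservation(out$preservation)
  message(sprintf("read_sample_table: %d rows parsed from %s", nrow(out), path))
  out
}

# A locus identification is "wild" when present, non-anthropogenic and (if
# confirmed = TRUE) high-scoring: E < confirm_evalue and identity >=
# confirm_identity.
locus_is_wild <- function(records, locus = c("12s", "16s"),
                          cfg = rule_config(), confirmed = TRUE) {
  locus <- match.arg(locus)
  spc <- records[[paste0("species_", locus)]]
  ev <- records[[paste0("evalue_", locus)]]
  pid <- records[[paste0("pident_", locus)]]
  ok <- !is.na(spc) & !(spc %in% cfg$exclusion_taxa)
  if (confirmed) {
    ok <- ok & !is.na(ev) & ev < cfg$confirm_evalue &
      !is.na(pid) & pid >= cfg$confirm_identity
  }
  ok
}

#' Taxonomic composition of a survey
#'
#' Proportions of identified samples by taxonomic group at the requested rank,
#' over records with at least one qualifying (wild, optionally confirmed)
#' identification. With `loci = "union"` a sample counts once even when both
#' loci agree; the 12S identification is preferred when both exist.
#'
#' @param records sample records from [read_sample_table()].
#' @param taxonomy a taxonomy resolving the best-match species names.
#' @param region optional region filter.
#' @param rank rank to group at (one of [RANKS]).
#' @param loci `"union"`, `"12s"` or `"16s"`.
#' @param cfg a [rule_config()].
#' @param confirmed require the confirmation thresholds?
#' @return data.frame `group`, `n`, `pct` (percentages sum to 100 up to
#'   rounding), sorted by descending share.
#' @export
composition <- function(records, taxonomy, region = NULL, rank = "order",
                        loci = "union", cfg = rule_config(),
                        confirmed = TRUE) {
  rank_index(rank)  # validates
  if (!is.null(region)) records <- records[records$region %in% region, , drop = FALSE]
  if (!nrow(records)) {
    return(data.frame(group = character(0), n = integer(0), pct = numeric(0)))
  }
  w12 <- if (loci %in% c("union", "12s")) locus_is_wild(records, "12s", cfg, confirmed) else rep(FALSE, nrow(records))
  w16 <- if (loci %in% c("union", "16s")) locus_is_wild(records, "16s", cfg, confirmed) else rep(FALSE, nrow(records))
  spc <- ifelse(w12, records$species_12s,
                ifelse(w16, records$species_16s, NA_character_))
  spc <- spc[!is.na(spc)]
  if (!length(spc)) {
    return(data.frame(group = character(0), n = integer(0), pct = numeric(0)))
  }
  grp <- lineage(taxonomy, spc)[[rank]]
  tab <- sort(table(grp), decreasing = TRUE)
  data.frame(group = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Cross-locus overlap among confirmed 12S identifications
#'
#' @inheritParams composition
#' @return list: `n_12S_confirmed`, `n_both` (wild identification at both
#'   loci), `pct_both` (`NA` when the denominator is zero).
#' @export
locus_overlap <- function(records, cfg = rule_config()) {
  w12 <- locus_is_wild(records, "12s", cfg, confirmed = TRUE)
  w16 <- locus_is_wild(records, "16s", cfg, confirmed = FALSE)
  n12 <- sum(w12)
  nboth <- sum(w12 & w16)
  list(n_12S_confirmed = n12, n_both = nboth,
       pct_both = if (n12 > 0) 100 * nboth / n12 else NA_real_)
}

#' Mean percent identity at a locus
#'
#' Arithmetic mean of the non-missing best-match identities.
#' @inheritParams composition
#' @param locus `"12s"` or `"16s"`.
#' @return numeric (NA when no identities present).
#' @export
mean_identity <- function(records, locus = c("12s", "16s")) {
  locus <- match.arg(locus)
  v <- records[[paste0("pident_", locus)]]
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else mean(v)
}

#' Wild-taxon detection rate
#'
#' Percent of all examined samples (including the ones yielding nothing —
#' hence `n_total` is supplied, not inferred) with at least one wild-taxon
#' identification.
#'
#' @inheritParams composition
#' @param n_total total samples examined (>= number of positives).
#' @param confirmed require confirmation thresholds?
#' @return percentage.
#' @export
detection_rate <- function(records, n_total, cfg = rule_config(),
                           confirmed = FALSE) {
  pos <- locus_is_wild(records, "12s", cfg, confirmed) |
    locus_is_wild(records, "16s", cfg, confirmed)
  npos <- length(unique(records$sample_id[pos]))
  if (n_total < npos) stop_invalid("n_total smaller than number of positive samples")
  if (npos == 0) return(0)
  100 * npos / n_total
}

#' Preservation-medium breakdown
#'
#' Counts of samples by field preservation medium, optionally restricted to
#' samples with wild-taxon identifications.
#'
#' @inheritParams detection_rate
#' @param wild_only restrict to wild-positive samples?
#' @return named integer vector (possibly empty).
#' @export
preservation_breakdown <- function(records, cfg = rule_config(),
                                   wild_only = TRUE, confirmed = FALSE) {
  if (wild_only) {
    pos <- locus_is_wild(records, "12s", cfg, confirmed) |
      locus_is_wild(records, "16s", cfg, confirmed)
    records <- records[pos, , drop = FALSE]
  }
  if (!nrow(records)) return(integer(0))
  tab <- table(records$preservation)
  stats::setNames(as.integer(tab), names(tab))
}
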
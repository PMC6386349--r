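#' Identification rule configuration
#'
#' Thresholds of the identification decision procedure. Defaults: queries are
#' retained only when the best E-value beats 1e-10 and beats the best
#' leech-host match by at least two orders of magnitude; an identification is
#' species-level when the best hit's percent identity beats the taxonomically
#' next-best species by at least 3 percentage points (assumed when the first
#' 100 hits are one species); identifications are "confirmed high-scoring"
#' below E = 1e-20 at >= 90% identity. The anthropogenic exclusion list names
#' humans and the common domestic/commensal taxa.
#'
#' @param retention_evalue retention threshold (strict `<`).
#' @param contamination_ratio orders of magnitude a target hit must beat the
#'   leech-host hit by (inclusive, multiplicative).
#' @param margin_pct identity margin in percentage points (inclusive `>=`).
#' @param shortcut_depth number of leading hits that, if all one species,
#'   short-circuit the margin check.
#' @param confirm_evalue,confirm_identity confirmation thresholds
#'   (strict `<` / inclusive `>=`).
#' @param exclusion_taxa species names excluded as anthropogenic.
#' @param tie_rel_tol optional relative tolerance for E-value tie detection
#'   (default 0 = exact equality as printed/stored).
#' @return list of class `"rule_config"`.
#' @export
rule_config <- function(retention_evalue = 1e-10,
                        contamination_ratio = 2,
                        margin_pct = 3,
                        shortcut_depth = 100L,
                        confirm_evalue = 1e-20,
                        confirm_identity = 90,
                        exclusion_taxa = default_exclusion_taxa(),
                        tie_rel_tol = 0) {
  stopifnot(retention_evalue > 0, contamination_ratio > 0, margin_pct >= 0,
            shortcut_depth >= 1, confirm_evalue > 0, confirm_identity > 0,
            tie_rel_tol >= 0)
  structure(list(retention_evalue = retention_evalue,
                 contamination_ratio = contamination_ratio,
                 margin_pct = margin_pct,
                 shortcut_depth = as.integer(shortcut_depth),
                 confirm_evalue = confirm_evalue,
                 confirm_identity = confirm_identity,
                 exclusion_taxa = exclusion_taxa,
                 tie_rel_tol = tie_rel_tol), class = "rule_config")
}

#' Default anthropogenic exclusion list
#'
#' Binomials for the excluded groups: humans, cattle, water buffalo, pig,
#' chicken and house-rats (the latter expanding to both commensal *Rattus*).
#' @return character vector of species names.
#' @export
default_exclusion_taxa <- function() {
  c("Homo sapiens", "Bos taurus", "Bubalus bubalis", "Sus scrofa",
    "Gallus gallus", "Rattus rattus", "Rattus norvegicus")
}

#' Leech-contamination retention filter
#'
#' A query is retained iff its best target E-value beats the retention
#' threshold (strictly) and, when a leech-host hit exists, is at least
#' `contamination_ratio` orders of magnitude better than the best host
#' E-value (inclusive). A zero target E-value against a nonzero host E-value
#' passes; both zero is indistinguishable and fails.
#'
#' @param best_target_evalue best E-value against non-host references (>= 0).
#' @param best_host_evalue best E-value against the leech-host genome, or
#'   `NULL`/`NA` when there is no host hit.
#' @param cfg a [rule_config()].
#' @return logical: retained?
#' @export
filter_contamination <- function(best_target_evalue, best_host_evalue = NULL,
                                 cfg = rule_config()) {
  if (is.na(best_target_evalue) || best_target_evalue < 0) {
    stop_invalid("E-values must be >= 0")
  }
  if (!is.null(best_host_evalue) && !is.na(best_host_evalue) &&
      best_host_evalue < 0) {
    stop_invalid("E-values must be >= 0")
  }
  if (best_target_evalue >= cfg$retention_evalue) return(FALSE)
  if (is.null(best_host_evalue) || is.na(best_host_evalue)) return(TRUE)
  if (best_target_evalue == 0 && best_host_evalue == 0) return(FALSE)
  # inclusive boundary, guarded against floating-point rounding of 10^-k
  best_target_evalue <= best_host_evalue * 10^(-cfg$contamination_ratio) *
    (1 + 1e-9)
}

assignment_row <- function(query_id, locus = NA_character_,
                           taxon_id = NA_character_,
                           taxon_name = NA_character_, rank = "none",
                           status = "unidentified", best_evalue = NA_real_,
                           best_identity = NA_real_, margin = NA_real_,
                           n_hits = 0L, tie_species = "") {
  data.frame(query_or_sample_id = query_id, locus = locus,
             taxon_id = taxon_id, taxon_name = taxon_name, rank = rank,
             status = status, best_evalue = best_evalue,
             best_identity = best_identity, margin_to_next_taxon = margin,
             n_supporting_hits = n_hits, tie_species = tie_species,
             stringsAsFactors = FALSE)
}

empty_assignments <- function() assignment_row("x")[0, , drop = FALSE]

hit_species <- function(hits, taxonomy) {
  lin <- lineage(taxonomy, hits$taxon_id)
  lin$species
}

#' Identify one query from its ranked hit table
#'
#' The decision procedure: (1) no hits, or best E-value failing the retention
#' threshold, gives `unidentified` / `below_threshold`; (2) if the first
#' `shortcut_depth` hits are all one species, that species is assigned
#' without a margin check; (3) otherwise the best hit is compared with the
#' best hit of a taxonomically different species — an identity lead of at
#' least `margin_pct` points gives a species-level call; (4) otherwise, and
#' whenever several species tie on the best E-value exactly, the call is
#' demoted to the deepest rank shared by all species in the tie/margin set;
#' (5) a set spanning classes yields rank `"none"`.
#'
#' @param hits hit-table rows for one query, sorted by the search module's
#'   total order (E-value asc, identity desc, accession).
#' @param taxonomy a taxonomy resolving every hit's `taxon_id`.
#' @param cfg a [rule_config()].
#' @return one-row assignment data.frame. `taxon_id` is the best hit's
#'   species id; for demoted calls `taxon_name` holds the shared name at the
#'   assigned rank.
#' @export
identify <- function(hits, taxonomy, cfg = rule_config()) {
  qid <- if (nrow(hits)) hits$qseqid[1] else NA_character_
  if (nrow(hits) == 0) return(assignment_row(qid))
  unknown <- !(hits$taxon_id %in% c(taxonomy$taxon_id, taxonomy$species))
  if (any(unknown)) {
    stop_invalid("hit references unknown taxon: ",
                 paste(unique(hits$taxon_id[unknown]), collapse = ", "))
  }
  hits <- hits[order(hits$evalue, -hits$pident, hits$sseqid), , drop = FALSE]
  best <- hits[1, ]
  if (!(best$evalue < cfg$retention_evalue)) {
    return(assignment_row(qid, best$locus, status = "below_threshold",
                          best_evalue = best$evalue,
                          best_identity = best$pident,
                          n_hits = nrow(hits)))
  }
  # Only retained hits count as candidate identifications: a short, chance
  # local alignment with a hopeless E-value is not a "match" in the margin
  # sense, however high its column identity.
  hits <- hits[hits$evalue < cfg$retention_evalue, , drop = FALSE]
  sp <- hit_species(hits, taxonomy)
  best_sp <- sp[1]

  # first-N shortcut: all leading retained hits one species => species-level
  k <- min(cfg$shortcut_depth, nrow(hits))
  if (length(unique(sp[seq_len(k)])) == 1L) {
    nxt <- which(sp != best_sp)
    margin <- if (length(nxt)) best$pident - hits$pident[nxt[1]] else NA_real_
    return(assignment_row(qid, best$locus, best$taxon_id, best_sp,
                          rank = "species", status = "species_level",
                          best_evalue = best$evalue,
                          best_identity = best$pident, margin = margin,
                          n_hits = nrow(hits), tie_species = best_sp))
  }

  # exact E-value tie at the top across species => demote to shared rank
  tied <- if (cfg$tie_rel_tol > 0) {
    abs(hits$evalue - best$evalue) <= cfg$tie_rel_tol * max(best$evalue, .Machine$double.xmin)
  } else hits$evalue == best$evalue
  tie_sp <- unique(sp[tied])
  if (length(tie_sp) > 1L) {
    return(demoted_assignment(qid, best, tie_sp, taxonomy, hits, sp, cfg))
  }

  # one representative hit per species: its best-ranked (E-value order) hit;
  # within-species duplicate accessions are skipped
  rep_idx <- which(!duplicated(sp))
  rep_sp <- sp[rep_idx]
  rep_pident <- hits$pident[rep_idx]

  # margin rule: best hit vs the taxonomically next-best species' hit
  nxt <- which(rep_sp != best_sp)
  if (!length(nxt)) {
    return(assignment_row(qid, best$locus, best$taxon_id, best_sp,
                          rank = "species", status = "species_level",
                          best_evalue = best$evalue,
                          best_identity = best$pident,
                          n_hits = nrow(hits), tie_species = best_sp))
  }
  margin <- best$pident - rep_pident[nxt[1]]
  if (margin >= cfg$margin_pct) {
    return(assignment_row(qid, best$locus, best$taxon_id, best_sp,
                          rank = "species", status = "species_level",
                          best_evalue = best$evalue,
                          best_identity = best$pident, margin = margin,
                          n_hits = nrow(hits), tie_species = best_sp))
  }
  # margin set: species whose representative identity is within margin_pct
  in_set <- unique(c(best_sp,
                     rep_sp[rep_pident > best$pident - cfg$margin_pct]))
  demoted_assignment(qid, best, in_set, taxonomy, hits, sp, cfg, margin)
}

demoted_assignment <- function(qid, best, species_set, taxonomy, hits, sp,
                               cfg, margin = NA_real_) {
  sr <- shared_rank(taxonomy, species_set)
  if (sr$rank == "none") {
    return(assignment_row(qid, best$locus, status = "unidentified",
                          best_evalue = best$evalue,
                          best_identity = best$pident, margin = margin,
                          n_hits = nrow(hits),
                          tie_species = paste(species_set, collapse = ";")))
  }
  status <- if (sr$rank == "species") "species_level" else "rank_demoted"
  assignment_row(qid, best$locus, best$taxon_id, sr$name, rank = sr$rank,
                 status = status, best_evalue = best$evalue,
                 best_identity = best$pident, margin = margin,
                 n_hits = nrow(hits),
                 tie_species = paste(species_set, collapse = ";"))
}

#' Exclude anthropogenic taxa
#'
#' Marks an assignment `excluded_anthropogenic` when the assigned species —
#' or any species in its tie set — is on the exclusion list (humans,
#' domestic animals, commensal rats by default). Otherwise the assignment is
#' returned unchanged.
#'
#' @param assignment one-row assignment data.frame.
#' @param taxonomy a taxonomy.
#' @param cfg a [rule_config()].
#' @return the (possibly updated) assignment.
#' @export
exclude_anthropogenic <- function(assignment, taxonomy, cfg = rule_config()) {
  if (!length(cfg$exclusion_taxa) || is.na(assignment$taxon_id)) return(assignment)
  tie <- strsplit(assignment$tie_species, ";", fixed = TRUE)[[1]]
  cand <- unique(c(assignment$taxon_name, tie))
  cand <- cand[!is.na(cand) & nzchar(cand)]
  if (any(cand %in% cfg$exclusion_taxa)) {
    assignment$status <- "excluded_anthropogenic"
  }
  assignment
}

#' Confirm a high-scoring identification
#'
#' Upgrades a retained, non-excluded identification to
#' `confirmed_high_scoring` when its best E-value beats `confirm_evalue`
#' (strictly) and its best identity is at least `confirm_identity` percent.
#'
#' @inheritParams exclude_anthropogenic
#' @return the (possibly updated) assignment.
#' @export
confirm_high_scoring <- function(assignment, cfg = rule_config()) {
  if (assignment$status %in% c("species_level", "rank_demoted") &&
      !is.na(assignment$best_evalue) &&
      assignment$best_evalue < cfg$confirm_evalue &&
      !is.na(assignment$best_identity) &&
      assignment$best_identity >= cfg$confirm_identity) {
    assignment$status <- "confirmed_high_scoring"
  }
  assignment
}

#' Assign every query in a hit table
#'
#' Runs the full per-query pipeline: split leech-host hits from target hits,
#' apply the contamination/retention filter, identify from the target hits,
#' apply the anthropogenic exclusion, then the high-scoring confirmation.
#'
#' @param hit_table extended BLAST tabular data.frame (possibly many queries).
#' @param taxonomy a taxonomy.
#' @param cfg a [rule_config()].
#' @param host_taxon taxon_id labelling leech-host (contaminant) references.
#' @param query_ids optional full set of query ids, so queries with zero hits
#'   appear as `unidentified` rows.
#' @return assignments data.frame, one row per query.
#' @export
assign_queries <- function(hit_table, taxonomy, cfg = rule_config(),
                           host_taxon = "leech_host", query_ids = NULL) {
  hit_table <- sort_hits(hit_table)
  ids <- query_ids %||% unique(hit_table$qseqid)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    qh <- hit_table[hit_table$qseqid == ids[i], , drop = FALSE]
    host <- qh[qh$taxon_id == host_taxon, , drop = FALSE]
    targ <- qh[qh$taxon_id != host_taxon, , drop = FALSE]
    if (nrow(targ) == 0) {
      out[[i]] <- assignment_row(ids[i],
                                 status = if (nrow(host)) "contaminant" else "unidentified",
                                 n_hits = 0L)
      next
    }
    best_t <- min(targ$evalue)
    best_h <- if (nrow(host)) min(host$evalue) else NULL
    if (!filter_contamination(best_t, best_h, cfg)) {
      status <- if (best_t < cfg$retention_evalue) "contaminant" else "below_threshold"
      out[[i]] <- assignment_row(ids[i], targ$locus[1],
                                 status = status, best_evalue = best_t,
                                 best_identity = max(targ$pident),
                                 n_hits = nrow(targ))
      next
    }
    a <- identify(targ, taxonomy, cfg)
    a <- exclude_anthropogenic(a, taxonomy, cfg)
    a <- confirm_high_scoring(a, cfg)
    out[[i]] <- a
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
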
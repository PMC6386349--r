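assignment_present <- function(a) {
  !is.null(a) && nrow(a) == 1 && !is.na(a$taxon_id) && a$rank != "none" &&
    a$status %in% c("species_level", "rank_demoted", "confirmed_high_scoring")
}

#' Reconcile 12S and 16S assignments for one sample
#'
#' Two loci can confirm each other, one can add data the other lacks, or they
#' can conflict. Compatibility is judged at the shallower of the two assigned
#' ranks; a confirmatory pair resolves at the deeper rank. Conflicts resolve
#' to the assignment with the larger best identity when the identity gap is
#' at least `margin_pct` points (mirroring how civet/mongoose/rodent
#' disagreements are adjudicated by identity), else remain unresolved.
#'
#' @param a12,a16 one-row assignment data.frames, or `NULL` when the locus
#'   yielded nothing.
#' @param taxonomy a taxonomy.
#' @param margin_pct identity gap required to resolve a conflict.
#' @return one-row data.frame: sample_id, status (`confirmatory`,
#'   `additional`, `conflict`, `none`), resolved_taxon, resolved_rank,
#'   resolution_basis.
#' @export
cross_locus <- function(a12 = NULL, a16 = NULL, taxonomy, margin_pct = 3) {
  p12 <- assignment_present(a12)
  p16 <- assignment_present(a16)
  sid <- if (p12) a12$query_or_sample_id else if (p16) a16$query_or_sample_id else NA_character_
  if (p12 && p16 && a12$query_or_sample_id != a16$query_or_sample_id) {
    stop_invalid("cross_locus: assignments reference different samples")
  }
  res <- function(status, taxon = NA_character_, rank = NA_character_, basis = "") {
    data.frame(sample_id = sid, status = status, resolved_taxon = taxon,
               resolved_rank = rank, resolution_basis = basis,
               stringsAsFactors = FALSE)
  }
  if (!p12 && !p16) return(res("none"))
  if (xor(p12, p16)) {
    a <- if (p12) a12 else a16
    return(res("additional", a$taxon_name, a$rank,
               sprintf("single locus (%s)", if (p12) "12S" else "16S")))
  }
  r12 <- rank_index(a12$rank); r16 <- rank_index(a16$rank)
  shallow <- RANKS[max(r12, r16)]
  l12 <- lineage(taxonomy, a12$taxon_id)[[shallow]]
  l16 <- lineage(taxonomy, a16$taxon_id)[[shallow]]
  if (identical(l12, l16)) {
    deep <- if (r12 <= r16) a12 else a16
    return(res("confirmatory", deep$taxon_name, deep$rank,
               sprintf("agree at %s", shallow)))
  }
  gap <- a12$best_identity - a16$best_identity
  if (!is.na(gap) && abs(gap) >= margin_pct) {
    win <- if (gap > 0) a12 else a16
    return(res("conflict", win$taxon_name, win$rank,
               sprintf("identity gap %.1f points favors %s", abs(gap),
                       if (gap > 0) "12S" else "16S")))
  }
  res("conflict", basis = "identity gap below margin; unresolved")
}

#' Flag geographically implausible identifications
#'
#' An assigned species not on the expected-taxon list for the sampling region
#' is flagged (never auto-overridden); the best-ranked hit species that *is*
#' on the list is suggested as an alternative, when one exists. No in-list
#' species among the hits is itself informative — it may indicate a taxon
#' with no reference data at all.
#'
#' @param assignment one-row assignment data.frame (species-level).
#' @param expected_taxa species names plausible for the region (nonempty).
#' @param hits the query's ranked hit table.
#' @param taxonomy a taxonomy.
#' @return the assignment with `implausible` (logical) and
#'   `suggested_alternative` columns added.
#' @export
plausibility_flag <- function(assignment, expected_taxa, hits, taxonomy) {
  if (!length(expected_taxa)) stop_invalid("expected_taxa must be nonempty")
  assignment$implausible <- FALSE
  assignment$suggested_alternative <- NA_character_
  if (is.na(assignment$taxon_id)) return(assignment)
  sp <- lineage(taxonomy, assignment$taxon_id)$species
  if (sp %in% expected_taxa) return(assignment)
  assignment$implausible <- TRUE
  if (nrow(hits)) {
    hits <- hits[order(hits$evalue, -hits$pident, hits$sseqid), , drop = FALSE]
    hsp <- hit_species(hits, taxonomy)
    inlist <- which(hsp %in% expected_taxa)
    if (length(inlist)) assignment$suggested_alternative <- hsp[inlist[1]]
  }
  assignment
}

#' Summarize a hit table into a per-contig candidate table
#'
#' Collapses a multi-contig hit table to one row per contig x species: that
#' species' best hit (search total order) on the contig. Host/contaminant
#' hits are dropped. The result feeds [coverage_aware_consensus()] and
#' [naive_locus_majority()].
#'
#' @param hits extended BLAST tabular data.frame (qseqid = contig id).
#' @param taxonomy a taxonomy.
#' @param host_taxon taxon_id of leech-host references to drop.
#' @return data.frame contig_id, locus, species, evalue, pident.
#' @export
hits_to_contig_table <- function(hits, taxonomy, host_taxon = "leech_host") {
  hits <- hits[hits$taxon_id != host_taxon, , drop = FALSE]
  hits <- sort_hits(hits)
  sp <- hit_species(hits, taxonomy)
  key <- paste(hits$qseqid, sp, sep = "\r")
  first <- !duplicated(key)
  data.frame(contig_id = hits$qseqid[first], locus = hits$locus[first],
             species = sp[first], evalue = hits$evalue[first],
             pident = hits$pident[first], stringsAsFactors = FALSE,
             row.names = NULL)
}

# Per-contig winner and per-candidate per-locus best identity/order.
contig_winners <- function(contig_table) {
  winners <- character(0)
  for (cid in unique(contig_table$contig_id)) {
    ct <- contig_table[contig_table$contig_id == cid, , drop = FALSE]
    ct <- ct[order(ct$evalue, -ct$pident, ct$species), , drop = FALSE]
    winners[cid] <- ct$species[1]
  }
  winners
}

#' Reference-coverage-aware consensus over a pool's contigs
#'
#' Multi-locus shotgun contigs from one pooled bloodmeal can split their best
#' matches between two taxa purely because the reference database lacks some
#' loci for the true host: loci present for the true taxon match it strongly,
#' and loci absent for it match a database-complete relative instead.
#' Candidate A *explains* candidate B when every locus at which B outranked A
#' is a locus the database lacks for A, and at every locus where both are
#' covered A's best identity is at least B's. A unique candidate explaining
#' all others wins; otherwise candidates are partitioned into connected
#' components (edge = the two candidates compete on a shared contig) and each
#' component is resolved independently — a pool genuinely containing two prey
#' taxa with disjoint loci then yields one winner per component.
#'
#' @param contig_table data.frame with one row per contig x candidate-species
#'   hit: `contig_id`, `locus`, `species`, `evalue`, `pident` (best hit of
#'   that species on that contig).
#' @param db a `ref_db` whose coverage matrix is consulted.
#' @param taxonomy a taxonomy (species names resolved against it).
#' @param margin_pct unused by the core rule; kept for interface parity.
#' @param pool_id label for reporting.
#' @return list of class `"consensus_result"`: `pool_id`, `candidates`
#'   (summary data.frame), `winner` (character vector, length >= 1 when
#'   resolved), `explained` (named logical per non-winner), `verdict`
#'   (`"resolved"` or `"ambiguous"`).
#' @export
coverage_aware_consensus <- function(contig_table, db, taxonomy,
                                     margin_pct = 3, pool_id = "pool1") {
  stopifnot(nrow(contig_table) >= 1)
  bad_loci <- setdiff(unique(contig_table$locus), db$loci)
  if (length(bad_loci)) {
    stop_invalid("contig locus absent from reference database: ",
                 paste(bad_loci, collapse = ", "))
  }
  winners <- contig_winners(contig_table)
  candidates <- unique(winners)

  cov_for <- function(sp, locus) {
    tid <- taxonomy$taxon_id[match(sp, taxonomy$species)]
    if (is.na(tid) || !tid %in% rownames(db$coverage)) return(FALSE)
    db$coverage[tid, locus]
  }
  # rank of species on a contig: 1 = best; Inf if absent
  contig_rank <- function(cid, sp) {
    ct <- contig_table[contig_table$contig_id == cid, , drop = FALSE]
    ct <- ct[order(ct$evalue, -ct$pident, ct$species), , drop = FALSE]
    r <- match(sp, ct$species)
    if (is.na(r)) Inf else r
  }
  best_ident <- function(sp, locus) {
    v <- contig_table$pident[contig_table$species == sp &
                               contig_table$locus == locus]
    if (length(v)) max(v) else NA_real_
  }

  explains <- function(a, b) {
    cids <- unique(contig_table$contig_id)
    for (cid in cids) {
      la <- contig_table$locus[contig_table$contig_id == cid][1]
      ra <- contig_rank(cid, a); rb <- contig_rank(cid, b)
      if (rb < ra) {               # b outranked a on this contig
        if (cov_for(a, la)) return(FALSE)
      }
    }
    for (l in unique(contig_table$locus)) {
      if (cov_for(a, l) && cov_for(b, l)) {
        ia <- best_ident(a, l); ib <- best_ident(b, l)
        if (!is.na(ia) && !is.na(ib) && ia < ib) return(FALSE)
      }
    }
    TRUE
  }

  resolve_set <- function(cands) {
    if (length(cands) == 1L) return(cands)
    winners_here <- character(0)
    for (a in cands) {
      if (all(vapply(setdiff(cands, a), function(b) explains(a, b), TRUE))) {
        winners_here <- c(winners_here, a)
      }
    }
    if (length(winners_here) == 1L) winners_here else NULL
  }

  explained_map <- list()
  win <- resolve_set(candidates)
  verdict <- "resolved"
  if (is.null(win)) {
    # partition candidates: edge when two candidates meet on a shared contig
    adj <- matrix(FALSE, length(candidates), length(candidates),
                  dimnames = list(candidates, candidates))
    for (cid in unique(contig_table$contig_id)) {
      sp_here <- intersect(candidates,
                           contig_table$species[contig_table$contig_id == cid])
      if (length(sp_here) > 1) adj[sp_here, sp_here] <- TRUE
    }
    comp <- rep(NA_integer_, length(candidates)); names(comp) <- candidates
    cn <- 0L
    for (c0 in candidates) {
      if (!is.na(comp[c0])) next
      cn <- cn + 1L
      queue <- c0
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[cur])) next
        comp[cur] <- cn
        queue <- c(queue, candidates[adj[cur, ] & is.na(comp)])
      }
    }
    win <- character(0)
    for (g in seq_len(cn)) {
      w <- resolve_set(candidates[comp == g])
      if (is.null(w)) { win <- NULL; break }
      win <- c(win, w)
    }
    verdict <- if (is.null(win) || !length(win)) "ambiguous" else "resolved"
    if (verdict == "ambiguous") win <- NULL
  }
  if (!is.null(win)) {
    for (b in setdiff(candidates, win)) {
      explained_map[[b]] <- any(vapply(win, function(a) explains(a, b), TRUE))
    }
  }
  cand_df <- do.call(rbind, lapply(candidates, function(spc) {
    won <- names(winners)[winners == spc]
    loci_won <- unique(contig_table$locus[contig_table$contig_id %in% won &
                                            contig_table$species == spc])
    data.frame(species = spc, n_contigs_won = length(won),
               loci_won = paste(sort(loci_won), collapse = ","),
               mean_identity = mean(contig_table$pident[
                 contig_table$species == spc]),
               stringsAsFactors = FALSE)
  }))
  structure(list(pool_id = pool_id, candidates = cand_df, winner = win,
                 explained = unlist(explained_map) %||% logical(0),
                 verdict = verdict),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("pool %s: %s\n", x$pool_id, x$verdict))
  if (!is.null(x$winner)) cat("  winner:", paste(x$winner, collapse = ", "), "\n")
  print(x$candidates)
  invisible(x)
}

#' Naive per-locus majority assignment (for comparison)
#'
#' Assigns the pool to the species winning the most contigs — the uncritical
#' reading the coverage-aware consensus exists to correct. Ties break by mean
#' identity, then name.
#'
#' @inheritParams coverage_aware_consensus
#' @return a species name.
#' @export
naive_locus_majority <- function(contig_table) {
  winners <- contig_winners(contig_table)
  tab <- table(winners)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  mi <- vapply(top, function(spc)
    mean(contig_table$pident[contig_table$species == spc]), 0)
  top[order(-mi, top)][1]
}

#' Human-readable evidence trail for a pool consensus
#' @param x a `consensus_result`.
#' @return character vector of report lines.
#' @export
consensus_report <- function(x) {
  lines <- c(sprintf("Pool %s — verdict: %s", x$pool_id, x$verdict))
  if (!is.null(x$winner)) {
    lines <- c(lines, sprintf("Winner(s): %s", paste(x$winner, collapse = ", ")))
  }
  for (i in seq_len(nrow(x$candidates))) {
    cd <- x$candidates[i, ]
    expl <- if (cd$species %in% names(x$explained)) {
      if (x$explained[[cd$species]])
        " [wins explained by reference-database gaps of the winner]" else
          " [wins NOT explained by coverage gaps]"
    } else ""
    lines <- c(lines, sprintf(
      "  %s: won %d contig(s) at loci {%s}, mean identity %.1f%%%s",
      cd$species, cd$n_contigs_won, cd$loci_won, cd$mean_identity, expl))
  }
  lines
}
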
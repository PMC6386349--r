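tx <- tiny_taxonomy()

test_that("cross_locus: confirmatory, additional, none", {
  # 12S at genus level, 16S at species level in the same genus ->
  # confirmatory, resolved at the deeper (species) rank
  a12 <- make_assignment(taxon_id = "A1", taxon_name = "Gena",
                         rank = "genus", status = "rank_demoted")
  a16 <- make_assignment(taxon_id = "A2", taxon_name = "Gena beta",
                         locus = "16S")
  r <- cross_locus(a12, a16, tx)
  expect_equal(r$status, "confirmatory")
  expect_equal(r$resolved_taxon, "Gena beta")
  expect_equal(r$resolved_rank, "species")

  r2 <- cross_locus(a12, NULL, tx)
  expect_equal(r2$status, "additional")
  expect_equal(r2$resolved_taxon, "Gena")

  expect_equal(cross_locus(NULL, NULL, tx)$status, "none")

  a16b <- make_assignment(sid = "other", taxon_id = "A2",
                          taxon_name = "Gena beta")
  expect_error(cross_locus(a12, a16b, tx), "different samples")
})

test_that("cross_locus: conflicts resolve by identity gap", {
  # civet-style case: 12S species X at 100%, 16S species Y at 92% ->
  # conflict resolved to the 12S identification
  a12 <- make_assignment(taxon_id = "A1", taxon_name = "Gena alpha", pid = 100)
  a16 <- make_assignment(taxon_id = "C", taxon_name = "Genc delta",
                         pid = 92, locus = "16S")
  r <- cross_locus(a12, a16, tx)
  expect_equal(r$status, "conflict")
  expect_equal(r$resolved_taxon, "Gena alpha")

  # gap below the margin stays unresolved
  a16c <- make_assignment(taxon_id = "C", taxon_name = "Genc delta",
                          pid = 98.5, locus = "16S")
  r2 <- cross_locus(a12, a16c, tx)
  expect_equal(r2$status, "conflict")
  expect_true(is.na(r2$resolved_taxon))
})

test_that("cross_locus is symmetric up to locus labels", {
  a12 <- make_assignment(taxon_id = "A1", taxon_name = "Gena alpha", pid = 100)
  a16 <- make_assignment(taxon_id = "C", taxon_name = "Genc delta", pid = 90,
                         locus = "16S")
  r <- cross_locus(a12, a16, tx)
  rs <- cross_locus(a16, a12, tx)
  expect_equal(r$status, rs$status)
  expect_equal(r$resolved_taxon, rs$resolved_taxon)
})

test_that("plausibility flags and suggested alternatives", {
  # mouse-deer case: assigned species absent from the regional list while a
  # listed congener is among the hits
  a <- make_assignment(taxon_id = "TJ", taxon_name = "Tragulus javanicus",
                       pid = 98)
  hits <- make_hits(make_hit(acc = "r1", taxon = "TJ", ev = 1e-60, pid = 98),
                    make_hit(acc = "r2", taxon = "TK", ev = 1e-50, pid = 95))
  expected <- c("Tragulus kanchil", "Gena alpha")
  f <- plausibility_flag(a, expected, hits, tx)
  expect_true(f$implausible)
  expect_equal(f$suggested_alternative, "Tragulus kanchil")
  expect_equal(f$taxon_name, a$taxon_name)  # never auto-overridden

  a2 <- make_assignment(taxon_id = "TK", taxon_name = "Tragulus kanchil")
  expect_false(plausibility_flag(a2, expected, hits, tx)$implausible)

  # no listed species among hits: flagged, alternative null — possibly a
  # taxon with no reference data at all
  f3 <- plausibility_flag(a, "Gend epsilon",
                          hits[hits$taxon_id == "TJ", ], tx)
  expect_true(f3$implausible)
  expect_true(is.na(f3$suggested_alternative))

  expect_error(plausibility_flag(a, character(0), hits, tx), "nonempty")
})

galidia_contigs <- function() {
  # A wins its three covered loci at 98-99%; B wins the four loci absent for
  # A at 91-92%; B is also hit (worse) on A's loci.
  rbind(
    data.frame(contig_id = "c1", locus = "cox1", species = "Gena alpha",
               evalue = 1e-80, pident = 98.5),
    data.frame(contig_id = "c1", locus = "cox1", species = "Gena beta",
               evalue = 1e-40, pident = 91.0),
    data.frame(contig_id = "c2", locus = "nd2", species = "Gena alpha",
               evalue = 1e-75, pident = 99.0),
    data.frame(contig_id = "c2", locus = "nd2", species = "Gena beta",
               evalue = 1e-42, pident = 90.5),
    data.frame(contig_id = "c3", locus = "cytb", species = "Gena alpha",
               evalue = 1e-70, pident = 98.0),
    data.frame(contig_id = "c3", locus = "cytb", species = "Gena beta",
               evalue = 1e-39, pident = 91.2),
    data.frame(contig_id = "c4", locus = "nd5", species = "Gena beta",
               evalue = 1e-45, pident = 91.8),
    data.frame(contig_id = "c5", locus = "nd4", species = "Gena beta",
               evalue = 1e-44, pident = 91.1),
    data.frame(contig_id = "c6", locus = "12S", species = "Gena beta",
               evalue = 1e-46, pident = 92.0),
    data.frame(contig_id = "c7", locus = "nd1", species = "Gena beta",
               evalue = 1e-41, pident = 91.4)
  )
}

galidia_db <- function() {
  loci <- c("cox1", "nd2", "cytb", "nd5", "nd4", "12S", "nd1")
  cov <- matrix(TRUE, 8, 7, dimnames = list(tx$taxon_id, loci))
  cov["A1", c("nd5", "nd4", "12S", "nd1")] <- FALSE
  make_refdb(cov)
}

test_that("coverage-aware consensus resolves the database-gap fixture", {
  res <- coverage_aware_consensus(galidia_contigs(), galidia_db(), tx)
  expect_equal(res$verdict, "resolved")
  expect_equal(res$winner, "Gena alpha")
  expect_true(res$explained[["Gena beta"]])
  # the naive majority falls for the database artifact
  expect_equal(naive_locus_majority(galidia_contigs()), "Gena beta")
  # report names the winner and the coverage explanation
  rep <- consensus_report(res)
  expect_true(any(grepl("Gena alpha", rep)))
  expect_true(any(grepl("explained by reference-database gaps", rep)))
})

test_that("consensus: ambiguity, single candidate, coverage errors", {
  # both candidates win one locus each with full coverage -> ambiguous
  ct <- rbind(
    data.frame(contig_id = "c1", locus = "cox1", species = "Gena alpha",
               evalue = 1e-80, pident = 98),
    data.frame(contig_id = "c1", locus = "cox1", species = "Gena beta",
               evalue = 1e-40, pident = 92),
    data.frame(contig_id = "c2", locus = "nd2", species = "Gena beta",
               evalue = 1e-70, pident = 97),
    data.frame(contig_id = "c2", locus = "nd2", species = "Gena alpha",
               evalue = 1e-35, pident = 91))
  cov <- matrix(TRUE, 8, 2, dimnames = list(tx$taxon_id, c("cox1", "nd2")))
  res <- coverage_aware_consensus(ct, make_refdb(cov), tx)
  expect_equal(res$verdict, "ambiguous")
  expect_null(res$winner)

  single <- ct[1, ]
  res1 <- coverage_aware_consensus(single, make_refdb(cov), tx)
  expect_equal(res1$verdict, "resolved")
  expect_equal(res1$winner, "Gena alpha")

  bad <- ct; bad$locus[1] <- "nd9"
  expect_error(coverage_aware_consensus(bad, make_refdb(cov), tx),
               "absent from reference database")
})

test_that("consensus partitions cleanly disjoint two-prey pools", {
  # tenrec+mongoose style pool: two taxa from different orders win disjoint
  # loci and never compete on a contig
  ct <- rbind(
    data.frame(contig_id = "c1", locus = "cox1", species = "Genc delta",
               evalue = 1e-90, pident = 99),
    data.frame(contig_id = "c2", locus = "nd2", species = "Gena alpha",
               evalue = 1e-80, pident = 98),
    data.frame(contig_id = "c3", locus = "cytb", species = "Gena alpha",
               evalue = 1e-75, pident = 98.5))
  loci <- c("cox1", "nd2", "cytb")
  cov <- matrix(TRUE, 8, 3, dimnames = list(tx$taxon_id, loci))
  res <- coverage_aware_consensus(ct, make_refdb(cov), tx)
  expect_equal(res$verdict, "resolved")
  expect_setequal(res$winner, c("Gena alpha", "Genc delta"))
})

test_that("complete coverage never contradicts the plain winner", {
  ct <- galidia_contigs()
  loci <- unique(ct$locus)
  cov <- matrix(TRUE, 8, length(loci), dimnames = list(tx$taxon_id, loci))
  res <- coverage_aware_consensus(ct, make_refdb(cov), tx)
  # with full coverage B's wins are real evidence: no unique explainer exists
  # unless it is also the majority winner
  if (res$verdict == "resolved") {
    expect_equal(res$winner, naive_locus_majority(ct))
  } else {
    expect_null(res$winner)
  }
})

test_that("hits_to_contig_table collapses per contig and species", {
  hits <- rbind(make_hit(qid = "c1", acc = "r1", taxon = "A1", ev = 1e-50,
                         pid = 99),
                make_hit(qid = "c1", acc = "r2", taxon = "A1", ev = 1e-45,
                         pid = 98),
                make_hit(qid = "c1", acc = "r3", taxon = "B", ev = 1e-30,
                         pid = 93),
                make_hit(qid = "c1", acc = "h", taxon = "leech_host",
                         ev = 1e-60, pid = 100, locus = "genome"))
  ct <- hits_to_contig_table(hits, tx)
  expect_equal(nrow(ct), 2L)
  expect_setequal(ct$species, c("Gena alpha", "Genb gamma"))
  expect_equal(ct$evalue[ct$species == "Gena alpha"], 1e-50)
})
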
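cfg <- rule_config()
tx <- tiny_taxonomy()

test_that("contamination filter truth table", {
  # target two orders of magnitude better than host -> retained
  expect_true(filter_contamination(1e-15, 1e-12, cfg))
  # only one order better -> rejected
  expect_false(filter_contamination(1e-12, 1e-11, cfg))
  # no host hit but fails the 1e-10 retention threshold -> rejected
  expect_false(filter_contamination(1e-9, NULL, cfg))

  # boundary: exactly two orders of magnitude is inclusive
  expect_true(filter_contamination(1e-13, 1e-11, cfg))
  # retention threshold is strict
  expect_false(filter_contamination(1e-10, NULL, cfg))
  expect_true(filter_contamination(9.9e-11, NULL, cfg))
  # zero E-values: zero vs nonzero passes, both zero indistinguishable
  expect_true(filter_contamination(0, 1e-50, cfg))
  expect_false(filter_contamination(0, 0, cfg))
  expect_error(filter_contamination(-1, NULL, cfg), ">= 0")
})

test_that("identify: margin rule grants and refuses species rank", {
  # best 99% vs different-family species at 95% -> species level, margin 4
  h <- make_hits(make_hit(taxon = "A1", ev = 1e-50, pid = 99),
                 make_hit(acc = "r2", taxon = "B", ev = 1e-40, pid = 95))
  a <- identify(h, tx, cfg)
  expect_equal(a$status, "species_level")
  expect_equal(a$rank, "species")
  expect_equal(a$taxon_name, "Gena alpha")
  expect_equal(a$margin_to_next_taxon, 4)

  # congeneric runner-up inside the margin -> demoted to genus
  h2 <- make_hits(make_hit(taxon = "A1", ev = 1e-50, pid = 99),
                  make_hit(acc = "r2", taxon = "A2", ev = 1e-45, pid = 97.5))
  a2 <- identify(h2, tx, cfg)
  expect_equal(a2$status, "rank_demoted")
  expect_equal(a2$rank, "genus")
  expect_equal(a2$taxon_name, "Gena")

  # margin exactly 3 points is inclusive -> species level
  h3 <- make_hits(make_hit(taxon = "A1", ev = 1e-50, pid = 99),
                  make_hit(acc = "r2", taxon = "A2", ev = 1e-45, pid = 96))
  expect_equal(identify(h3, tx, cfg)$status, "species_level")
})

test_that("identify: exact E-value ties demote to the discernible rank", {
  h <- make_hits(make_hit(acc = "r1", taxon = "A1", ev = 1e-60, pid = 99),
                 make_hit(acc = "r2", taxon = "A2", ev = 1e-60, pid = 99))
  a <- identify(h, tx, cfg)
  expect_equal(a$rank, "genus")
  expect_equal(a$taxon_name, "Gena")

  # tie across genera of one family -> family; across classes -> unidentified
  h2 <- make_hits(make_hit(acc = "r1", taxon = "A1", ev = 1e-60, pid = 99),
                  make_hit(acc = "r2", taxon = "B", ev = 1e-60, pid = 99))
  expect_equal(identify(h2, tx, cfg)$rank, "family")
  h2b <- make_hits(make_hit(acc = "r1", taxon = "A1", ev = 1e-60, pid = 99),
                   make_hit(acc = "r2", taxon = "C", ev = 1e-60, pid = 99))
  expect_equal(identify(h2b, tx, cfg)$rank, "class")

  h3 <- make_hits(make_hit(acc = "r1", taxon = "A1", ev = 1e-60, pid = 99),
                  make_hit(acc = "r2", taxon = "D", ev = 1e-60, pid = 99))
  a3 <- identify(h3, tx, cfg)
  expect_equal(a3$rank, "none")
  expect_equal(a3$status, "unidentified")
  expect_true(is.na(a3$taxon_id))
})

test_that("identify: first-100 shortcut overrides the margin check", {
  same <- do.call(rbind, lapply(1:100, function(i) {
    make_hit(acc = sprintf("r%03d", i), taxon = "A1", ev = 10^(-60 + i * 0.1),
             pid = 99)
  }))
  close_other <- do.call(rbind, lapply(1:20, function(i) {
    make_hit(acc = sprintf("s%03d", i), taxon = "A2", ev = 1e-30, pid = 98.9)
  }))
  a <- identify(rbind(same, close_other), tx, cfg)
  expect_equal(a$status, "species_level")
  expect_equal(a$taxon_name, "Gena alpha")
  expect_equal(a$n_supporting_hits, 120L)
})

test_that("identify: empty, below-threshold and unknown-taxon inputs", {
  expect_equal(identify(make_hit()[0, ], tx, cfg)$status, "unidentified")
  a <- identify(make_hit(ev = 1e-8), tx, cfg)
  expect_equal(a$status, "below_threshold")
  expect_true(is.na(a$taxon_id))
  expect_error(identify(make_hit(taxon = "zz"), tx, cfg), "unknown taxon")
})

test_that("junk sub-threshold hits do not drag the rank down", {
  # a chance 100%-identity hit with a hopeless E-value is not a candidate
  h <- make_hits(make_hit(taxon = "A1", ev = 1e-50, pid = 99),
                 make_hit(acc = "r2", taxon = "D", ev = 0.5, pid = 100,
                          len = 12))
  a <- identify(h, tx, cfg)
  expect_equal(a$status, "species_level")
  expect_equal(a$taxon_name, "Gena alpha")
})

test_that("anthropogenic exclusion", {
  hum <- make_assignment(taxon_id = "HS", taxon_name = "Homo sapiens")
  expect_equal(exclude_anthropogenic(hum, tx, cfg)$status,
               "excluded_anthropogenic")
  wild <- make_assignment()
  expect_identical(exclude_anthropogenic(wild, tx, cfg), wild)
  cfg_open <- rule_config(exclusion_taxa = character(0))
  expect_identical(exclude_anthropogenic(hum, tx, cfg_open), hum)
  # an excluded species inside the tie set also triggers exclusion
  demoted <- make_assignment(rank = "genus", taxon_name = "Homo",
                             status = "rank_demoted")
  demoted$tie_species <- "Homo sapiens;Homo neanderthalensis"
  expect_equal(exclude_anthropogenic(demoted, tx, cfg)$status,
               "excluded_anthropogenic")
})

test_that("high-scoring confirmation thresholds", {
  mk <- function(ev, pid) make_assignment(ev = ev, pid = pid)
  expect_equal(confirm_high_scoring(mk(5e-29, 96), cfg)$status,
               "confirmed_high_scoring")
  expect_equal(confirm_high_scoring(mk(1e-14, 98), cfg)$status,
               "species_level")
  expect_equal(confirm_high_scoring(mk(1e-21, 89.9), cfg)$status,
               "species_level")
  expect_equal(confirm_high_scoring(mk(1e-21, 90), cfg)$status,
               "confirmed_high_scoring")
  # excluded assignments are never confirmed
  ex <- mk(1e-30, 99); ex$status <- "excluded_anthropogenic"
  expect_equal(confirm_high_scoring(ex, cfg)$status, "excluded_anthropogenic")
})

test_that("property: raising the margin never promotes to species level", {
  set.seed(404)
  taxa <- c("A1", "A2", "B", "C", "D")
  for (i in 1:60) {
    n <- sample(2:6, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(j) {
      make_hit(acc = sprintf("r%02d", j), taxon = sample(taxa, 1),
               ev = 10^-sample(15:60, 1), pid = round(runif(1, 90, 100), 1))
    }))
    a_low <- identify(h, tx, rule_config(margin_pct = 1))
    a_mid <- identify(h, tx, rule_config(margin_pct = 3))
    a_high <- identify(h, tx, rule_config(margin_pct = 6))
    expect_false(a_low$status == "rank_demoted" &&
                   a_mid$status == "species_level")
    expect_false(a_mid$status == "rank_demoted" &&
                   a_high$status == "species_level")
  }
})

test_that("property: LCA rank equals a brute-force path comparison", {
  # independent oracle: deepest common prefix of full lineage paths
  brute_lca <- function(taxonomy, ids) {
    lin <- lineage(taxonomy, ids)
    path_ranks <- rev(RANKS)  # class first
    depth <- 0L
    for (r in path_ranks) {
      if (length(unique(lin[[r]])) == 1L) depth <- depth + 1L else break
    }
    if (depth == 0L) "none" else path_ranks[depth]
  }
  set.seed(505)
  for (i in 1:20) {
    txr <- generate_taxonomy(sample(2:5, 1), sample(2:10, 1), seed = i)
    ids <- sample(txr$taxon_id, sample(2:min(6, nrow(txr)), 1))
    expect_equal(shared_rank(txr, ids)$rank, brute_lca(txr, ids),
                 info = paste("seed", i))
  }
})

test_that("contamination recovery on half-background samples", {
  w <- make_world(seed = 77, per_base_error = 0, background_fraction = 0.5)
  sm <- simulate_sample(w$tx, w$ts, w$host, "t006", mode = "amplicon",
                        locus = "16S", n_queries = 200, config = w$cfg)
  hits <- search(sm$queries, w$db)
  asn <- assign_queries(hits, w$tx, cfg, query_ids = sm$queries$query_id)
  m <- merge(asn, sm$truth, by.x = "query_or_sample_id", by.y = "query_id")
  retained <- !(m$status %in% c("contaminant", "below_threshold",
                                "unidentified"))
  host_q <- m$source_class == "leech_host"
  expect_gte(mean(!retained[host_q]), 0.99)
  expect_gte(mean(retained[!host_q]), 0.90)
})
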
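# Shared fixtures, built in code at test time.

# Small simulated world: taxonomy, true sequences, host genome, reference DB.
make_world <- function(seed = 7, n_orders = 3, species_per_order = 4, ...) {
  cfg <- sim_config(n_orders = n_orders, species_per_order = species_per_order,
                    seed = seed, ...)
  tx <- generate_taxonomy(cfg$n_orders, cfg$species_per_order, cfg$seed)
  ts <- generate_true_sequences(tx, cfg)
  host <- generate_host_genome(cfg)
  db <- generate_reference_db(tx, cfg$loci, cfg, true_seqs = ts, host = host)
  list(cfg = cfg, tx = tx, ts = ts, host = host, db = db)
}

# Hand-built five-rank taxonomy with controlled relationships:
# A1, A2 congeners; B same family; C same class, different order; D other
# class; plus anthropogenic species.
tiny_taxonomy <- function() {
  tx <- data.frame(
    taxon_id = c("A1", "A2", "B", "C", "D", "HS", "TJ", "TK"),
    name = c("Gena alpha", "Gena beta", "Genb gamma", "Genc delta",
             "Gend epsilon", "Homo sapiens", "Tragulus javanicus",
             "Tragulus kanchil"),
    species = c("Gena alpha", "Gena beta", "Genb gamma", "Genc delta",
                "Gend epsilon", "Homo sapiens", "Tragulus javanicus",
                "Tragulus kanchil"),
    genus = c("Gena", "Gena", "Genb", "Genc", "Gend", "Homo", "Tragulus",
              "Tragulus"),
    family = c("Famida", "Famida", "Famida", "Famidb", "Famidc", "Hominidae",
               "Tragulidae", "Tragulidae"),
    order = c("Ordoa", "Ordoa", "Ordoa", "Ordob", "Ordoc", "Primates",
              "Artiodactyla", "Artiodactyla"),
    class = c("Classa", "Classa", "Classa", "Classa", "Classb", "Classa",
              "Classa", "Classa"),
    is_excluded = FALSE, regions = "", stringsAsFactors = FALSE)
  class(tx) <- c("taxonomy", "data.frame")
  tx
}

# One hit-table row in the extended BLAST tabular layout.
make_hit <- function(qid = "q1", acc = "r1", taxon = "A1", ev = 1e-50,
                     pid = 99, locus = "12S", len = 100) {
  data.frame(qseqid = qid, sseqid = acc, pident = pid, length = len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = ev, bitscore = 100,
             taxon_id = taxon, locus = locus, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

# Minimal one-row assignment for reconciliation tests.
make_assignment <- function(sid = "s1", taxon_id = "A1",
                            taxon_name = "Gena alpha", rank = "species",
                            status = "species_level", ev = 1e-40, pid = 99,
                            locus = "12S") {
  data.frame(query_or_sample_id = sid, locus = locus, taxon_id = taxon_id,
             taxon_name = taxon_name, rank = rank, status = status,
             best_evalue = ev, best_identity = pid,
             margin_to_next_taxon = NA_real_, n_supporting_hits = 1L,
             tie_species = taxon_name, stringsAsFactors = FALSE)
}

# Hand-constructed reference DB wrapper (sequences optional) so coverage
# geometries can be forced without simulation.
make_refdb <- function(coverage, loci = colnames(coverage)) {
  structure(list(
    sequences = data.frame(accession = character(0), taxon_id = character(0),
                           locus = character(0), sequence = character(0)),
    loci = loci, coverage = coverage, total_length = 1L), class = "ref_db")
}
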
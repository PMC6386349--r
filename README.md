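# idnatax

Taxonomic assignment of invertebrate-ingested DNA (iDNA) from leech
bloodmeals.

## The problem

Terrestrial haemadipsid leeches ingest vertebrate blood, and the mitochondrial
DNA in their gut contents can be amplified and sequenced long after feeding —
even from decade-old, ethanol-fixed museum specimens. That makes leeches
cheap, self-deploying biodiversity samplers: identify the host species behind
each bloodmeal and you have an indirect faunal survey of the forest the
leeches came from.

The identification step is where surveys go wrong. Each gut-derived read or
contig is compared against a reference sequence database, and the best match
is taken as the host — but reference databases are radically uneven. A taxon
represented at only three mitochondrial loci will "lose" every other locus to
its best-covered relative, and an uncritical per-locus majority vote then
confidently names the wrong species. `idnatax` implements the full
desk-scale decision pipeline for this problem:

* **Homology search** — optimal local alignment (Smith–Waterman, affine
  gaps) of every query against an annotated multi-locus reference set, with
  bit scores `bit = (λS − ln K)/ln 2` and E-values `E = m·n·2^(−bit)`
  (Karlin–Altschul), ranked into BLAST-style tabular hit tables. External
  BLAST `outfmt 6` files are accepted in place of the internal engine.
* **Identification rules** — retention only when the best E-value beats
  `1e-10` *and* beats the best match to the leech's own genome by at least
  two orders of magnitude (contamination screen); a species-level call only
  when the best hit's percent identity beats the taxonomically next-best
  species by ≥ 3 points (assumed when the first 100 hits are one species);
  exact E-value ties demoted to the lowest rank at which there is
  discernment (LCA over the tie set); exclusion of humans and domestic taxa;
  confirmation of high-scoring matches (E < `1e-20`, identity ≥ 90%).
* **Reconciliation** — cross-validation of 12S vs 16S identifications per
  sample (confirmatory / additional / conflict), geographic-plausibility
  flags, and a **reference-coverage-aware consensus**: candidate A explains
  candidate B's contig wins if every locus B won is a locus the database
  lacks for A, while A matches at least as well wherever both are covered.
  The unique explaining candidate wins, resolving database-gap artifacts
  that defeat naive majority assignment.
* **Survey statistics** — composition by order, cross-locus overlap, mean
  identities, detection rates and preservation-medium breakdowns from an
  S1-style per-sample best-match table.
* **Synthetic data** — a generator for ranked taxonomies, reference
  databases with controllable per-taxon-per-locus coverage gaps, amplicon
  reads and shotgun contigs with substitution errors and legacy-DNA-style
  truncation, leech-host background reads, and complete ground truth — so
  every rule above is validated against known answers.

## Worked example

```r
library(idnatax)

cfg  <- sim_config(n_orders = 2, species_per_order = 3,
                   loci = c("12S", "16S"), seed = 11,
                   background_fraction = 0.2)
tx   <- generate_taxonomy(2, 3, seed = 11)
ts   <- generate_true_sequences(tx, cfg)
host <- generate_host_genome(cfg)
db   <- generate_reference_db(tx, cfg$loci, cfg, true_seqs = ts, host = host)
db
#> ref_db: 13 sequences, 2 loci, 12/12 taxon-locus cells covered, 8600 bases

sm   <- simulate_sample(tx, ts, host, source_taxon = "t002",
                        mode = "amplicon", locus = "12S",
                        n_queries = 8, config = cfg)
hits <- search(sm$queries, db)
asn  <- assign_queries(hits, tx, rule_config(),
                       query_ids = sm$queries$query_id)
asn[, c("query_or_sample_id", "taxon_name", "rank", "status",
        "best_evalue", "best_identity")]
#>   query_or_sample_id    taxon_name    rank                 status  best_evalue best_identity
#> 1           S1_q0001          <NA>    none        below_threshold 2.602203e+00       100.000
#> 2           S1_q0002 Xodiba nesuxo species confirmed_high_scoring 8.053830e-65        99.237
#> 3           S1_q0003 Xodiba nesuxo species confirmed_high_scoring 8.770559e-61       100.000
#> ...
```

Query `S1_q0001` is a leech-host background read: its best non-host match is
a chance 100%-identity micro-alignment with a hopeless E-value (2.6), so it
is rejected — identity alone is never trusted. The remaining reads are true
bloodmeal reads from taxon `t002` ("Xodiba nesuxo" in this simulated
taxonomy) and are all identified to species and confirmed high-scoring
(E ≪ 1e-20, identity ≥ 90%), matching the configured ground truth in
`sm$truth`.

A complete survey can also be driven from the command line:

```sh
exec/idnatax all --config config.yaml --seed 11 --out results/
```

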
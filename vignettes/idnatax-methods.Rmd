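---
title: "idnatax: methods, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{idnatax: methods, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idnatax)
```

## Scope

`idnatax` identifies vertebrate hosts from DNA ingested by blood-feeding
terrestrial leeches (iDNA). It covers the dry half of such a survey: homology
search of gut-derived sequences against a multi-locus reference database,
the filtering and identification decision rules, cross-locus and
coverage-aware reconciliation, and survey-level summaries — plus a
synthetic-data generator with ground truth used to validate every rule. Wet
lab concerns (PCR, library preparation, platform error profiles, contig
assembly) and phylogenetics are out of scope; shotgun contigs are accepted
as input.

## The search model

Queries are aligned to every reference by optimal local alignment
(Smith–Waterman) under affine gaps: match `+2`, mismatch `−3`, gap open `5`,
gap extend `2` by default (a gap of length $L$ costs $5 + 2L$). `N` scores
as a mismatch against everything, including `N`. Raw scores $S$ are
converted to bits and E-values with the Karlin–Altschul form

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-\mathrm{bit}},$$

with $m$ the query length and $n$ the total database length, and
$\lambda = 0.625$, $K = 0.41$ (published gapped-blastn values for this
scheme; both configurable via `scoring_scheme()`). There is no edge-effect
correction and no heuristic seeding: the engine is a desk-scale stand-in
for BLAST, not a reimplementation. Absolute E-values therefore differ from
runs against large public databases — every downstream rule uses only
thresholds and *ratios* of E-values, which is what the decision procedure
was designed around. Hits are totally ordered (E-value ascending, identity
descending, accession), so searches are byte-reproducible; external BLAST
tabular files (12 columns + `taxon_id`, `locus`) can replace the internal
engine.

Percent identity is computed over the columns of the optimal local
alignment. One consequence matters downstream: a biologically meaningless
8-bp chance match has 100% identity. Identity is therefore never consulted
before the E-value retention gate (see below).

## The identification decision procedure

Thresholds live in `rule_config()`; defaults in parentheses.

1. **Retention / contamination screen.** A query is retained only when its
   best E-value beats the retention threshold (`1e-10`, strict) and, when
   the reference set contains the leech-host genome, beats the best host
   match by at least `contamination_ratio` (2) orders of magnitude
   (inclusive, multiplicative; a zero target E-value against a nonzero host
   E-value passes, two zeros are indistinguishable and fail).
2. **Shortcut.** If the first `shortcut_depth` (100) retained hits are all
   one species, that species is assigned without a margin check. This is
   implemented as a sufficient condition, as the original labor-saving rule
   was phrased.
3. **Margin rule.** Otherwise the best hit is compared with the best hit of
   a *taxonomically different* species (within-species duplicate accessions
   are skipped): an identity lead of at least `margin_pct` (3) percentage
   points — inclusive — gives a species-level call. The margin is applied
   to percent identity, not to E-values: the survey's supplementary-table
   caption states the rule that way, while the main text conflates it with
   E-values; the caption is taken as authoritative.
4. **Rank demotion.** When several species tie on the best E-value exactly
   (an optional relative tolerance, default off, handles floating-point hit
   tables), or fall within the margin, the call is demoted to the deepest
   rank — species < genus < family < order < class — at which all species
   in the set share a name (an LCA over the set). A set spanning classes
   yields rank `none`.
5. **Exclusion and confirmation.** Calls to humans and domestic/commensal
   taxa (configurable synonym-expanded list; "house rats" covers both
   commensal *Rattus*) are marked excluded; remaining calls with
   E < `1e-20` and identity ≥ 90% are marked confirmed high-scoring.

Only retained hits (E-value past the retention threshold) participate in
steps 2–4. This is the one place the implementation sharpens the published
wording: a chance 10-bp alignment at 100% identity with E ≈ 1 must not drag
a call down to class rank. In real BLAST output against a large database
such hits do not surface among the top 100 matches; in a desk-scale search
they would, so the retention gate doubles as the candidate filter.

## Reconciliation

**Cross-locus (12S/16S).** Per sample, two locus assignments are
*confirmatory* when they agree at the shallower of their two ranks (the
resolved taxon is then the deeper one), *additional* when only one locus
yielded an identification, and in *conflict* otherwise. Conflicts resolve to
the locus with the higher percent identity when the gap is at least
`margin_pct`, mirroring how civet- and mongoose-type disagreements are
adjudicated; otherwise they stay unresolved. Geographic plausibility is
advisory only: an assignment outside the expected regional list is flagged,
with the best-ranked in-list hit suggested, and never auto-overridden — a
flagged assignment with *no* in-list alternative may represent a taxon with
no reference data at all.

**Coverage-aware consensus.** For a pool of shotgun contigs, candidate
species are those winning at least one contig (win order: E-value, then
identity — the search module's total order). Candidate $A$ *explains*
candidate $B$ iff every locus where $B$ outranked $A$ is a locus the
database lacks for $A$, and at every locus where both are covered $A$'s
best identity is at least $B$'s. A unique candidate explaining all others
wins. When no single explainer exists, candidates are partitioned into
connected components (edge = the two candidates compete on a shared
contig) and each component is resolved independently: a pool genuinely
containing two prey taxa with disjoint loci then yields one winner per
component, while genuinely conflicting evidence stays `ambiguous`. The
disjoint-coverage criterion formalizes the published verbal argument; the
partition rule is this package's own design choice for multi-prey pools.
With a complete coverage matrix the consensus can never contradict the
plain majority winner (property-tested). `naive_locus_majority()` is kept
as the explicit foil and misassigns essentially every database-gap pool in
simulation.

## The synthetic world

The generator states one fixed world; its defaults were chosen once, as
follows, and are not tuned against test outcomes.

* **Taxonomy**: 3 orders × 4 species (orders grouped into classes in blocks
  of three; genera per order ≈ √species so multi-species genera exist);
  pseudo-Latin names from a seeded syllable generator.
* **Sequences**: one random 300-bp ancestor per locus; independent point
  substitutions (Jukes–Cantor-style, no indels in generation) on each edge
  of the lineage tree at $d/2$ per edge, so sister species diverge by
  ≈ `interspecies_divergence` $d$ (default 0.10 — typical of mitochondrial
  barcodes between congeners), congeneric genera by ≈ $2d$, orders by
  ≈ $4d$. Reference sequences add `intraspecies_divergence` (0.005)
  polymorphism. Within-genus identity strictly exceeding between-order
  identity is property-tested over ten taxonomies.
* **Reads**: truncated to a uniform length in `read_length` (90–150 bp,
  mimicking degraded legacy-specimen templates; the degradation level is a
  free parameter — the source material gives no quantitative decay model),
  with per-base substitution error 0.01. No chimeras, no quality scores, no
  platform-specific (homopolymer) error profiles.
* **Background**: a designated leech-host taxon outside the simulated
  tetrapod clade, represented by one long (5 kb) unannotated genome
  sequence; each read is background with probability
  `background_fraction` (0.1).
* **Coverage gaps**: each taxon × locus cell of the reference database is
  filled with probability `locus_coverage_prob` — a scalar or a per-cell
  matrix, which is how the database-gap fixtures force the
  mongoose-style geometry exactly.
* **Reproducibility**: one root seed; taxonomy, database, host and each
  sample's reads draw from named child streams (`child_seed`), so adding
  reads never perturbs the taxonomy. Identical configuration and seed give
  byte-identical FASTA/TSV outputs.

What a green test on this world does **not** establish: performance on real
amplicon chemistry (primer bias, chimeras), on indel-rich or homopolymer
error profiles, on taxonomies whose barcode gap is narrower than the read
error, or with absolute E-value calibration comparable to nr/nt. The
generator's role is to verify the *decision logic* — that the rules recover
known truth when their stated assumptions hold, and that the coverage-gap
artifact is real and corrected.

## Numerical and degenerate-input choices

* All E-value comparisons are strict (`<`) except those phrased "at least",
  which are inclusive; the two-orders-of-magnitude comparison multiplies by
  $10^{-2}$ with a $1 + 10^{-9}$ relative guard so the inclusive boundary
  survives floating point.
* Ties in hit tables break deterministically by accession; tie *detection*
  on E-values is exact equality by default, with an optional relative
  tolerance for floating-point tables.
* A query whose best alignment has non-positive score yields zero hits; an
  all-gap coverage draw yields an empty database with `total_length` 0 and
  a warning; empty surveys (`n = 0`) and empty query sets produce empty,
  well-formed outputs rather than errors.
* Percent identity counts character-identical columns of the local
  alignment; `N`–`N` columns count as identical even though they *score* as
  mismatches (scoring and identity answer different questions).
* The survey statistics expose two "wild taxon" filters, confirmed
  (E < 1e-20, identity ≥ 90) and unconfirmed, because the published 55- and
  39-sample denominators use different inclusion rules; composition counts
  a sample once under `loci = "union"`, preferring the 12S identification.

## Known limitations

* The alignment engine is exact but $O(mn)$ per pair with no seeding; it is
  meant for hundreds of queries against kilobase-scale local databases, not
  for nr/nt-scale searches — use external BLAST tabular input there.
* Assignment quality is bounded by the margin rule's assumption that the
  reference barcode gap exceeds read error plus intraspecific
  polymorphism; when it does not, calls demote to genus or family by
  design rather than guessing.
* The coverage-aware consensus assumes the coverage matrix is known and
  correct; it reasons about *absence* of reference loci, so an unindexed
  but present sequence (e.g., mislabelled locus) defeats it.
* The per-sample table reader normalizes preservation media to
  RNAlater/ethanol/unknown and warns on anything else; it does not attempt
  spreadsheet parsing — convert to TSV first.
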
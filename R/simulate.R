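#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults describe a
#' small but realistic leech-gut survey: a dozen tetrapod species across three
#' orders, six mitochondrial loci, ~10% sister-species divergence (typical of
#' mitochondrial barcodes between congeners), 0.5% within-species
#' polymorphism, 1% per-base read error (degraded-template sequencing), reads
#' truncated to 90-150 bp (short 12S amplicons from legacy material), and 10%
#' of reads from the leech host itself.
#'
#' @param n_orders,species_per_order taxonomy shape.
#' @param loci locus labels simulated for every taxon.
#' @param locus_coverage_prob probability that a taxon x locus cell of the
#'   reference database holds a sequence, or a taxon x locus logical/numeric
#'   matrix of per-cell probabilities (rownames = taxon ids, colnames = loci).
#' @param interspecies_divergence expected substitutions/site between sister
#'   species (same genus); deeper splits accumulate proportionally.
#' @param intraspecies_divergence expected substitutions/site between a
#'   species' true sequence and its database representative.
#' @param locus_length length of each simulated locus (bases).
#' @param read_length length-2 range (or scalar) reads are truncated to,
#'   mimicking degraded legacy-specimen DNA.
#' @param per_base_error substitution probability per base in reads.
#' @param background_fraction fraction of reads drawn from the leech host.
#' @param composition named list: region -> named numeric vector of sampling
#'   weights over taxon ids (or species names).
#' @param host_genome_length length of the simulated leech-host genome.
#' @param host_taxon_id label for the leech-host background taxon.
#' @param seed root seed; all child streams derive from it.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_orders = 3L,
                       species_per_order = 4L,
                       loci = c("12S", "16S", "cox1", "nd2", "cytb", "nd5"),
                       locus_coverage_prob = 1.0,
                       interspecies_divergence = 0.10,
                       intraspecies_divergence = 0.005,
                       locus_length = 300L,
                       read_length = c(90L, 150L),
                       per_base_error = 0.01,
                       background_fraction = 0.1,
                       composition = NULL,
                       host_genome_length = 5000L,
                       host_taxon_id = "leech_host",
                       seed = 1L) {
  if (is.numeric(locus_coverage_prob) && !is.matrix(locus_coverage_prob)) {
    if (locus_coverage_prob < 0 || locus_coverage_prob > 1) {
      stop_invalid("locus_coverage_prob must be in [0, 1]")
    }
  }
  for (p in c(interspecies_divergence, intraspecies_divergence, per_base_error,
              background_fraction)) {
    if (p < 0 || p > 1) stop_invalid("probabilities must be in [0, 1]")
  }
  if (!is.null(composition)) {
    for (reg in names(composition)) {
      w <- composition[[reg]]
      if (any(w < 0)) stop_invalid("composition weights must be nonnegative")
    }
  }
  if (length(read_length) == 1L) read_length <- rep(read_length, 2L)
  structure(list(
    n_orders = as.integer(n_orders),
    species_per_order = as.integer(species_per_order),
    loci = loci,
    locus_coverage_prob = locus_coverage_prob,
    interspecies_divergence = interspecies_divergence,
    intraspecies_divergence = intraspecies_divergence,
    locus_length = as.integer(locus_length),
    read_length = as.integer(read_length),
    per_base_error = per_base_error,
    background_fraction = background_fraction,
    composition = composition,
    host_genome_length = as.integer(host_genome_length),
    host_taxon_id = host_taxon_id,
    seed = as.integer(seed)
  ), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

# Jukes-Cantor-style point substitutions: each site mutates with probability p
# to one of the three other bases. No indels in generation (indels only arise
# in alignment of error-mutated reads).
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < p)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1L), "")
  }
  paste(v, collapse = "")
}

# Substitution probability per lineage-tree edge, as a fraction of the
# interspecies divergence d: every edge mutates at d/2, so sister species
# (same genus) diverge by ~d, congeneric-genus pairs by ~2d, cross-order
# pairs by ~4d — the identity ordering the assignment rules rely on.
.lvl_frac <- c(class = 0.5, order = 0.5, family = 0.5, genus = 0.5,
               species = 0.5)

#' Generate the true per-taxon, per-locus sequences (the generating model)
#'
#' Every taxon possesses every locus in the generating model; database
#' incompleteness is applied later by [generate_reference_db()]. Sequences
#' descend from a per-locus random ancestor with independent substitutions on
#' each edge of the lineage tree, so within-genus identity exceeds
#' between-order identity in expectation.
#'
#' @param taxonomy a taxonomy.
#' @param config a [sim_config()].
#' @return named list: locus -> named character vector (taxon_id -> sequence).
#' @export
generate_true_sequences <- function(taxonomy, config) {
  d <- config$interspecies_divergence
  with_seed(child_seed(config$seed, "trueseq"), {
    out <- list()
    for (locus in config$loci) {
      anc <- random_seq(config$locus_length)
      node_seq <- new.env(parent = emptyenv())
      get_node <- function(rank, name, parent_seq) {
        key <- paste(rank, name, sep = "|")
        if (!is.null(node_seq[[key]])) return(node_seq[[key]])
        s <- mutate_seq(parent_seq, d * .lvl_frac[[rank]])
        node_seq[[key]] <- s
        s
      }
      seqs <- character(nrow(taxonomy))
      names(seqs) <- taxonomy$taxon_id
      for (i in seq_len(nrow(taxonomy))) {
        s <- anc
        for (r in rev(RANKS)) {       # class down to species
          s <- get_node(r, taxonomy[[r]][i], s)
        }
        seqs[[taxonomy$taxon_id[i]]] <- s
      }
      out[[locus]] <- seqs
    }
    out
  })
}

#' Simulate the leech-host genome
#'
#' One long unannotated sequence standing in for the sanguivore's own genome,
#' used both to generate background reads and as the contamination screen
#' reference.
#'
#' @param config a [sim_config()].
#' @return character scalar sequence.
#' @export
generate_host_genome <- function(config) {
  with_seed(child_seed(config$seed, "host"), random_seq(config$host_genome_length))
}

#' Generate a reference database with locus-coverage gaps
#'
#' Each taxon x locus cell is present with probability
#' `config$locus_coverage_prob` (or the per-cell value if a matrix was
#' supplied). A present cell contributes one accession whose sequence is the
#' taxon's true sequence mutated at the intraspecies divergence. The derived
#' boolean coverage matrix is the object whose incompleteness the
#' reconciliation module reasons about.
#'
#' @param taxonomy a taxonomy.
#' @param loci character vector of locus labels (nonempty).
#' @param config a [sim_config()].
#' @param true_seqs optional precomputed [generate_true_sequences()] output.
#' @param host optional host genome string appended as accession
#'   `host0001` with locus `"genome"` (the contamination screen entry).
#' @return list of class `"ref_db"`: `sequences` (data.frame accession,
#'   taxon_id, locus, sequence), `loci`, `coverage` (taxon x locus logical
#'   matrix), `total_length`.
#' @export
generate_reference_db <- function(taxonomy, loci = NULL, config,
                                  true_seqs = NULL, host = NULL) {
  loci <- loci %||% config$loci
  if (length(loci) == 0) stop_invalid("loci must be nonempty")
  true_seqs <- true_seqs %||% generate_true_sequences(taxonomy, config)
  cov_spec <- config$locus_coverage_prob
  with_seed(child_seed(config$seed, "db"), {
    coverage <- matrix(FALSE, nrow(taxonomy), length(loci),
                       dimnames = list(taxonomy$taxon_id, loci))
    for (t in taxonomy$taxon_id) {
      for (l in loci) {
        p <- if (is.matrix(cov_spec)) {
          ri <- if (t %in% rownames(cov_spec)) t else match(t, taxonomy$taxon_id)
          as.numeric(cov_spec[ri, l])
        } else cov_spec
        coverage[t, l] <- stats::runif(1) < p || p >= 1
      }
    }
    rows <- list()
    k <- 0L
    for (t in taxonomy$taxon_id) {
      for (l in loci) {
        if (!coverage[t, l]) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          accession = sprintf("ref%04d", k),
          taxon_id = t, locus = l,
          sequence = mutate_seq(true_seqs[[l]][[t]],
                                config$intraspecies_divergence),
          stringsAsFactors = FALSE
        )
      }
    }
    sequences <- if (k > 0) do.call(rbind, rows) else
      data.frame(accession = character(0), taxon_id = character(0),
                 locus = character(0), sequence = character(0))
    if (!is.null(host)) {
      sequences <- rbind(sequences, data.frame(
        accession = "host0001", taxon_id = config$host_taxon_id,
        locus = "genome", sequence = host, stringsAsFactors = FALSE))
    }
    db <- structure(list(sequences = sequences, loci = loci,
                         coverage = coverage,
                         total_length = sum(nchar(sequences$sequence))),
                    class = "ref_db")
    if (db$total_length == 0) {
      warning("reference database is empty (total_length = 0)", call. = FALSE)
    }
    db
  })
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("ref_db: %d sequences, %d loci, %d/%d taxon-locus cells covered, %d bases\n",
              nrow(x$sequences), length(x$loci), sum(x$coverage),
              length(x$coverage), x$total_length))
  invisible(x)
}

draw_read <- function(seq, config) {
  rl <- if (config$read_length[1] == config$read_length[2]) config$read_length[1]
        else sample(config$read_length[1]:config$read_length[2], 1L)
  rl <- min(rl, nchar(seq))
  start <- if (nchar(seq) > rl) sample.int(nchar(seq) - rl + 1L, 1L) else 1L
  mutate_seq(substr(seq, start, start + rl - 1L), config$per_base_error)
}

#' Simulate one sample's query reads with ground truth
#'
#' Amplicon mode draws all reads from one locus (primer-targeted); shotgun
#' mode draws each read's locus uniformly from the loci the true taxon
#' possesses in the generating model — which the reference database may lack.
#' A `background_fraction` of reads comes from the leech host genome instead
#' of the bloodmeal taxon.
#'
#' @param taxonomy a taxonomy.
#' @param true_seqs output of [generate_true_sequences()].
#' @param host_genome output of [generate_host_genome()].
#' @param source_taxon taxon_id of the bloodmeal source (must be in taxonomy).
#' @param mode `"amplicon"` or `"shotgun"`.
#' @param locus required in amplicon mode; must be one of `config$loci`.
#' @param n_queries number of reads.
#' @param config a [sim_config()].
#' @param sample_id prefix for query ids.
#' @param stream_seed optional explicit seed for this sample's read stream.
#' @return list with `queries` (data.frame query_id, sequence) and `truth`
#'   (data.frame query_id, source_taxon_id, source_class, locus, error_rate,
#'   seed); exactly one truth row per query.
#' @export
simulate_sample <- function(taxonomy, true_seqs, host_genome, source_taxon,
                            mode = c("amplicon", "shotgun"), locus = NULL,
                            n_queries = 10L, config, sample_id = "S1",
                            stream_seed = NULL) {
  mode <- match.arg(mode)
  if (!source_taxon %in% taxonomy$taxon_id) {
    stop_invalid("source_taxon not in taxonomy: ", source_taxon)
  }
  if (mode == "amplicon") {
    if (is.null(locus) || !locus %in% config$loci) {
      stop_invalid("amplicon locus must be one of config$loci")
    }
  }
  seed <- stream_seed %||% child_seed(config$seed, paste0("reads|", sample_id))
  with_seed(seed, {
    qid <- sprintf("%s_q%04d", sample_id, seq_len(n_queries))
    is_bg <- stats::runif(n_queries) < config$background_fraction
    seqs <- character(n_queries)
    tloc <- character(n_queries)
    tsrc <- character(n_queries)
    tcls <- character(n_queries)
    for (i in seq_len(max(n_queries, 0L))) {
      if (n_queries == 0L) break
      if (is_bg[i]) {
        seqs[i] <- draw_read(host_genome, config)
        tloc[i] <- "genome"
        tsrc[i] <- config$host_taxon_id
        tcls[i] <- "leech_host"
      } else {
        li <- if (mode == "amplicon") locus else sample(config$loci, 1L)
        seqs[i] <- draw_read(true_seqs[[li]][[source_taxon]], config)
        tloc[i] <- if (mode == "shotgun") li else locus
        tsrc[i] <- source_taxon
        tcls[i] <- "bloodmeal"
      }
    }
    list(
      queries = data.frame(query_id = qid, sequence = seqs,
                           stringsAsFactors = FALSE),
      truth = data.frame(query_id = qid, source_taxon_id = tsrc,
                         source_class = tcls, locus = tloc,
                         error_rate = config$per_base_error, seed = seed,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a regional survey of leech samples
#'
#' For each region in `config$composition`, draws `n_samples_per_region`
#' source taxa with the configured weights and simulates one amplicon query
#' set per sample.
#'
#' @param taxonomy,true_seqs,host_genome as in [simulate_sample()].
#' @param config a [sim_config()] with non-null `composition`.
#' @param n_samples_per_region samples per region (0 allowed: empty survey).
#' @param locus amplicon locus for the per-sample reads.
#' @param queries_per_sample reads per sample.
#' @return list with `samples` (sample_id, region, source_taxon_id),
#'   `queries`, `truth` (per read, with sample_id column added).
#' @export
simulate_survey <- function(taxonomy, true_seqs, host_genome, config,
                            n_samples_per_region = 10L, locus = "12S",
                            queries_per_sample = 1L) {
  comp <- config$composition
  if (is.null(comp) || !length(comp)) stop_invalid("config$composition must be set")
  for (reg in names(comp)) {
    if (sum(comp[[reg]]) <= 0) {
      stop_invalid("composition weights for region '", reg, "' are all zero")
    }
  }
  samples <- data.frame(sample_id = character(0), region = character(0),
                        source_taxon_id = character(0), stringsAsFactors = FALSE)
  queries <- data.frame(query_id = character(0), sequence = character(0),
                        stringsAsFactors = FALSE)
  truth <- NULL
  if (n_samples_per_region > 0) {
    for (reg in names(comp)) {
      w <- comp[[reg]]
      ids <- names(w)
      # accept species names as weight labels
      unk <- setdiff(ids, c(taxonomy$taxon_id, taxonomy$species))
      if (length(unk)) stop_invalid("composition names unknown taxa: ",
                                    paste(unk, collapse = ", "))
      ids <- ifelse(ids %in% taxonomy$taxon_id, ids,
                    taxonomy$taxon_id[match(ids, taxonomy$species)])
      src <- with_seed(child_seed(config$seed, paste0("survey|", reg)), {
        sample(ids, n_samples_per_region, replace = TRUE, prob = w / sum(w))
      })
      for (i in seq_len(n_samples_per_region)) {
        sid <- sprintf("%s_%04d", reg, i)
        sm <- simulate_sample(taxonomy, true_seqs, host_genome, src[i],
                              mode = "amplicon", locus = locus,
                              n_queries = queries_per_sample, config,
                              sample_id = sid)
        sm$truth$sample_id <- sid
        samples <- rbind(samples, data.frame(sample_id = sid, region = reg,
                                             source_taxon_id = src[i],
                                             stringsAsFactors = FALSE))
        queries <- rbind(queries, sm$queries)
        truth <- rbind(truth, sm$truth)
      }
    }
  }
  if (is.null(truth)) {
    truth <- data.frame(query_id = character(0), source_taxon_id = character(0),
                        source_class = character(0), locus = character(0),
                        error_rate = numeric(0), seed = integer(0),
                        sample_id = character(0), stringsAsFactors = FALSE)
  }
  list(samples = samples, queries = queries, truth = truth)
}

#' FASTA and truth-table I/O for simulated data
#'
#' Reference headers carry `accession|taxon_id|locus`; a sidecar TSV maps
#' accession to full lineage and locus. Query FASTA headers are the query ids.
#'
#' @param queries data.frame (query_id, sequence).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_query_fasta <- function(queries, path) {
  x <- Biostrings::DNAStringSet(queries$sequence)
  names(x) <- queries$query_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_query_fasta
#' @param db a `ref_db`.
#' @param taxonomy taxonomy used for the sidecar lineage TSV.
#' @param sidecar optional path for the accession -> lineage/locus TSV.
#' @export
write_reference_fasta <- function(db, path, taxonomy = NULL, sidecar = NULL) {
  x <- Biostrings::DNAStringSet(db$sequences$sequence)
  names(x) <- with(db$sequences, paste(accession, taxon_id, locus, sep = "|"))
  Biostrings::writeXStringSet(x, path)
  if (!is.null(sidecar) && !is.null(taxonomy)) {
    side <- db$sequences[, c("accession", "taxon_id", "locus")]
    known <- side$taxon_id %in% taxonomy$taxon_id
    lin <- as.data.frame(matrix(NA_character_, nrow(side), length(RANKS),
                                dimnames = list(NULL, RANKS)))
    if (any(known)) lin[known, ] <- lineage(taxonomy, side$taxon_id[known])
    utils::write.table(cbind(side, lin), sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_query_fasta
#' @export
read_query_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(query_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname write_query_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop_invalid("reference headers must be accession|taxon_id|locus; bad: ",
                 names(x)[bad][1])
  }
  sequences <- data.frame(
    accession = vapply(parts, `[`, "", 1L),
    taxon_id = vapply(parts, `[`, "", 2L),
    locus = vapply(parts, `[`, "", 3L),
    sequence = as.character(x), stringsAsFactors = FALSE, row.names = NULL)
  loci <- setdiff(unique(sequences$locus), "genome")
  taxa <- unique(sequences$taxon_id)
  coverage <- matrix(FALSE, length(taxa), length(loci),
                     dimnames = list(taxa, loci))
  for (i in seq_len(nrow(sequences))) {
    if (sequences$locus[i] %in% loci) {
      coverage[sequences$taxon_id[i], sequences$locus[i]] <- TRUE
    }
  }
  structure(list(sequences = sequences, loci = loci, coverage = coverage,
                 total_length = sum(nchar(sequences$sequence))),
            class = "ref_db")
}

#' @rdname write_query_fasta
#' @param truth truth data.frame from the simulators.
#' @param seed seed recorded in the header.
#' @export
write_truth <- function(truth, path, seed = NULL) {
  write_tsv_seeded(truth, path, seed)
}
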
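#' Load a pipeline configuration
#'
#' A single YAML (or JSON) file with optional blocks `sim` (arguments to
#' [sim_config()]), `rules` (arguments to [rule_config()]), `paths`
#' (queries/references/taxonomy/hits/sample_table), `seed`, `out_dir`.
#'
#' @param path config file, or `NULL` for all defaults.
#' @param overrides named list merged over the file contents (flag overrides).
#' @return list of class `"pipeline_config"` with `sim`, `rules`, `paths`,
#'   `seed`, `out_dir`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  raw <- utils::modifyList(raw, overrides)
  seed <- as.integer(raw$seed %||% 1L)
  sim_args <- raw$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  if (!is.null(sim_args$composition)) {
    sim_args$composition <- lapply(sim_args$composition, unlist)
  }
  structure(list(
    sim = do.call(sim_config, sim_args),
    rules = do.call(rule_config, raw$rules %||% list()),
    paths = raw$paths %||% list(),
    seed = seed,
    out_dir = raw$out_dir %||% "."
  ), class = "pipeline_config")
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Pipeline stages
#'
#' `run_simulate` writes a complete synthetic fixture set (reference FASTA +
#' lineage sidecar, taxonomy TSV, coverage TSV, per-sample query FASTA, truth
#' TSV). `run_assign` searches queries against the references (or ingests an
#' external BLAST tabular file) and writes assignments. `run_reconcile`
#' combines per-sample 12S/16S assignments and runs the coverage-aware
#' consensus per pool of shotgun contigs. `run_summarize` recomputes the
#' survey metrics from an S1-style table. Every stage is deterministic given
#' its inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (defaults to the config's).
#' @return invisibly, a named list of the files written.
#' @export
run_simulate <- function(config, out_dir = config$out_dir) {
  ensure_dir(out_dir)
  sim <- config$sim
  tx <- generate_taxonomy(sim$n_orders, sim$species_per_order, sim$seed)
  ts <- generate_true_sequences(tx, sim)
  host <- generate_host_genome(sim)
  db <- generate_reference_db(tx, sim$loci, sim, true_seqs = ts, host = host)
  files <- list(
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    references = file.path(out_dir, "references.fasta"),
    ref_sidecar = file.path(out_dir, "references.tsv"),
    coverage = file.path(out_dir, "coverage.tsv"),
    queries = file.path(out_dir, "queries.fasta"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_taxonomy(tx, files$taxonomy, seed = sim$seed)
  write_reference_fasta(db, files$references, tx, files$ref_sidecar)
  write_tsv_seeded(data.frame(taxon_id = rownames(db$coverage),
                              db$coverage, check.names = FALSE),
                   files$coverage, seed = sim$seed)
  comp <- sim$composition
  if (is.null(comp)) {
    comp <- list(regionA = stats::setNames(rep(1, nrow(tx)), tx$taxon_id))
    sim$composition <- comp
  }
  sv <- simulate_survey(tx, ts, host, sim,
                        n_samples_per_region = 10L, locus = sim$loci[1])
  write_query_fasta(sv$queries, files$queries)
  write_truth(sv$truth, files$truth, seed = sim$seed)
  invisible(files)
}

#' @rdname run_simulate
#' @param hits_path optional external BLAST tabular file used instead of the
#'   internal search engine.
#' @export
run_assign <- function(config, out_dir = config$out_dir, hits_path = NULL) {
  ensure_dir(out_dir)
  paths <- config$paths
  tx_path <- paths$taxonomy %||% file.path(out_dir, "taxonomy.tsv")
  if (!file.exists(tx_path)) stop_invalid("taxonomy file not found: ", tx_path)
  tx <- read_taxonomy(tx_path)
  q_path <- paths$queries %||% file.path(out_dir, "queries.fasta")
  queries <- if (file.exists(q_path)) read_query_fasta(q_path) else
    data.frame(query_id = character(0), sequence = character(0))
  if (!is.null(hits_path %||% paths$hits)) {
    hits <- read_blast_tab(hits_path %||% paths$hits)
  } else if (nrow(queries)) {
    r_path <- paths$references %||% file.path(out_dir, "references.fasta")
    if (!file.exists(r_path)) stop_invalid("reference file not found: ", r_path)
    db <- read_reference_fasta(r_path)
    hits <- search(queries, db, scoring_scheme(),
                   max_hits = config$rules$shortcut_depth + 20L)
  } else {
    hits <- empty_hits()
  }
  assignments <- if (nrow(hits) || nrow(queries)) {
    assign_queries(hits, tx, config$rules,
                   host_taxon = config$sim$host_taxon_id,
                   query_ids = if (nrow(queries)) queries$query_id else NULL)
  } else {
    empty_assignments()
  }
  files <- list(hits = file.path(out_dir, "hits.tsv"),
                assignments = file.path(out_dir, "assignments.tsv"))
  write_blast_tab(hits, files$hits)
  write_tsv_seeded(assignments, files$assignments, seed = config$seed)
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_reconcile <- function(config, out_dir = config$out_dir) {
  ensure_dir(out_dir)
  paths <- config$paths
  a_path <- paths$assignments %||% file.path(out_dir, "assignments.tsv")
  if (!file.exists(a_path)) stop_invalid("assignments file not found: ", a_path)
  assignments <- read_tsv_plain(a_path)
  tx <- read_taxonomy(paths$taxonomy %||% file.path(out_dir, "taxonomy.tsv"))
  # per-sample 12S/16S cross-validation: sample id = query id prefix
  assignments$sample_id <- sub("_q[0-9]+$", "", assignments$query_or_sample_id)
  rows <- list()
  for (sid in unique(assignments$sample_id)) {
    sa <- assignments[assignments$sample_id == sid, , drop = FALSE]
    pick <- function(loc) {
      cand <- sa[!is.na(sa$locus) & sa$locus == loc &
                   sa$status %in% c("species_level", "rank_demoted",
                                    "confirmed_high_scoring"), , drop = FALSE]
      if (!nrow(cand)) return(NULL)
      cand[order(cand$best_evalue), ][1, ]
    }
    rows[[sid]] <- cross_locus(pick("12S"), pick("16S"), tx)
    rows[[sid]]$sample_id <- sid
  }
  recon <- do.call(rbind, rows)
  files <- list(reconciliation = file.path(out_dir, "reconciliation.tsv"))
  write_tsv_seeded(recon, files$reconciliation, seed = config$seed)
  invisible(files)
}

#' @rdname run_simulate
#' @param n_total total samples examined, for the detection rate.
#' @export
run_summarize <- function(config, out_dir = config$out_dir, n_total = NULL) {
  ensure_dir(out_dir)
  paths <- config$paths
  st_path <- paths$sample_table %||% file.path(out_dir, "sample_table.tsv")
  if (!file.exists(st_path)) stop_invalid("sample table not found: ", st_path)
  cmap <- paths$column_map %||% default_column_map()
  records <- read_sample_table(st_path, cmap)
  tx <- read_taxonomy(paths$taxonomy %||% file.path(out_dir, "taxonomy.tsv"))
  cfg <- config$rules
  n_total <- n_total %||% nrow(records)
  comp <- composition(records, tx, cfg = cfg)
  ov <- locus_overlap(records, cfg)
  metrics <- list(
    n_records = nrow(records),
    mean_identity_12S = mean_identity(records, "12s"),
    mean_identity_16S = mean_identity(records, "16s"),
    locus_overlap = ov,
    detection_rate_pct = detection_rate(records, n_total, cfg),
    preservation = as.list(preservation_breakdown(records, cfg))
  )
  files <- list(composition = file.path(out_dir, "composition.tsv"),
                metrics = file.path(out_dir, "metrics.json"))
  write_tsv_seeded(comp, files$composition, seed = config$seed)
  jsonlite::write_json(metrics, files$metrics, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_all <- function(config, out_dir = config$out_dir) {
  f1 <- run_simulate(config, out_dir)
  f2 <- run_assign(config, out_dir)
  f3 <- run_reconcile(config, out_dir)
  invisible(c(f1, f2, f3))
}

#' Command-line entry point
#'
#' `idnatax <simulate|assign|reconcile|summarize|all> --config cfg.yaml
#' [--seed N] [--out DIR] [--hits hits.tsv]`. Logs go to stderr; machine
#' outputs to files only. Returns (invisibly) an exit status: nonzero on any
#' data error, with the offending record named in the message.
#'
#' @param argv character vector of CLI arguments.
#' @return integer exit status, invisibly.
#' @export
idnatax_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: idnatax <simulate|assign|reconcile|summarize|all> [--config FILE] [--seed N] [--out DIR] [--hits FILE]"
  if (!length(argv)) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]
  opts <- list(config = NULL, seed = NULL, out = NULL, hits = NULL)
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      message("unknown or incomplete flag: ", argv[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    overrides <- list()
    if (!is.null(opts$seed)) overrides$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) overrides$out_dir <- opts$out
    cfg <- pipeline_config(opts$config, overrides)
    switch(cmd,
      simulate = run_simulate(cfg),
      assign = run_assign(cfg, hits_path = opts$hits),
      reconcile = run_reconcile(cfg),
      summarize = run_summarize(cfg),
      all = run_all(cfg),
      stop_invalid("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
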
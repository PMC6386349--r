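#' Taxonomic rank ladder
#'
#' Ranks ordered from deepest (species) to shallowest (class). Identification
#' demotion ("lowest rank at which there was discernment") walks this ladder.
#' @export
RANKS <- c("species", "genus", "family", "order", "class")

rank_index <- function(rank) {
  i <- match(rank, RANKS)
  if (any(is.na(i))) stop_invalid("unknown rank: ", paste(rank[is.na(i)], collapse = ", "))
  i
}

# Pronounceable pseudo-Latin names so simulated taxonomies read like real ones.
.syllables <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ra",
                "su", "te", "vi", "xo", "zu", "ka", "lo", "mi", "ne", "or")

rand_name <- function(n_syl = 3, capitalize = TRUE) {
  s <- paste(sample(.syllables, n_syl, replace = TRUE), collapse = "")
  if (capitalize) s <- paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  s
}

unique_names <- function(n, n_syl = 3, capitalize = TRUE, suffix = "") {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(rand_name(n_syl, capitalize), suffix)
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}

#' Generate a random ranked taxonomy
#'
#' Builds a tree-shaped taxonomy: each order holds one or more families, each
#' family one or more genera, and each genus one or more species, with
#' `species_per_order` species in every order. Orders are grouped into classes
#' in blocks of three so that large taxonomies span more than one class.
#'
#' @param n_orders number of orders (>= 1).
#' @param species_per_order species in each order (>= 1).
#' @param seed integer seed; the same seed always yields the same taxonomy.
#' @return a `data.frame` of class `"taxonomy"` with columns `taxon_id`,
#'   `name` (binomial), one column per rank in [RANKS], `is_excluded` and
#'   `regions` (comma-separated labels, empty = unrestricted).
#' @examples
#' tx <- generate_taxonomy(3, 4, seed = 7)
#' nrow(tx)  # 12
#' @export
generate_taxonomy <- function(n_orders, species_per_order, seed = 1L) {
  if (!is.numeric(n_orders) || n_orders < 1 ||
      !is.numeric(species_per_order) || species_per_order < 1) {
    stop_invalid("n_orders and species_per_order must be >= 1")
  }
  n_orders <- as.integer(n_orders)
  species_per_order <- as.integer(species_per_order)
  with_seed(child_seed(seed, "taxonomy"), {
    n_sp <- n_orders * species_per_order
    class_names <- unique_names(ceiling(n_orders / 3), 3, TRUE, "ia")
    order_names <- unique_names(n_orders, 3, TRUE, "iformes")
    # genera per order scales ~ sqrt(species) so multi-species genera exist
    genera_per_order <- pmax(1L, as.integer(ceiling(sqrt(species_per_order))))
    n_gen <- n_orders * genera_per_order
    family_per_order <- pmax(1L, genera_per_order %/% 2L)
    family_names <- unique_names(n_orders * family_per_order, 3, TRUE, "idae")
    genus_names <- unique_names(n_gen, 3, TRUE)
    epithets <- unique_names(n_sp, 3, FALSE)

    rows <- vector("list", n_sp)
    k <- 0L
    for (o in seq_len(n_orders)) {
      cls <- class_names[ceiling(o / 3)]
      fams <- family_names[((o - 1L) * family_per_order + 1L):(o * family_per_order)]
      gens <- genus_names[((o - 1L) * genera_per_order + 1L):(o * genera_per_order)]
      gen_fam <- fams[((seq_along(gens) - 1L) %% length(fams)) + 1L]
      for (s in seq_len(species_per_order)) {
        k <- k + 1L
        gi <- ((s - 1L) %% length(gens)) + 1L
        rows[[k]] <- data.frame(
          taxon_id = sprintf("t%03d", k),
          name = paste(gens[gi], epithets[k]),
          species = paste(gens[gi], epithets[k]),
          genus = gens[gi],
          family = gen_fam[gi],
          order = order_names[o],
          class = cls,
          is_excluded = FALSE,
          regions = "",
          stringsAsFactors = FALSE
        )
      }
    }
    tx <- do.call(rbind, rows)
    class(tx) <- c("taxonomy", "data.frame")
    tx
  })
}

#' Look up the lineage of a taxon
#'
#' @param taxonomy a taxonomy `data.frame`.
#' @param taxon_id taxon identifier(s) or species name(s).
#' @return data.frame of lineage columns (one row per id).
#' @export
lineage <- function(taxonomy, taxon_id) {
  i <- match(taxon_id, taxonomy$taxon_id)
  miss <- is.na(i)
  i[miss] <- match(taxon_id[miss], taxonomy$species)
  if (any(is.na(i))) {
    stop_invalid("unknown taxon: ", paste(taxon_id[is.na(i)], collapse = ", "))
  }
  taxonomy[i, RANKS, drop = FALSE]
}

#' Deepest rank shared by a set of taxa (LCA rank)
#'
#' Walks the rank ladder from species up and returns the first rank at which
#' all taxa carry the same name — the "lowest rank at which there is
#' discernment". Returns `"none"` when the set spans classes.
#'
#' @param taxonomy a taxonomy `data.frame`.
#' @param taxon_ids taxon ids or species names (length >= 1).
#' @return list with `rank` (character, possibly "none") and `name` (the
#'   shared name at that rank, or `NA`).
#' @export
shared_rank <- function(taxonomy, taxon_ids) {
  lin <- lineage(taxonomy, unique(taxon_ids))
  for (r in RANKS) {
    if (length(unique(lin[[r]])) == 1L) {
      return(list(rank = r, name = lin[[r]][1]))
    }
  }
  list(rank = "none", name = NA_character_)
}

#' Write / read a taxonomy as TSV
#' @param taxonomy taxonomy data.frame.
#' @param path file path.
#' @param seed optional seed recorded in the file header.
#' @return the path (write) or the taxonomy (read).
#' @export
write_taxonomy <- function(taxonomy, path, seed = NULL) {
  write_tsv_seeded(as.data.frame(taxonomy), path, seed)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_invalid("taxonomy file not found: ", path)
  tx <- read_tsv_plain(path)
  need <- c("taxon_id", "name", RANKS)
  miss <- setdiff(need, names(tx))
  if (length(miss)) stop_invalid("taxonomy missing columns: ", paste(miss, collapse = ", "))
  if (is.null(tx$is_excluded)) tx$is_excluded <- FALSE
  if (is.null(tx$regions)) tx$regions <- ""
  class(tx) <- c("taxonomy", "data.frame")
  tx
}
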
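# Cross-species neighborhood conservation of focal-species gene pairs.
#
# "Gene neighbors" means immediately adjacent genes in order index on the
# same chromosome, strand-agnostic.  A pair's "appeared species" are the
# non-focal species in which BOTH genes have at least one ortholog; the
# pair's neighborhood is conserved when its orthologous counterparts are
# adjacent in more than half of those species.

#' Immediately adjacent genes of a gene
#'
#' @param annot A [genome_annotation()].
#' @param gene Gene ID present in `annot`.
#' @return Character vector of at most two gene IDs (the genes at order
#'   index ±1 on the same chromosome); length 1 at a chromosome end, length
#'   0 for a singleton chromosome.
#' @export
adjacent_neighbors <- function(annot, gene) {
  stopifnot(inherits(annot, "genome_annotation"))
  gi <- annot$gene_index
  if (!gene %in% rownames(gi)) {
    stop("unknown gene: ", gene, " (species ", annot$species_id, ")",
         call. = FALSE)
  }
  chrom <- gi[gene, "chrom"]
  idx <- gi[gene, "index"]
  genes <- annot$chromosomes[[chrom]]
  pos <- idx + 1L  # chromosome vector is 1-based
  res <- character(0)
  if (pos > 1L) res <- c(res, genes[[pos - 1L]])
  if (pos < length(genes)) res <- c(res, genes[[pos + 1L]])
  res
}

#' Species in which both genes of a pair have orthologs
#'
#' @param gene_a,gene_b Focal gene IDs.
#' @param orthomap An [orthology_map()].
#' @return Character vector of non-focal species labels, in universe order.
#'   Genes absent from the map contribute no species (empty result).
#' @export
appeared_species <- function(gene_a, gene_b, orthomap) {
  stopifnot(inherits(orthomap, "orthology_map"))
  pres <- orthomap$presence
  if (!(gene_a %in% rownames(pres)) || !(gene_b %in% rownames(pres))) {
    return(character(0))
  }
  orthomap$species_universe[pres[gene_a, ] & pres[gene_b, ]]
}

#' Minimum neighbor-species count for a conserved neighborhood
#'
#' The conservation rule requires adjacency in more than half (>= 50%) of
#' the appeared species; as an integer count this is `ceiling(n / 2)`,
#' e.g. 3, 4, 4, 5 and 5 species for pairs appearing in 6, 7, 8, 9 and 10
#' species.
#'
#' @param n_appeared Number of appeared species (>= 1).
#' @return Integer threshold.
#' @export
conservation_threshold <- function(n_appeared) {
  if (!is.numeric(n_appeared) || length(n_appeared) != 1L ||
      is.na(n_appeared) || n_appeared < 1) {
    stop("`n_appeared` must be a single integer >= 1", call. = FALSE)
  }
  as.integer(ceiling(n_appeared / 2))
}

#' Are two focal genes' orthologs neighbors in a given species?
#'
#' True when some ortholog of `gene_a` is immediately adjacent to some
#' ortholog of `gene_b` in that species (existential rule for one-to-many
#' orthology).
#'
#' @param gene_a,gene_b Focal gene IDs.
#' @param species Non-focal species label.
#' @param orthomap An [orthology_map()].
#' @param annots Named list of [genome_annotation()] objects, one per
#'   non-focal species.
#' @return Logical scalar.
#' @export
neighbors_in_species <- function(gene_a, gene_b, species, orthomap, annots) {
  annot <- annots[[species]]
  if (is.null(annot)) {
    stop("no annotation loaded for species: ", species, call. = FALSE)
  }
  xs <- orthologs_of(orthomap, gene_a, species)
  ys <- orthologs_of(orthomap, gene_b, species)
  if (!length(xs) || !length(ys)) return(FALSE)
  gi <- annot$gene_index
  xs <- xs[xs %in% rownames(gi)]
  ys <- ys[ys %in% rownames(gi)]
  if (!length(xs) || !length(ys)) return(FALSE)
  for (x in xs) {
    for (y in ys) {
      if (x == y) next
      if (gi[x, "chrom"] == gi[y, "chrom"] &&
          abs(gi[x, "index"] - gi[y, "index"]) == 1L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Adjacent gene pairs of one species' genome as a two-column data.table.
species_adjacency <- function(annot) {
  pieces <- lapply(annot$chromosomes, function(genes) {
    n <- length(genes)
    if (n < 2L) return(NULL)
    data.table::data.table(sg_a = genes[-n], sg_b = genes[-1L])
  })
  out <- data.table::rbindlist(pieces)
  if (!nrow(out)) {
    out <- data.table::data.table(sg_a = character(), sg_b = character())
  }
  out
}

# For every focal pair adjacent (via orthologs) in >= 1 non-focal species:
# one row per (pair, species).  Backbone of the batch classifier.
pair_neighbor_table <- function(annots, orthomap) {
  species <- orthomap$species_universe
  missing_sp <- setdiff(species, names(annots))
  if (length(missing_sp)) {
    stop("no annotation loaded for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  tab <- orthomap$table
  pieces <- lapply(species, function(s) {
    adj <- species_adjacency(annots[[s]])
    if (!nrow(adj)) return(NULL)
    rev_map <- tab[tab$species == s, c("ortholog_gene", "focal_gene")]
    if (!nrow(rev_map)) return(NULL)
    m1 <- merge(adj, rev_map, by.x = "sg_a", by.y = "ortholog_gene",
                allow.cartesian = TRUE)
    data.table::setnames(m1, "focal_gene", "focal_a")
    m2 <- merge(m1, rev_map, by.x = "sg_b", by.y = "ortholog_gene",
                allow.cartesian = TRUE)
    data.table::setnames(m2, "focal_gene", "focal_b")
    m2 <- m2[m2$focal_a != m2$focal_b]
    if (!nrow(m2)) return(NULL)
    data.table::data.table(pkey = pair_key(m2$focal_a, m2$focal_b),
                           species = s)
  })
  out <- data.table::rbindlist(pieces)
  if (!nrow(out)) {
    return(data.table::data.table(pkey = character(), species = character()))
  }
  unique(out)
}

#' Focal gene pairs that are ortholog-neighbors in at least one species
#'
#' These are the only pairs that can be classified `conserved` or
#' `single_species`, so they form the candidate search space.
#'
#' @param annots Named list of non-focal [genome_annotation()] objects.
#' @param orthomap An [orthology_map()].
#' @return data.table with columns `gene_a`, `gene_b` (lexicographically
#'   ordered within each row), no duplicates.
#' @export
find_candidate_pairs <- function(annots, orthomap) {
  nb <- pair_neighbor_table(annots, orthomap)
  keys <- sort(unique(nb$pkey))
  if (!length(keys)) {
    return(data.table::data.table(gene_a = character(),
                                  gene_b = character()))
  }
  data.table::as.data.table(split_pair_key(keys))
}

# Per-gene eligibility: orthologs in at least
# ceiling(eligibility_fraction * |species universe|) species.
gene_eligibility <- function(orthomap, eligibility_fraction = 0.6) {
  need <- as.integer(ceiling(eligibility_fraction *
                               length(orthomap$species_universe)))
  counts <- rowSums(orthomap$presence)
  counts >= need
}

#' Classify every candidate pair's neighborhood conservation
#'
#' Batch version of [classify_pair()]: finds all candidate pairs and labels
#' each `conserved`, `single_species` or `other`.  A pair is `conserved`
#' when (i) each gene individually has orthologs in at least
#' `eligibility_fraction` of the non-focal species and (ii) its orthologs
#' are neighbors in at least [conservation_threshold()] of the appeared
#' species.  `single_species` pairs are ortholog-neighbors in exactly one
#' species (per-gene eligibility also enforced when
#' `necns_eligibility = TRUE`, the default, so the control group is
#' presence-matched).  `conserved` takes precedence when both definitions
#' hold (possible only at very low appeared counts).
#'
#' @param annots Named list of non-focal [genome_annotation()] objects.
#' @param orthomap An [orthology_map()].
#' @param eligibility_fraction Minimum fraction of non-focal species with an
#'   ortholog, per gene (default 0.6).
#' @param necns_eligibility Enforce per-gene eligibility for
#'   `single_species` pairs too (default `TRUE`).
#' @return data.table with columns `gene_a`, `gene_b`, `n_appeared`,
#'   `n_neighbor_species`, `neighbor_species` (comma-separated), `class`.
#' @export
classify_pairs <- function(annots, orthomap, eligibility_fraction = 0.6,
                           necns_eligibility = TRUE) {
  nb <- pair_neighbor_table(annots, orthomap)
  if (!nrow(nb)) {
    return(data.table::data.table(
      gene_a = character(), gene_b = character(), n_appeared = integer(),
      n_neighbor_species = integer(), neighbor_species = character(),
      class = character()))
  }
  species <- NULL  # appease R CMD check; data.table NSE
  agg <- nb[, list(n_neighbor_species = length(species),
                   neighbor_species = paste(sort(species), collapse = ",")),
            by = "pkey"]
  pairs <- split_pair_key(agg$pkey)
  gene_a <- pairs[, "gene_a"]
  gene_b <- pairs[, "gene_b"]
  pres <- orthomap$presence
  n_appeared <- rowSums(pres[gene_a, , drop = FALSE] &
                          pres[gene_b, , drop = FALSE])
  eligible <- gene_eligibility(orthomap, eligibility_fraction)
  elig_pair <- eligible[gene_a] & eligible[gene_b]
  threshold <- ceiling(n_appeared / 2)
  conserved <- elig_pair & agg$n_neighbor_species >= threshold &
    n_appeared >= 1
  single <- !conserved & agg$n_neighbor_species == 1L
  if (necns_eligibility) single <- single & elig_pair
  cls <- ifelse(conserved, "conserved",
                ifelse(single, "single_species", "other"))
  data.table::data.table(
    gene_a = gene_a, gene_b = gene_b,
    n_appeared = as.integer(n_appeared),
    n_neighbor_species = agg$n_neighbor_species,
    neighbor_species = agg$neighbor_species,
    class = cls
  )
}

#' Classify one focal gene pair's neighborhood conservation
#'
#' @inheritParams classify_pairs
#' @param gene_a,gene_b Focal gene IDs.
#' @return An object of class `pair_conservation` with fields `gene_a`,
#'   `gene_b`, `appeared` (species vector), `neighbor_species`,
#'   `conservation_class`.
#' @export
classify_pair <- function(gene_a, gene_b, orthomap, annots,
                          eligibility_fraction = 0.6,
                          necns_eligibility = TRUE) {
  app <- appeared_species(gene_a, gene_b, orthomap)
  nb <- app[vapply(app, function(s) {
    neighbors_in_species(gene_a, gene_b, s, orthomap, annots)
  }, logical(1L))]
  eligible <- gene_eligibility(orthomap, eligibility_fraction)
  elig_pair <- isTRUE(eligible[gene_a]) && isTRUE(eligible[gene_b])
  cls <- "other"
  if (length(app) >= 1 && elig_pair &&
      length(nb) >= conservation_threshold(length(app))) {
    cls <- "conserved"
  } else if (length(nb) == 1L && (elig_pair || !necns_eligibility)) {
    cls <- "single_species"
  }
  structure(
    list(gene_a = gene_a, gene_b = gene_b, appeared = app,
         neighbor_species = nb, conservation_class = cls),
    class = "pair_conservation"
  )
}

#' @export
print.pair_conservation <- function(x, ...) {
  cat(sprintf("pair_conservation: (%s, %s) — %s; neighbors in %d of %d appeared species\n",
              x$gene_a, x$gene_b, x$conservation_class,
              length(x$neighbor_species), length(x$appeared)))
  invisible(x)
}
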
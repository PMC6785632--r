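# Separation in the focal species and derivation of the two gene groups:
# ECNS (evolutionary-conserved neighbors separated) and NECNS
# (single-species neighbors separated, the presence-matched control).

#' Number of genes between two genes on the same chromosome
#'
#' @param annot Focal [genome_annotation()].
#' @param gene_a,gene_b Gene IDs present in `annot`.
#' @return `|index_a - index_b| - 1` when on the same chromosome,
#'   `NA_integer_` (undefined) otherwise.
#' @export
intervening_count <- function(annot, gene_a, gene_b) {
  stopifnot(inherits(annot, "genome_annotation"))
  gi <- annot$gene_index
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(gi)) stop("unknown gene: ", g, call. = FALSE)
  }
  if (gi[gene_a, "chrom"] != gi[gene_b, "chrom"]) return(NA_integer_)
  abs(gi[gene_a, "index"] - gi[gene_b, "index"]) - 1L
}

#' Is a gene pair separated in the focal species?
#'
#' Separated means on different chromosomes, or flanked by at least
#' `min_intervening` genes on the same chromosome.
#'
#' @inheritParams intervening_count
#' @param min_intervening Minimum intervening gene count (default 15).
#' @return Logical scalar.
#' @export
is_separated <- function(annot, gene_a, gene_b, min_intervening = 15L) {
  n <- intervening_count(annot, gene_a, gene_b)
  is.na(n) || n >= min_intervening
}

# Vectorized separation over pair columns; used by the batch derivations.
separated_vec <- function(annot, gene_a, gene_b, min_intervening = 15L) {
  gi <- annot$gene_index
  unknown <- setdiff(unique(c(gene_a, gene_b)), rownames(gi))
  if (length(unknown)) {
    stop("unknown gene: ", unknown[[1L]], call. = FALSE)
  }
  chrom_a <- gi[gene_a, "chrom"]
  chrom_b <- gi[gene_b, "chrom"]
  idx_a <- gi[gene_a, "index"]
  idx_b <- gi[gene_b, "index"]
  chrom_a != chrom_b | abs(idx_a - idx_b) - 1L >= min_intervening
}

#' Derive ECNS and NECNS gene groups from classified pairs
#'
#' Conserved-separated pairs are the `conserved` pairs passing
#' [is_separated()].  ECNS genes are the genes of those pairs, minus any
#' gene that also occurs in a conserved pair failing the separation
#' criterion (such a gene has not separated from all of its conserved
#' neighbors).  NECNS genes are the genes of `single_species` pairs passing
#' the separation criterion, minus any gene occurring in any conserved pair
#' at all.  Every exclusion is recorded.
#'
#' @param pair_classifications data.table as returned by [classify_pairs()].
#' @param focal_annot Focal [genome_annotation()].
#' @param min_intervening Separation threshold (default 15).
#' @param exclusion_mode `"separation"` (default): the ECNS exclusion set is
#'   genes in conserved pairs failing [is_separated()]; `"adjacent"`:
#'   stricter variant excluding only genes in conserved pairs still
#'   immediately adjacent in the focal species.
#' @return An object of class `group_assignment` with fields `ecns`,
#'   `necns`, `conserved_separated_pairs`, `single_separated_pairs`,
#'   `before_partners` (gene -> partner set), `exclusion_log`
#'   (gene -> reason).
#' @export
derive_groups <- function(pair_classifications, focal_annot,
                          min_intervening = 15L,
                          exclusion_mode = c("separation", "adjacent")) {
  exclusion_mode <- match.arg(exclusion_mode)
  pc <- data.table::as.data.table(pair_classifications)
  stopifnot(all(c("gene_a", "gene_b", "class") %in% names(pc)))
  if (nrow(pc)) {
    pc$separated <- separated_vec(focal_annot, pc$gene_a, pc$gene_b,
                                  min_intervening)
  } else {
    pc$separated <- logical(0)
  }
  cons <- pc[pc$class == "conserved"]
  single <- pc[pc$class == "single_species"]

  cons_sep <- cons[cons$separated]
  cons_nonsep <- cons[!cons$separated]
  if (exclusion_mode == "adjacent" && nrow(cons)) {
    adj <- vapply(seq_len(nrow(cons)), function(i) {
      n <- intervening_count(focal_annot, cons$gene_a[[i]], cons$gene_b[[i]])
      !is.na(n) && n == 0L
    }, logical(1L))
    cons_nonsep <- cons[adj]
  }

  ecns_candidates <- unique(c(cons_sep$gene_a, cons_sep$gene_b))
  ecns_excluded <- intersect(ecns_candidates,
                             unique(c(cons_nonsep$gene_a,
                                      cons_nonsep$gene_b)))
  ecns <- setdiff(ecns_candidates, ecns_excluded)

  single_sep <- single[single$separated]
  necns_candidates <- unique(c(single_sep$gene_a, single_sep$gene_b))
  conserved_genes <- unique(c(cons$gene_a, cons$gene_b))
  necns_excluded <- intersect(necns_candidates, conserved_genes)
  necns <- setdiff(necns_candidates, necns_excluded)

  exclusion_log <- c(
    stats::setNames(rep("in_conserved_pair_failing_separation",
                        length(ecns_excluded)), ecns_excluded),
    stats::setNames(rep("in_conserved_pair", length(necns_excluded)),
                    necns_excluded)
  )

  partner_map <- function(pairs, genes) {
    out <- stats::setNames(vector("list", length(genes)), genes)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[[i]]; b <- pairs$gene_b[[i]]
      if (a %in% genes) out[[a]] <- union(out[[a]], b)
      if (b %in% genes) out[[b]] <- union(out[[b]], a)
    }
    out
  }
  before_partners <- c(partner_map(cons_sep, ecns),
                       partner_map(single_sep, necns))

  stopifnot(length(intersect(ecns, necns)) == 0L)
  stopifnot(all(lengths(before_partners) > 0L))

  structure(
    list(ecns = sort(ecns), necns = sort(necns),
         conserved_separated_pairs =
           cons_sep[, c("gene_a", "gene_b"), with = FALSE],
         single_separated_pairs =
           single_sep[, c("gene_a", "gene_b"), with = FALSE],
         before_partners = before_partners,
         exclusion_log = exclusion_log,
         min_intervening = min_intervening,
         exclusion_mode = exclusion_mode),
    class = "group_assignment"
  )
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf(
    "group_assignment: %d ECNS, %d NECNS genes; %d conserved-separated, %d single-species-separated pairs; %d exclusions\n",
    length(x$ecns), length(x$necns), nrow(x$conserved_separated_pairs),
    nrow(x$single_separated_pairs), length(x$exclusion_log)))
  invisible(x)
}

#' Current neighbors of a group gene in the focal species
#'
#' The after-separation neighbors of an ECNS/NECNS gene are simply its
#' currently adjacent genes in the focal genome.
#'
#' @param group_gene Gene ID.
#' @param focal_annot Focal [genome_annotation()].
#' @return Character vector of at most two gene IDs.
#' @export
after_separation_neighbors <- function(group_gene, focal_annot) {
  adjacent_neighbors(focal_annot, group_gene)
}

#' Before/after-separation cross pairs of a gene group
#'
#' For each group gene, pairs every before-separation partner with every
#' current (after-separation) neighbor.  Pairs where both members coincide,
#' pairs adjacent in the focal species, and pairs whose orthologs are
#' adjacent in any non-focal species are dropped (neighbor pairs in any one
#' species are excluded).  Identical (before, after) pairs arising from
#' different source genes are kept in the audit table; use
#' [unique_cross_pairs()] for deduplicated frequency statistics.
#'
#' @param assignment A [derive_groups()] result.
#' @param group `"ecns"` or `"necns"`.
#' @param focal_annot Focal [genome_annotation()].
#' @param orthomap An [orthology_map()].
#' @param annots Named list of non-focal [genome_annotation()] objects.
#' @return data.table with columns `before_gene`, `after_gene`,
#'   `source_gene`, `group` (one row per source gene, i.e. with
#'   multiplicity).
#' @export
cross_pairs <- function(assignment, group = c("ecns", "necns"), focal_annot,
                        orthomap, annots) {
  group <- match.arg(group)
  stopifnot(inherits(assignment, "group_assignment"))
  genes <- assignment[[group]]
  rows <- lapply(genes, function(g) {
    before <- assignment$before_partners[[g]]
    after <- after_separation_neighbors(g, focal_annot)
    if (!length(before) || !length(after)) return(NULL)
    grid <- expand.grid(before_gene = before, after_gene = after,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$before_gene != grid$after_gene, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    grid$source_gene <- g
    grid
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    return(data.table::data.table(before_gene = character(),
                                  after_gene = character(),
                                  source_gene = character(),
                                  group = character()))
  }
  # Drop pairs that are neighbors in the focal species...
  iv <- vapply(seq_len(nrow(out)), function(i) {
    n <- intervening_count(focal_annot, out$before_gene[[i]],
                           out$after_gene[[i]])
    !is.na(n) && n == 0L
  }, logical(1L))
  out <- out[!iv]
  # ...or ortholog-neighbors in any non-focal species.
  if (nrow(out)) {
    nb <- pair_neighbor_table(annots, orthomap)
    keys <- pair_key(out$before_gene, out$after_gene)
    out <- out[!keys %in% nb$pkey]
  }
  out$group <- group
  out[]
}

#' Deduplicate cross pairs, recording multiplicity
#'
#' @param cp A [cross_pairs()] table.
#' @return data.table with columns `before_gene`, `after_gene`,
#'   `multiplicity` (number of source genes yielding the pair); one row per
#'   distinct unordered pair.
#' @export
unique_cross_pairs <- function(cp) {
  cp <- data.table::as.data.table(cp)
  if (!nrow(cp)) {
    return(data.table::data.table(before_gene = character(),
                                  after_gene = character(),
                                  multiplicity = integer()))
  }
  key <- pair_key(cp$before_gene, cp$after_gene)
  tab <- table(key)
  mat <- split_pair_key(names(tab))
  data.table::data.table(before_gene = mat[, "gene_a"],
                         after_gene = mat[, "gene_b"],
                         multiplicity = as.integer(tab))
}

#' Fraction of a gene set falling in a reference set
#'
#' @param genes Non-empty character vector (deduplicated internally).
#' @param reference Character vector.
#' @return `|genes intersect reference| / |genes|`.
#' @export
set_fraction <- function(genes, reference) {
  genes <- unique(genes)
  if (!length(genes)) stop("`genes` must be non-empty", call. = FALSE)
  length(intersect(genes, reference)) / length(genes)
}
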
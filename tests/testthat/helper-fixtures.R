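# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# A small annotation from a compact spec: chroms is a named list of gene
# vectors in chromosomal order.
make_annotation <- function(chroms, species_id = "test") {
  rows <- lapply(names(chroms), function(k) {
    v <- chroms[[k]]
    data.frame(gene = v, chrom = k, start = seq_along(v) * 100L,
               end = seq_along(v) * 100L + 50L, strand = "+",
               stringsAsFactors = FALSE)
  })
  genome_annotation(do.call(rbind, rows), species_id)
}

# Orthology map in which each focal gene g maps 1:1 to "<sp>_<g>" in every
# species where `present[[sp]]` contains it.
make_orthomap <- function(present, focal = "sp00") {
  rows <- do.call(rbind, lapply(names(present), function(s) {
    g <- present[[s]]
    if (!length(g)) return(NULL)
    data.frame(focal_gene = g, species = s,
               ortholog_gene = paste0(s, "_", g), stringsAsFactors = FALSE)
  }))
  orthology_map(rows, focal, species_universe = names(present))
}

# Prefixed copy of an annotation spec for a non-focal species.
prefix_chroms <- function(chroms, sp) {
  lapply(chroms, function(v) paste0(sp, "_", v))
}

# Small synthetic configuration used where full default scale is not
# needed; study-condition parameters (loss, thresholds, rho, enrichment)
# keep their defaults.
small_config <- function(seed, ...) {
  args <- list(genes_per_genome = 300L, n_chromosomes = 10L,
               n_planted_ecns_pairs = 10L,
               n_planted_single_species_pairs = 10L,
               n_conditions = 20L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

# Rank-then-Pearson Spearman oracle (independent of the implementation).
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# Brute-force Mann-Whitney U oracle: count a_i > b_j pairs plus half-ties.
u_oracle <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}
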
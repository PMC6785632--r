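# Multi-species synthetic data generator with planted ground truth.
#
# Layout strategy: all species share a fixed "backbone" gene order derived
# from a common ancestor.  Planted genes live outside the backbone and are
# inserted at backbone junctions ("slots"):
#   * a conserved-separated unit [a, b] is inserted adjacently in every
#     non-focal species, reusing each insertion slot in 2 (or 3) species so
#     that the incidental flank adjacencies are shared by too few species
#     to count as conserved and too many to count as single-species;
#   * a single-species unit [c, d] is adjacent only in one designated
#     species (appended at a chromosome tail, whose single flank adjacency
#     is repeated in a second species), with both genes inserted separately
#     elsewhere in all remaining species;
#   * in the focal species every planted gene is inserted at its own slot,
#     pair members on different chromosomes, i.e. separated.
# Gene loss and random inversions/translocations are then applied as noise
# (planted genes are exempt from loss, and rearrangement breakpoints that
# would break a planted adjacency or separation are rejected), so that with
# zero noise the pipeline must recover the planted truth exactly.

#' Configuration for the synthetic multi-species dataset
#'
#' @param n_species Total species count, first one focal (default 11).
#'   At least 8, so incidental flank adjacencies can never reach the
#'   conservation threshold.
#' @param genes_per_genome Genes per genome including planted genes
#'   (default 800).
#' @param n_chromosomes Chromosomes per genome (default 16, yeast-like).
#' @param loss_rate Per-gene, per-species probability that a backbone gene
#'   has no ortholog in a non-focal species (default 0.1).
#' @param rearrangement_events Random inversions/translocations applied to
#'   every species (default 3).
#' @param n_planted_ecns_pairs Conserved-but-separated pair count
#'   (default 30).
#' @param n_planted_single_species_pairs Single-species separated pair
#'   count (default 30).
#' @param coexpression_rho Latent Pearson correlation planted on designated
#'   cross pairs (default 0.4).
#' @param n_conditions Base expression conditions; each is emitted in two
#'   replicates (default 50).
#' @param noise_sd Replicate-level noise standard deviation (default 0.1).
#' @param interspecies_sd Species-level expression noise standard deviation
#'   (default 0.5).
#' @param cofeature_background Probability that a random gene pair shares a
#'   feature (default 0.05).
#' @param cofeature_enrichment Probability that a planted cross pair is
#'   given a shared feature / interaction edge (default 0.5).
#' @param n_tf_sets,n_cc_sets Number of TF-target / cellular-component sets
#'   (default 25 each).
#' @param essential_rates Essentiality probabilities for ECNS, NECNS and
#'   remaining genes (defaults 0.22, 0.07, 0.16).
#' @param min_intervening Separation threshold used when planting
#'   (default 15).
#' @param seed Mandatory RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_species = 11L,
                         genes_per_genome = 800L,
                         n_chromosomes = 16L,
                         loss_rate = 0.1,
                         rearrangement_events = 3L,
                         n_planted_ecns_pairs = 30L,
                         n_planted_single_species_pairs = 30L,
                         coexpression_rho = 0.4,
                         n_conditions = 50L,
                         noise_sd = 0.1,
                         interspecies_sd = 0.5,
                         cofeature_background = 0.05,
                         cofeature_enrichment = 0.5,
                         n_tf_sets = 25L,
                         n_cc_sets = 25L,
                         essential_rates = c(ecns = 0.22, necns = 0.07,
                                             other = 0.16),
                         min_intervening = 15L,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  probs <- c(loss_rate, coexpression_rho, cofeature_background,
             cofeature_enrichment, essential_rates)
  if (any(probs < 0 | probs > 1)) {
    stop("rates/probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(n_species, genes_per_genome, n_chromosomes, n_conditions)
  if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
  if (n_species < 8L) {
    # With fewer than 7 non-focal species, spreading a planted gene over an
    # odd species count forces an insertion context shared by 3 species,
    # which would reach the conservation threshold ceiling(6 / 2) = 3.
    stop("`n_species` must be at least 8", call. = FALSE)
  }
  if (!all(c("ecns", "necns", "other") %in% names(essential_rates))) {
    stop("`essential_rates` must name ecns, necns and other", call. = FALSE)
  }
  structure(
    list(n_species = as.integer(n_species),
         genes_per_genome = as.integer(genes_per_genome),
         n_chromosomes = as.integer(n_chromosomes),
         loss_rate = loss_rate,
         rearrangement_events = as.integer(rearrangement_events),
         n_planted_ecns_pairs = as.integer(n_planted_ecns_pairs),
         n_planted_single_species_pairs =
           as.integer(n_planted_single_species_pairs),
         coexpression_rho = coexpression_rho,
         n_conditions = as.integer(n_conditions),
         noise_sd = noise_sd,
         interspecies_sd = interspecies_sd,
         cofeature_background = cofeature_background,
         cofeature_enrichment = cofeature_enrichment,
         n_tf_sets = as.integer(n_tf_sets),
         n_cc_sets = as.integer(n_cc_sets),
         essential_rates = essential_rates,
         min_intervening = as.integer(min_intervening),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Split a species vector into groups of 2 (plus one group of 3 when odd).
partition_species <- function(species) {
  n <- length(species)
  stopifnot(n >= 2L)
  groups <- list()
  i <- 1L
  if (n %% 2L == 1L) {
    groups[[1L]] <- species[1:3]
    i <- 4L
  }
  while (i <= n) {
    groups[[length(groups) + 1L]] <- species[c(i, i + 1L)]
    i <- i + 2L
  }
  groups
}

# Position lookup for a genome represented as a chrom -> gene-vector list.
genome_positions <- function(genome) {
  chrom <- rep(names(genome), lengths(genome))
  pos <- unlist(lapply(genome, seq_along), use.names = FALSE)
  genes <- unlist(genome, use.names = FALSE)
  list(chrom = stats::setNames(chrom, genes),
       pos = stats::setNames(pos, genes))
}

adjacency_ok <- function(posmap, a, b) {
  !is.na(posmap$chrom[a]) && !is.na(posmap$chrom[b]) &&
    posmap$chrom[[a]] == posmap$chrom[[b]] &&
    abs(posmap$pos[[a]] - posmap$pos[[b]]) == 1L
}

separation_ok <- function(posmap, a, b, min_intervening) {
  posmap$chrom[[a]] != posmap$chrom[[b]] ||
    abs(posmap$pos[[a]] - posmap$pos[[b]]) - 1L >= min_intervening
}

# One random rearrangement event (inversion or segment translocation).
random_event <- function(genome) {
  type <- sample(c("inversion", "translocation"), 1L)
  lens <- lengths(genome)
  if (type == "translocation" && length(genome) < 2L) type <- "inversion"
  if (type == "inversion") {
    eligible <- names(genome)[lens >= 2L]
    if (!length(eligible)) return(genome)
    k <- sample(eligible, 1L)
    v <- genome[[k]]
    ij <- sort(sample.int(length(v), 2L))
    genome[[k]] <- c(v[seq_len(ij[1L] - 1L)], rev(v[ij[1L]:ij[2L]]),
                     v[seq_len(length(v) - ij[2L]) + ij[2L]])
  } else {
    eligible <- names(genome)[lens >= 1L]
    src <- sample(eligible, 1L)
    v <- genome[[src]]
    seg_len <- sample.int(min(5L, length(v)), 1L)
    i <- sample.int(length(v) - seg_len + 1L, 1L)
    seg <- v[i:(i + seg_len - 1L)]
    genome[[src]] <- v[-(i:(i + seg_len - 1L))]
    tgt <- sample(setdiff(names(genome), src), 1L)
    w <- genome[[tgt]]
    at <- sample.int(length(w) + 1L, 1L) - 1L
    genome[[tgt]] <- append(w, seg, after = at)
  }
  genome
}

# Apply `n_events` random events, rejecting any event that breaks a
# required planted adjacency, creates a forbidden one, or (focal genome)
# un-separates a planted pair.
apply_rearrangements <- function(genome, n_events, required_adj,
                                 forbidden_adj, separated_pairs,
                                 min_intervening, max_tries = 30L) {
  constraints_ok <- function(g) {
    pm <- genome_positions(g)
    for (p in required_adj) {
      if (!adjacency_ok(pm, p[[1L]], p[[2L]])) return(FALSE)
    }
    for (p in forbidden_adj) {
      if (adjacency_ok(pm, p[[1L]], p[[2L]])) return(FALSE)
    }
    for (p in separated_pairs) {
      if (!separation_ok(pm, p[[1L]], p[[2L]], min_intervening)) {
        return(FALSE)
      }
    }
    TRUE
  }
  for (e in seq_len(n_events)) {
    for (try in seq_len(max_tries)) {
      cand <- random_event(genome)
      if (constraints_ok(cand)) {
        genome <- cand
        break
      }
    }
  }
  genome
}

#' Simulate multi-species genomes with planted neighborhood structure
#'
#' See the package vignette for the construction.  With
#' `loss_rate = 0` and `rearrangement_events = 0` the planted
#' conserved-separated and single-species pairs are, by construction, the
#' only such pairs the identification pipeline can find.
#'
#' @param config A [synth_config()].
#' @return List with `annotations` (named list of [genome_annotation()],
#'   focal species first), `orthomap` (an [orthology_map()]), `truth` (a
#'   `synth_truth` object) and `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, simulate_genomes_impl(config))
}

simulate_genomes_impl <- function(config) {
  n_sp <- config$n_species
  sp <- sprintf("sp%02d", seq_len(n_sp) - 1L)
  focal <- sp[[1L]]
  nonfocal <- sp[-1L]
  G <- config$genes_per_genome
  K <- config$n_chromosomes
  nE <- config$n_planted_ecns_pairs
  nN <- config$n_planted_single_species_pairs

  n_planted <- 2L * (nE + nN)
  if (G - n_planted < K * 6L) {
    stop("infeasible planting: too few backbone genes (",
         G - n_planted, ") for ", K, " chromosomes", call. = FALSE)
  }
  ids <- sprintf("g%04d", seq_len(G))
  planted <- sample(ids, n_planted)
  ecns_units <- if (nE) matrix(planted[seq_len(2L * nE)], ncol = 2L,
                               byrow = TRUE) else matrix(character(), ncol = 2L)
  necns_units <- if (nN) matrix(planted[2L * nE + seq_len(2L * nN)],
                                ncol = 2L, byrow = TRUE) else
    matrix(character(), ncol = 2L)
  backbone_ids <- setdiff(ids, planted)
  chroms <- sprintf("chr%02d", seq_len(K))
  assignment <- rep(chroms, each = ceiling(length(backbone_ids) / K))
  backbone <- split(backbone_ids, assignment[seq_along(backbone_ids)])
  backbone <- backbone[chroms[chroms %in% names(backbone)]]

  # Global slot pool: one row per backbone junction; each slot is consumed
  # by at most one planted placement context across the whole simulation.
  slot_list <- lapply(names(backbone), function(k) {
    v <- backbone[[k]]
    if (length(v) < 2L) return(NULL)
    data.frame(chrom = k, pos = seq_len(length(v) - 1L),
               g1 = v[-length(v)], g2 = v[-1L], stringsAsFactors = FALSE)
  })
  slots <- do.call(rbind, slot_list)
  slots$avail <- TRUE

  draw_slot <- function(avoid_genes, avoid_chroms = character(0)) {
    ok <- slots$avail & !(slots$g1 %in% avoid_genes) &
      !(slots$g2 %in% avoid_genes) & !(slots$chrom %in% avoid_chroms)
    idx <- which(ok)
    if (!length(idx)) {
      stop("infeasible planting: slot pool exhausted", call. = FALSE)
    }
    i <- idx[[sample.int(length(idx), 1L)]]
    slots$avail[i] <<- FALSE
    slots[i, , drop = FALSE]
  }

  # Per-species placement records.
  insertions <- stats::setNames(
    lapply(sp, function(s) list()), sp)
  tails <- stats::setNames(lapply(sp, function(s) list()), sp)
  tail_used <- matrix(FALSE, nrow = n_sp, ncol = K,
                      dimnames = list(sp, chroms))
  add_insertion <- function(s, slot, genes) {
    insertions[[s]][[length(insertions[[s]]) + 1L]] <<-
      list(chrom = slot$chrom, pos = slot$pos, genes = genes)
  }

  place_focal_pair <- function(g1, g2, used) {
    s1 <- draw_slot(used)
    used <- c(used, s1$g1, s1$g2)
    s2 <- draw_slot(used, avoid_chroms = s1$chrom)
    add_insertion(focal, s1, g1)
    add_insertion(focal, s2, g2)
    c(used, s2$g1, s2$g2)
  }

  for (u in seq_len(nE)) {
    a <- ecns_units[u, 1L]; b <- ecns_units[u, 2L]
    used <- character(0)
    for (grp in partition_species(sample(nonfocal))) {
      slot <- draw_slot(used)
      used <- c(used, slot$g1, slot$g2)
      for (s in grp) add_insertion(s, slot, c(a, b))
    }
    place_focal_pair(a, b, used)
  }

  necns_star <- character(nN)
  for (u in seq_len(nN)) {
    cg <- necns_units[u, 1L]; dg <- necns_units[u, 2L]
    used <- character(0)
    # Tail placement: [c, d] at a chromosome tail in s_star; c alone at the
    # same tail in s2, so the single flank adjacency is shared by 2 species.
    placed <- FALSE
    for (pair_try in sample(length(nonfocal) * (length(nonfocal) - 1L))) {
      cand <- sample(nonfocal, 2L)
      free <- chroms[!tail_used[cand[[1L]], ] & !tail_used[cand[[2L]], ] &
                       lengths(backbone)[chroms] >= 2L]
      if (length(free)) {
        k <- if (length(free) == 1L) free else sample(free, 1L)
        s_star <- cand[[1L]]; s2 <- cand[[2L]]
        tails[[s_star]][[length(tails[[s_star]]) + 1L]] <-
          list(chrom = k, genes = c(cg, dg))
        tails[[s2]][[length(tails[[s2]]) + 1L]] <-
          list(chrom = k, genes = cg)
        tail_used[s_star, k] <- TRUE
        tail_used[s2, k] <- TRUE
        tail_gene <- backbone[[k]][[length(backbone[[k]])]]
        used <- c(used, tail_gene)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible planting: no free chromosome tail for ",
           "single-species pair ", u, call. = FALSE)
    }
    necns_star[[u]] <- s_star
    for (grp in partition_species(sample(setdiff(nonfocal,
                                                 c(s_star, s2))))) {
      slot <- draw_slot(used)
      used <- c(used, slot$g1, slot$g2)
      for (s in grp) add_insertion(s, slot, cg)
    }
    for (grp in partition_species(sample(setdiff(nonfocal, s_star)))) {
      slot <- draw_slot(used)
      used <- c(used, slot$g1, slot$g2)
      for (s in grp) add_insertion(s, slot, dg)
    }
    place_focal_pair(cg, dg, used)
  }

  # Assemble genomes: backbone + insertions (descending position) + tails.
  genomes <- stats::setNames(lapply(sp, function(s) {
    genome <- backbone
    ins <- insertions[[s]]
    if (length(ins)) {
      by_chrom <- split(ins, vapply(ins, `[[`, character(1L), "chrom"))
      for (k in names(by_chrom)) {
        recs <- by_chrom[[k]]
        ord <- order(vapply(recs, `[[`, numeric(1L), "pos"),
                     decreasing = TRUE)
        for (r in recs[ord]) {
          genome[[k]] <- append(genome[[k]], r$genes, after = r$pos)
        }
      }
    }
    for (tl in tails[[s]]) {
      genome[[tl$chrom]] <- c(genome[[tl$chrom]], tl$genes)
    }
    genome
  }), sp)

  # Gene loss (backbone genes only; planted genes are exempt so the
  # planted structure is guaranteed consistent).
  if (config$loss_rate > 0) {
    for (s in nonfocal) {
      lost <- backbone_ids[stats::runif(length(backbone_ids)) <
                             config$loss_rate]
      if (length(lost)) {
        genomes[[s]] <- lapply(genomes[[s]], function(v) v[!v %in% lost])
      }
    }
  }

  # Rearrangement noise under planted-structure constraints.
  ecns_pairs <- lapply(seq_len(nE), function(u) ecns_units[u, ])
  necns_pairs <- lapply(seq_len(nN), function(u) necns_units[u, ])
  if (config$rearrangement_events > 0L) {
    for (s in sp) {
      if (s == focal) {
        required <- list()
        forbidden <- list()
        sep_pairs <- c(ecns_pairs, necns_pairs)
      } else {
        required <- c(ecns_pairs,
                      necns_pairs[necns_star == s])
        forbidden <- necns_pairs[necns_star != s]
        sep_pairs <- list()
      }
      genomes[[s]] <- apply_rearrangements(
        genomes[[s]], config$rearrangement_events, required, forbidden,
        sep_pairs, config$min_intervening)
    }
  }

  # Annotations (species-local gene IDs are prefixed outside the focal
  # species) and the orthology map recording descent.
  annotations <- stats::setNames(lapply(sp, function(s) {
    genome <- genomes[[s]]
    rows <- lapply(names(genome), function(k) {
      v <- genome[[k]]
      if (!length(v)) return(NULL)
      local_ids <- if (s == focal) v else paste0(s, "_", v)
      n <- length(v)
      data.frame(gene = local_ids, chrom = k,
                 start = seq_len(n) * 1000L,
                 end = seq_len(n) * 1000L + 500L,
                 strand = "+", stringsAsFactors = FALSE)
    })
    genome_annotation(do.call(rbind, rows), species_id = s)
  }), sp)

  ortho_rows <- data.table::rbindlist(lapply(nonfocal, function(s) {
    present <- unlist(genomes[[s]], use.names = FALSE)
    data.table::data.table(focal_gene = present, species = s,
                           ortholog_gene = paste0(s, "_", present))
  }))
  orthomap <- orthology_map(ortho_rows, focal_species = focal,
                            species_universe = nonfocal)

  truth <- build_truth(config, annotations[[focal]], ecns_units,
                       necns_units, necns_star, focal, sp)
  check_truth(truth, annotations, orthomap, config)

  list(annotations = annotations, orthomap = orthomap, truth = truth,
       config = config)
}

# Planted truth, including the before/after cross pairs implied by the
# final focal gene order.
build_truth <- function(config, focal_annot, ecns_units, necns_units,
                        necns_star, focal, sp) {
  pair_dt <- function(m) {
    if (!nrow(m)) {
      return(data.table::data.table(gene_a = character(),
                                    gene_b = character()))
    }
    data.table::data.table(gene_a = pmin(m[, 1L], m[, 2L]),
                           gene_b = pmax(m[, 1L], m[, 2L]))
  }
  cross_of_units <- function(units) {
    rows <- list()
    for (u in seq_len(nrow(units))) {
      a <- units[u, 1L]; b <- units[u, 2L]
      for (g in c(a, b)) {
        partner <- if (g == a) b else a
        for (nbr in adjacent_neighbors(focal_annot, g)) {
          if (nbr != partner) {
            rows[[length(rows) + 1L]] <-
              data.table::data.table(before_gene = partner,
                                     after_gene = nbr, source_gene = g)
          }
        }
      }
    }
    out <- data.table::rbindlist(rows)
    if (!nrow(out)) {
      out <- data.table::data.table(before_gene = character(),
                                    after_gene = character(),
                                    source_gene = character())
    }
    out
  }
  ecns_cross <- cross_of_units(ecns_units)
  necns_cross <- cross_of_units(necns_units)

  # One disjoint coexpressed pair per conserved-separated unit: the
  # before-partner paired with the first after-neighbor of the other gene.
  used <- character(0)
  coex <- list()
  for (u in seq_len(nrow(ecns_units))) {
    a <- ecns_units[u, 1L]; b <- ecns_units[u, 2L]
    nbrs <- adjacent_neighbors(focal_annot, a)
    nbrs <- setdiff(nbrs, c(b, used))
    if (b %in% used || !length(nbrs)) next
    coex[[length(coex) + 1L]] <-
      data.table::data.table(gene_a = b, gene_b = nbrs[[1L]],
                             rho = config$coexpression_rho)
    used <- c(used, b, nbrs[[1L]])
  }
  coex_dt <- data.table::rbindlist(coex)
  if (!nrow(coex_dt)) {
    coex_dt <- data.table::data.table(gene_a = character(),
                                      gene_b = character(), rho = numeric())
  }

  structure(
    list(focal_species = focal, species = sp,
         ecns_pairs = pair_dt(ecns_units),
         single_species_pairs =
           cbind(pair_dt(necns_units),
                 data.table::data.table(species = necns_star)),
         ecns_genes = sort(as.vector(ecns_units)),
         necns_genes = sort(as.vector(necns_units)),
         ecns_cross_pairs = ecns_cross,
         necns_cross_pairs = necns_cross,
         coexpressed_pairs = coex_dt,
         cofeature_pairs = unique(
           ecns_cross[, c("before_gene", "after_gene"), with = FALSE])),
    class = "synth_truth"
  )
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(
    "synth_truth: %d conserved-separated pairs (%d genes), %d single-species pairs (%d genes), %d cross pairs, %d coexpressed pairs\n",
    nrow(x$ecns_pairs), length(x$ecns_genes),
    nrow(x$single_species_pairs), length(x$necns_genes),
    nrow(x$cofeature_pairs), nrow(x$coexpressed_pairs)))
  invisible(x)
}

# Consistency check run on every emission: planted pairs really are
# separated in the focal species, conserved pairs adjacent in at least the
# threshold number of appeared species, single-species pairs in exactly one.
check_truth <- function(truth, annotations, orthomap, config) {
  focal_annot <- annotations[[truth$focal_species]]
  nf_annots <- annotations[names(annotations) != truth$focal_species]
  for (i in seq_len(nrow(truth$ecns_pairs))) {
    a <- truth$ecns_pairs$gene_a[[i]]; b <- truth$ecns_pairs$gene_b[[i]]
    if (!is_separated(focal_annot, a, b, config$min_intervening)) {
      stop("synthetic truth inconsistent: planted conserved pair (", a,
           ", ", b, ") not separated in the focal species", call. = FALSE)
    }
    app <- appeared_species(a, b, orthomap)
    nb <- sum(vapply(app, function(s) {
      neighbors_in_species(a, b, s, orthomap, nf_annots)
    }, logical(1L)))
    if (nb < conservation_threshold(length(app))) {
      stop("synthetic truth inconsistent: planted conserved pair (", a,
           ", ", b, ") adjacent in only ", nb, " of ", length(app),
           " appeared species", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(truth$single_species_pairs))) {
    a <- truth$single_species_pairs$gene_a[[i]]
    b <- truth$single_species_pairs$gene_b[[i]]
    if (!is_separated(focal_annot, a, b, config$min_intervening)) {
      stop("synthetic truth inconsistent: planted single-species pair (",
           a, ", ", b, ") not separated in the focal species",
           call. = FALSE)
    }
    nb <- sum(vapply(orthomap$species_universe, function(s) {
      neighbors_in_species(a, b, s, orthomap, nf_annots)
    }, logical(1L)))
    if (nb != 1L) {
      stop("synthetic truth inconsistent: planted single-species pair (",
           a, ", ", b, ") adjacent in ", nb, " species", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate per-species expression matrices
#'
#' Every gene has a latent condition profile shared by its orthologs;
#' planted coexpressed pairs share a latent factor with weight
#' `sqrt(rho)`.  Species-level noise (`interspecies_sd`) and
#' replicate-level noise (`noise_sd`) are added on top, and each condition
#' is emitted in two replicate columns (`<cond>.r1`, `<cond>.r2`).
#'
#' @param config A [synth_config()].
#' @param truth A `synth_truth` from [simulate_genomes()].
#' @param annotations Per-species annotations from [simulate_genomes()].
#' @param orthomap The [orthology_map()] from [simulate_genomes()].
#' @return Named list of [expression_matrix()] objects.
#' @export
simulate_expression <- function(config, truth, annotations, orthomap) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 1L, {
    focal <- truth$focal_species
    base_conds <- sprintf("c%03d", seq_len(config$n_conditions))
    cols <- as.vector(rbind(paste0(base_conds, ".r1"),
                            paste0(base_conds, ".r2")))
    focal_genes <- annotations[[focal]]$gene_index$gene
    latent <- matrix(stats::rnorm(length(focal_genes) *
                                    config$n_conditions),
                     nrow = length(focal_genes),
                     dimnames = list(focal_genes, base_conds))
    cp <- truth$coexpressed_pairs
    for (i in seq_len(nrow(cp))) {
      rho <- cp$rho[[i]]
      f <- stats::rnorm(config$n_conditions)
      for (g in c(cp$gene_a[[i]], cp$gene_b[[i]])) {
        latent[g, ] <- sqrt(rho) * f +
          sqrt(1 - rho) * stats::rnorm(config$n_conditions)
      }
    }
    mats <- lapply(names(annotations), function(s) {
      local_ids <- annotations[[s]]$gene_index$gene
      bare <- if (s == focal) local_ids else sub("^[^_]+_", "", local_ids)
      prof <- latent[bare, , drop = FALSE] +
        matrix(stats::rnorm(length(bare) * config$n_conditions,
                            sd = config$interspecies_sd),
               nrow = length(bare))
      vals <- matrix(NA_real_, nrow = length(bare), ncol = length(cols),
                     dimnames = list(local_ids, cols))
      for (j in seq_along(base_conds)) {
        for (r in 1:2) {
          vals[, 2L * (j - 1L) + r] <- prof[, j] +
            stats::rnorm(length(bare), sd = config$noise_sd)
        }
      }
      expression_matrix(vals, species_id = s,
                        replicate_groups = infer_replicate_groups(cols))
    })
    stats::setNames(mats, names(annotations))
  })
}

#' Simulate feature sets and interaction networks
#'
#' Background TF-target and cellular-component memberships are drawn so a
#' random gene pair shares a set with probability `cofeature_background`;
#' each planted cross pair additionally receives a shared set / an
#' interaction edge of each type with probability `cofeature_enrichment`.
#' Essentiality is drawn per group (`essential_rates`).
#'
#' @param config A [synth_config()].
#' @param truth A `synth_truth`.
#' @param gene_universe Focal gene IDs.
#' @return List with elements `tf_targets`, `cellular_component`,
#'   `essential` (all [gene_set_collection()]) and `network`
#'   (an [interaction_network()]).
#' @export
simulate_features <- function(config, truth, gene_universe) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 2L, {
    planted <- truth$cofeature_pairs
    make_sets <- function(n_sets, prefix) {
      p <- sqrt(1 - (1 - config$cofeature_background)^(1 / n_sets))
      sets <- lapply(seq_len(n_sets), function(i) {
        gene_universe[stats::runif(length(gene_universe)) < p]
      })
      names(sets) <- sprintf("%s%03d", prefix, seq_len(n_sets))
      for (i in seq_len(nrow(planted))) {
        if (stats::runif(1L) < config$cofeature_enrichment) {
          t <- sample.int(n_sets, 1L)
          sets[[t]] <- union(sets[[t]],
                             c(planted$before_gene[[i]],
                               planted$after_gene[[i]]))
        }
      }
      sets[lengths(sets) > 0L]
    }
    tf <- gene_set_collection(make_sets(config$n_tf_sets, "TF"),
                              kind = "tf_targets")
    cc <- gene_set_collection(make_sets(config$n_cc_sets, "CC"),
                              kind = "cellular_component")

    rates <- config$essential_rates
    r <- rep(rates[["other"]], length(gene_universe))
    r[gene_universe %in% truth$ecns_genes] <- rates[["ecns"]]
    r[gene_universe %in% truth$necns_genes] <- rates[["necns"]]
    essential_genes <- gene_universe[stats::runif(length(gene_universe)) < r]
    ess <- gene_set_collection(list(essential = essential_genes),
                               kind = "essential")

    n_bg <- round(config$cofeature_background *
                    choose(length(gene_universe), 2))
    edge_rows <- lapply(INTERACTION_TYPES, function(ty) {
      i <- sample(gene_universe, n_bg, replace = TRUE)
      j <- sample(gene_universe, n_bg, replace = TRUE)
      keep <- i != j
      bg <- data.table::data.table(gene_a = i[keep], gene_b = j[keep],
                                   type = ty)
      pl <- planted[stats::runif(nrow(planted)) <
                      config$cofeature_enrichment]
      if (nrow(pl)) {
        bg <- rbind(bg, data.table::data.table(gene_a = pl$before_gene,
                                               gene_b = pl$after_gene,
                                               type = ty))
      }
      bg
    })
    network <- interaction_network(data.table::rbindlist(edge_rows))
    list(tf_targets = tf, cellular_component = cc, essential = ess,
         network = network)
  })
}

#' Simulate a complete synthetic dataset
#'
#' @param config A [synth_config()].
#' @return List with `annotations`, `orthomap`, `truth`, `expression`,
#'   `features` and `config`.
#' @export
simulate_dataset <- function(config) {
  gen <- simulate_genomes(config)
  expr <- simulate_expression(config, gen$truth, gen$annotations,
                              gen$orthomap)
  feats <- simulate_features(config, gen$truth,
                             gen$annotations[[gen$truth$focal_species]]$gene_index$gene)
  c(gen, list(expression = expr, features = feats))
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits one annotation TSV and one expression TSV per species, the
#' long-format orthology TSV, GMT files for the three gene-set kinds, the
#' interaction TSV and a machine-readable `truth.json`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(dataset$annotations)) {
    write_annotation(dataset$annotations[[s]],
                     file.path(dir, paste0("annotation_", s, ".tsv")))
    write_expression(dataset$expression[[s]],
                     file.path(dir, paste0("expression_", s, ".tsv")))
  }
  write_orthology(dataset$orthomap, file.path(dir, "orthology.tsv"))
  write_gene_sets(dataset$features$tf_targets,
                  file.path(dir, "tf_targets.gmt"))
  write_gene_sets(dataset$features$cellular_component,
                  file.path(dir, "cellular_component.gmt"))
  write_gene_sets(dataset$features$essential,
                  file.path(dir, "essential.gmt"))
  write_interactions(dataset$features$network,
                     file.path(dir, "interactions.tsv"))
  truth <- dataset$truth
  truth_json <- list(
    focal_species = truth$focal_species, species = truth$species,
    ecns_pairs = truth$ecns_pairs,
    single_species_pairs = truth$single_species_pairs,
    ecns_genes = truth$ecns_genes, necns_genes = truth$necns_genes,
    ecns_cross_pairs = truth$ecns_cross_pairs,
    necns_cross_pairs = truth$necns_cross_pairs,
    coexpressed_pairs = truth$coexpressed_pairs,
    cofeature_pairs = truth$cofeature_pairs
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE)
  invisible(dir)
}
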
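# Co-feature frequencies for gene pairs and the chromosome-matched
# randomization test.
#
# The null model replaces every distinct gene occurring in the pair list
# with a uniformly drawn gene from the same chromosome (never the gene
# itself), applies that one mapping to all pairs, and recomputes the
# co-feature frequency; the empirical P value is the fraction of
# randomizations whose frequency is strictly higher than the observed one.
# Because a strictly-greater count can legitimately be zero, the add-one
# estimate (k + 1) / (n_iter + 1) is always reported alongside.

# Normalize a pair argument to a two-column character matrix.
as_pair_matrix <- function(pairs) {
  if (is.matrix(pairs) && ncol(pairs) >= 2L) {
    return(cbind(as.character(pairs[, 1L]), as.character(pairs[, 2L])))
  }
  df <- as.data.frame(pairs)
  cols <- if (all(c("before_gene", "after_gene") %in% names(df))) {
    c("before_gene", "after_gene")
  } else if (all(c("gene_a", "gene_b") %in% names(df))) {
    c("gene_a", "gene_b")
  } else {
    names(df)[1:2]
  }
  cbind(as.character(df[[cols[[1L]]]]), as.character(df[[cols[[2L]]]]))
}

# Build a vectorized co-feature predicate: function(genes_a, genes_b) ->
# logical.  Self-pairs: never satisfy interaction features (no self-edges);
# satisfy a shared-set feature iff the gene belongs to any set.
feature_checker <- function(features, feature) {
  if (inherits(features, "gene_set_collection")) {
    if (!feature %in% c("co_tf", "co_component", "co_set")) {
      stop("feature label ", feature,
           " does not match a gene-set collection", call. = FALSE)
    }
    genes <- sort(unique(unlist(features$sets)))
    m <- matrix(FALSE, nrow = length(genes), ncol = length(features$sets),
                dimnames = list(genes, names(features$sets)))
    for (nm in names(features$sets)) {
      m[features$sets[[nm]], nm] <- TRUE
    }
    function(genes_a, genes_b) {
      ia <- match(genes_a, genes)
      ib <- match(genes_b, genes)
      out <- logical(length(genes_a))
      ok <- !is.na(ia) & !is.na(ib)
      if (any(ok)) {
        out[ok] <- rowSums(m[ia[ok], , drop = FALSE] &
                             m[ib[ok], , drop = FALSE]) > 0L
      }
      out
    }
  } else if (inherits(features, "interaction_network")) {
    if (!feature %in% INTERACTION_TYPES) {
      stop("feature label ", feature,
           " is not an interaction type", call. = FALSE)
    }
    ed <- features$edges[features$edges$type == feature, ]
    keys <- pair_key(ed$gene_a, ed$gene_b)
    function(genes_a, genes_b) {
      self <- genes_a == genes_b
      out <- pair_key(genes_a, genes_b) %in% keys
      out & !self
    }
  } else {
    stop("`features` must be a gene_set_collection or interaction_network",
         call. = FALSE)
  }
}

#' Co-feature frequency of a gene-pair list
#'
#' For set features (`co_tf`, `co_component`), the fraction of pairs whose
#' two genes share at least one set; for interaction features
#' (`negative_genetic`, `positive_genetic`, `ppi`), the fraction of pairs
#' connected by an edge of that type.
#'
#' @param pairs Two-column pair table (e.g. from [unique_cross_pairs()]).
#' @param features A [gene_set_collection()] or [interaction_network()].
#' @param feature Feature label (see above).
#' @return Fraction in `[0, 1]`.
#' @export
cofeature_frequency <- function(pairs, features, feature) {
  pm <- as_pair_matrix(pairs)
  if (!nrow(pm)) stop("`pairs` must be non-empty", call. = FALSE)
  checker <- feature_checker(features, feature)
  mean(checker(pm[, 1L], pm[, 2L]))
}

#' Chromosome-matched randomization of a gene-pair list
#'
#' Each distinct gene occurring in `pairs` is independently replaced by a
#' uniform draw from its own chromosome excluding itself; the one mapping
#' is applied to every pair.  Pairs that collapse onto a single gene are
#' kept.
#'
#' @param pairs Two-column pair table.
#' @param focal_annot Focal [genome_annotation()].
#' @param seed Explicit RNG seed.
#' @return Two-column character matrix of randomized pairs (same row
#'   order).
#' @export
matched_randomization <- function(pairs, focal_annot, seed) {
  pm <- as_pair_matrix(pairs)
  pools <- replacement_pools(pm, focal_annot)
  mapping <- with_seed(seed, {
    vapply(pools, function(pool) pool[sample.int(length(pool), 1L)],
           character(1L))
  })
  cbind(mapping[pm[, 1L]], mapping[pm[, 2L]])
}

# Same-chromosome replacement pool (excluding self) for every distinct
# gene in the pair matrix; singleton chromosomes are a hard error.
replacement_pools <- function(pm, focal_annot) {
  stopifnot(inherits(focal_annot, "genome_annotation"))
  gi <- focal_annot$gene_index
  genes <- unique(as.vector(pm))
  unknown <- setdiff(genes, rownames(gi))
  if (length(unknown)) {
    stop("unknown gene in pairs: ", unknown[[1L]], call. = FALSE)
  }
  pools <- lapply(genes, function(g) {
    mates <- focal_annot$chromosomes[[gi[g, "chrom"]]]
    mates <- mates[mates != g]
    if (!length(mates)) {
      stop("gene ", g, " is alone on chromosome ", gi[g, "chrom"],
           "; chromosome-matched replacement impossible", call. = FALSE)
    }
    mates
  })
  stats::setNames(pools, genes)
}

#' Chromosome-matched permutation test of a co-feature frequency
#'
#' Computes the observed co-feature frequency of `pairs`, then repeats the
#' chromosome-matched randomization `n_iter` times, recomputing the
#' frequency each time.  The empirical P value is the fraction of
#' randomizations with a strictly higher frequency than observed; the
#' add-one estimate `(k + 1) / (n_iter + 1)` is reported alongside.
#'
#' @inheritParams cofeature_frequency
#' @param focal_annot Focal [genome_annotation()].
#' @param n_iter Number of randomizations (default 100000).
#' @param seed Explicit RNG seed.
#' @param keep_null Keep the full null frequency vector (default `TRUE`;
#'   set `FALSE` to save memory at very large `n_iter`).
#' @return An object of class `permutation_result` with fields `feature`,
#'   `observed_frequency`, `null_frequencies`, `empirical_p`,
#'   `empirical_p_addone`, `n_iter`, `seed`.
#' @export
permutation_test <- function(pairs, features, feature, focal_annot,
                             n_iter = 100000L, seed, keep_null = TRUE) {
  pm <- as_pair_matrix(pairs)
  if (!nrow(pm)) stop("`pairs` must be non-empty", call. = FALSE)
  n_iter <- as.integer(n_iter)
  checker <- feature_checker(features, feature)
  observed_count <- sum(checker(pm[, 1L], pm[, 2L]))
  pools <- replacement_pools(pm, focal_annot)
  genes <- names(pools)
  ia <- match(pm[, 1L], genes)
  ib <- match(pm[, 2L], genes)
  n_pairs <- nrow(pm)

  null_counts <- with_seed(seed, {
    counts <- integer(n_iter)
    done <- 0L
    chunk <- min(n_iter, 2000L)
    while (done < n_iter) {
      m <- min(chunk, n_iter - done)
      repl <- vapply(pools, function(pool) {
        pool[sample.int(length(pool), m, replace = TRUE)]
      }, character(m))
      repl <- matrix(repl, nrow = m)  # iterations x genes
      acc <- integer(m)
      for (p in seq_len(n_pairs)) {
        acc <- acc + checker(repl[, ia[[p]]], repl[, ib[[p]]])
      }
      counts[(done + 1L):(done + m)] <- acc
      done <- done + m
    }
    counts
  })

  k <- sum(null_counts > observed_count)
  structure(
    list(feature = feature,
         observed_frequency = observed_count / n_pairs,
         null_frequencies = if (keep_null) null_counts / n_pairs else NULL,
         empirical_p = k / n_iter,
         empirical_p_addone = (k + 1) / (n_iter + 1),
         n_iter = n_iter, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %s — observed %.4f, empirical P %.5g (add-one %.5g) over %d iterations (seed %s)\n",
    x$feature, x$observed_frequency, x$empirical_p, x$empirical_p_addone,
    x$n_iter, format(x$seed)))
  invisible(x)
}
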
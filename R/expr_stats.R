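# Expression divergence, pairwise coexpression, group contrasts and
# bootstrap summaries.
#
# Divergence recipe: per gene and species pair, raw divergence is
# 1 - Pearson correlation of the matched-condition expression profiles of
# the gene's representatives in the two species; it is corrected by
# subtracting the average intraspecies divergence of the two species
# (estimated from replicate profiles), z-normalized over genes within each
# species pair, and finally averaged over the species pairs in which the
# gene is represented, giving one dimensionless value per gene.

#' Spearman coexpression of two expression profiles
#'
#' Computed over the shared non-missing conditions (matched by name when
#' both profiles are named, by position otherwise); ties get average ranks.
#'
#' @param profile_a,profile_b Numeric vectors of per-condition expression.
#' @return Spearman rho, or `NA_real_` when fewer than 3 shared non-missing
#'   conditions exist (excluded from downstream summaries).
#' @export
spearman_coexpression <- function(profile_a, profile_b) {
  if (!is.null(names(profile_a)) && !is.null(names(profile_b))) {
    shared <- intersect(names(profile_a), names(profile_b))
    profile_a <- profile_a[shared]
    profile_b <- profile_b[shared]
  } else if (length(profile_a) != length(profile_b)) {
    stop("unnamed profiles must have equal length", call. = FALSE)
  }
  ok <- !is.na(profile_a) & !is.na(profile_b)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(profile_a[ok], profile_b[ok], method = "spearman")
}

# Mean intraspecies divergence of one species: 1 - correlation between
# first- and second-replicate profiles, averaged over genes.  Requires
# replicate_groups with at least two >=2-replicate condition groups.
intraspecies_divergence <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  rg <- mat$replicate_groups
  if (is.null(rg)) {
    stop("species ", mat$species_id,
         " lacks replicate_groups; intraspecies baseline undefined",
         call. = FALSE)
  }
  groups <- split(names(rg), rg)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 3L) {
    stop("species ", mat$species_id,
         " needs >= 3 replicated condition groups for the intraspecies ",
         "baseline", call. = FALSE)
  }
  rep1 <- vapply(groups, `[[`, character(1L), 1L)
  rep2 <- vapply(groups, `[[`, character(1L), 2L)
  v1 <- mat$values[, rep1, drop = FALSE]
  v2 <- mat$values[, rep2, drop = FALSE]
  cors <- vapply(seq_len(nrow(v1)), function(i) {
    ok <- !is.na(v1[i, ]) & !is.na(v2[i, ])
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(v1[i, ok], v2[i, ok])
  }, numeric(1L))
  mean(1 - cors, na.rm = TRUE)
}

# Representatives of each focal gene in one species: the gene itself for
# the focal species, its ortholog set otherwise.
species_representatives <- function(species, orthomap, focal) {
  if (species == focal) return(NULL)
  tab <- orthomap$table[orthomap$table$species == species, ]
  split(tab$ortholog_gene, tab$focal_gene)
}

#' Per-gene expression divergence across species
#'
#' Applies the correction/normalization/averaging recipe described above to
#' every unordered pair of the supplied species.  One-to-many orthologs
#' contribute their minimum-divergence (best-correlated) representative by
#' default.
#'
#' @param matrices Named list of [expression_matrix()] objects (must
#'   include the focal species); conditions are matched across species by
#'   label.
#' @param orthomap An [orthology_map()].
#' @param focal Focal species label.
#' @param ortholog_mode `"min"` (default): minimum-divergence ortholog;
#'   `"mean"`: average over ortholog combinations.
#' @return An object of class `divergence_profile` with fields
#'   `divergence` (named per-gene values), `pairwise_components` (named
#'   list, one z-scaled per-gene vector per species pair) and
#'   `intraspecies_baseline` (named per-species means).
#' @export
expression_divergence <- function(matrices, orthomap, focal,
                                  ortholog_mode = c("min", "mean")) {
  ortholog_mode <- match.arg(ortholog_mode)
  stopifnot(inherits(orthomap, "orthology_map"))
  if (!focal %in% names(matrices)) {
    stop("`matrices` must include the focal species ", focal, call. = FALSE)
  }
  species <- names(matrices)
  baseline <- vapply(matrices, intraspecies_divergence, numeric(1L))
  reps <- lapply(stats::setNames(species, species),
                 species_representatives, orthomap, focal)
  focal_genes <- rownames(orthomap$presence)
  focal_genes <- focal_genes[focal_genes %in% matrices[[focal]]$genes]

  pair_grid <- utils::combn(species, 2L)
  components <- list()
  for (k in seq_len(ncol(pair_grid))) {
    si <- pair_grid[1L, k]; sj <- pair_grid[2L, k]
    mi <- matrices[[si]]; mj <- matrices[[sj]]
    shared <- intersect(mi$conditions, mj$conditions)
    if (length(shared) < 3L) {
      stop("species pair (", si, ", ", sj, ") shares fewer than 3 ",
           "conditions", call. = FALSE)
    }
    vi <- mi$values[, shared, drop = FALSE]
    vj <- mj$values[, shared, drop = FALSE]
    raw <- vapply(focal_genes, function(g) {
      gi <- if (si == focal) g else reps[[si]][[g]]
      gj <- if (sj == focal) g else reps[[sj]][[g]]
      gi <- gi[gi %in% rownames(vi)]
      gj <- gj[gj %in% rownames(vj)]
      if (!length(gi) || !length(gj)) return(NA_real_)
      divs <- outer(gi, gj, Vectorize(function(x, y) {
        ok <- !is.na(vi[x, ]) & !is.na(vj[y, ])
        if (sum(ok) < 3L) return(NA_real_)
        1 - stats::cor(vi[x, ok], vj[y, ok])
      }))
      if (all(is.na(divs))) return(NA_real_)
      if (ortholog_mode == "min") min(divs, na.rm = TRUE)
      else mean(divs, na.rm = TRUE)
    }, numeric(1L))
    corrected <- raw - mean(baseline[c(si, sj)])
    sdv <- stats::sd(corrected, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) {
      stop("degenerate divergence component for species pair (", si, ", ",
           sj, "): zero variance over genes; non-degenerate input required",
           call. = FALSE)
    }
    z <- (corrected - mean(corrected, na.rm = TRUE)) / sdv
    components[[paste(si, sj, sep = "|")]] <- z
  }
  comp_mat <- do.call(cbind, components)
  divergence <- rowMeans(comp_mat, na.rm = TRUE)
  divergence <- divergence[!is.nan(divergence)]
  if (length(dropped <- setdiff(focal_genes, names(divergence)))) {
    ns_log("expression_divergence: ", length(dropped),
           " gene(s) without orthologs in any species pair dropped")
  }
  structure(
    list(divergence = divergence, pairwise_components = components,
         intraspecies_baseline = baseline),
    class = "divergence_profile"
  )
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf(
    "divergence_profile: %d genes over %d species pair(s)\n",
    length(x$divergence), length(x$pairwise_components)))
  invisible(x)
}

#' Mann-Whitney U comparison of two value groups
#'
#' Exact permutation enumeration (tie-safe) when both groups have at most 8
#' values; tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List with `U` (the U statistic of `values_a`, counting
#'   `a_i > b_j` pairs plus half-ties) and `p_value` (two-sided).
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a); nb <- length(values_b)
  if (na == 0L || nb == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  u_stat <- function(x_idx, combined, na) {
    ranks <- rank(combined)
    sum(ranks[x_idx]) - na * (na + 1) / 2
  }
  combined <- c(values_a, values_b)
  u_obs <- u_stat(seq_len(na), combined, na)
  if (na <= 8L && nb <= 8L) {
    mu <- na * nb / 2
    sets <- utils::combn(na + nb, na)
    u_all <- apply(sets, 2L, function(idx) u_stat(idx, combined, na))
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
    )
    p <- wt$p.value
  }
  list(U = u_obs, p_value = p)
}

#' Bootstrap percentile confidence interval for the median
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed Explicit RNG seed (mandatory).
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000L, alpha = 0.05, seed) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least 2 values to bootstrap", call. = FALSE)
  }
  meds <- with_seed(seed, {
    resamples <- matrix(sample(values, length(values) * n_boot,
                               replace = TRUE), ncol = n_boot)
    apply(resamples, 2L, stats::median)
  })
  ci <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(low = ci[[1L]], high = ci[[2L]])
}

#' Background coexpression distribution over random gene pairs
#'
#' Spearman rho for gene pairs of one species.  All `choose(n, 2)` pairs
#' are enumerated when the genome has at most `full_enum_limit` genes;
#' above that, `n_pairs` distinct pairs are sampled uniformly.
#'
#' @param matrix An [expression_matrix()].
#' @param n_pairs Number of pairs to sample in sampling mode (default 1e5).
#' @param seed Explicit RNG seed (mandatory, used only in sampling mode but
#'   always required for a stable call signature).
#' @param full_enum_limit Gene-count limit for full enumeration
#'   (default 2000).
#' @return Numeric vector of rho values; pairs with fewer than 3 shared
#'   non-missing conditions are dropped.
#' @export
coexpression_background <- function(matrix, n_pairs = 1e5L, seed,
                                    full_enum_limit = 2000L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (n_pairs < 1L) stop("`n_pairs` must be >= 1", call. = FALSE)
  vals <- matrix$values
  n <- nrow(vals)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (n <= full_enum_limit) {
    cm <- suppressWarnings(
      stats::cor(t(vals), method = "spearman", use = "pairwise.complete.obs")
    )
    rho <- cm[upper.tri(cm)]
    return(rho[!is.na(rho)])
  }
  pairs <- with_seed(seed, {
    acc <- matrix(integer(0), ncol = 2L)
    while (nrow(acc) < n_pairs) {
      draw <- ceiling(1.2 * (n_pairs - nrow(acc)))
      i <- sample.int(n, draw, replace = TRUE)
      j <- sample.int(n, draw, replace = TRUE)
      keep <- i != j
      cand <- cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))
      acc <- unique(rbind(acc, cand))
    }
    acc[seq_len(n_pairs), , drop = FALSE]
  })
  rho <- vapply(seq_len(nrow(pairs)), function(k) {
    spearman_coexpression(vals[pairs[k, 1L], ], vals[pairs[k, 2L], ])
  }, numeric(1L))
  rho[!is.na(rho)]
}
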
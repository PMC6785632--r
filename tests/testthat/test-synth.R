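test_that("no-op evolution yields identical gene orders everywhere", {
  cfg <- small_config(101, n_species = 8L, loss_rate = 0,
                      rearrangement_events = 0L,
                      n_planted_ecns_pairs = 0L,
                      n_planted_single_species_pairs = 0L)
  gen <- simulate_genomes(cfg)
  focal_order <- lapply(gen$annotations[[1L]]$chromosomes, identity)
  for (s in names(gen$annotations)[-1L]) {
    stripped <- lapply(gen$annotations[[s]]$chromosomes,
                       function(v) sub("^[^_]+_", "", v))
    expect_identical(stripped, focal_order)
  }
  # every adjacent focal pair is a neighbor pair in all non-focal species
  pairs <- classify_pairs(gen$annotations[-1L], gen$orthomap)
  expect_true(all(pairs$class == "conserved"))
  expect_true(all(pairs$n_neighbor_species ==
                    length(gen$orthomap$species_universe)))
})

test_that("gene loss tracks the configured rate", {
  cfg <- synth_config(genes_per_genome = 2000L, n_chromosomes = 16L,
                      loss_rate = 0.3, rearrangement_events = 0L,
                      n_planted_ecns_pairs = 0L,
                      n_planted_single_species_pairs = 0L, seed = 55L)
  gen <- simulate_genomes(cfg)
  frac <- colMeans(gen$orthomap$presence)
  expect_true(all(abs(frac - 0.7) < 0.03))
})

test_that("planted truth is internally consistent under noise", {
  for (seed in c(71L, 72L)) {
    gen <- simulate_genomes(small_config(seed))
    focal <- gen$annotations[[1L]]
    nf <- gen$annotations[-1L]
    for (i in seq_len(nrow(gen$truth$ecns_pairs))) {
      a <- gen$truth$ecns_pairs$gene_a[[i]]
      b <- gen$truth$ecns_pairs$gene_b[[i]]
      expect_true(is_separated(focal, a, b))
      app <- appeared_species(a, b, gen$orthomap)
      nb <- sum(vapply(app, function(s) {
        neighbors_in_species(a, b, s, gen$orthomap, nf)
      }, logical(1L)))
      expect_gte(nb, conservation_threshold(length(app)))
    }
    for (i in seq_len(nrow(gen$truth$single_species_pairs))) {
      a <- gen$truth$single_species_pairs$gene_a[[i]]
      b <- gen$truth$single_species_pairs$gene_b[[i]]
      expect_true(is_separated(focal, a, b))
      nb <- sum(vapply(gen$orthomap$species_universe, function(s) {
        neighbors_in_species(a, b, s, gen$orthomap, nf)
      }, logical(1L)))
      expect_equal(nb, 1L)
    }
  }
})

test_that("simulated genomes satisfy annotation invariants", {
  gen <- simulate_genomes(small_config(81))
  for (ann in gen$annotations) {
    gi <- ann$gene_index
    expect_false(anyDuplicated(gi$gene) > 0)
    for (k in names(ann$chromosomes)) {
      idx <- gi[ann$chromosomes[[k]], "index"]
      expect_equal(idx, seq_along(idx) - 1L)
    }
    expect_true(all(gi$start <= gi$end))
  }
})

test_that("expression simulation plants the requested coexpression", {
  # rho = 0: planted pairs are uncorrelated (~100 pairs, 50 conditions)
  cfg0 <- synth_config(genes_per_genome = 1000L,
                       n_planted_ecns_pairs = 100L,
                       n_planted_single_species_pairs = 0L,
                       coexpression_rho = 0, noise_sd = 0,
                       interspecies_sd = 0, n_conditions = 50L,
                       rearrangement_events = 0L, seed = 111L)
  gen0 <- simulate_genomes(cfg0)
  ex0 <- simulate_expression(cfg0, gen0$truth, gen0$annotations,
                             gen0$orthomap)
  fm0 <- ex0[[gen0$truth$focal_species]]
  cp0 <- gen0$truth$coexpressed_pairs
  rho0 <- vapply(seq_len(nrow(cp0)), function(i) {
    spearman_coexpression(fm0$values[cp0$gene_a[[i]], ],
                          fm0$values[cp0$gene_b[[i]], ])
  }, numeric(1L))
  expect_lt(abs(mean(rho0)), 0.05)

  # rho = 0.5, noise-free: mean Spearman near the bivariate-normal mapping
  # rho_s = (6 / pi) * asin(rho / 2)
  cfg5 <- synth_config(genes_per_genome = 1000L,
                       n_planted_ecns_pairs = 100L,
                       n_planted_single_species_pairs = 0L,
                       coexpression_rho = 0.5, noise_sd = 0,
                       interspecies_sd = 0, n_conditions = 100L,
                       rearrangement_events = 0L, seed = 112L)
  gen5 <- simulate_genomes(cfg5)
  ex5 <- simulate_expression(cfg5, gen5$truth, gen5$annotations,
                             gen5$orthomap)
  fm5 <- ex5[[gen5$truth$focal_species]]
  cp5 <- gen5$truth$coexpressed_pairs
  rho5 <- vapply(seq_len(nrow(cp5)), function(i) {
    spearman_coexpression(fm5$values[cp5$gene_a[[i]], ],
                          fm5$values[cp5$gene_b[[i]], ])
  }, numeric(1L))
  expect_lt(abs(mean(rho5) - (6 / pi) * asin(0.5 / 2)), 0.1)

  # determinism
  ex5b <- simulate_expression(cfg5, gen5$truth, gen5$annotations,
                              gen5$orthomap)
  expect_identical(lapply(ex5, `[[`, "values"),
                   lapply(ex5b, `[[`, "values"))
})

test_that("feature simulation matches background rates under the null", {
  cfg <- small_config(121, cofeature_enrichment = 0.05)
  gen <- simulate_genomes(cfg)
  genes <- gen$annotations[[1L]]$gene_index$gene
  feats <- simulate_features(cfg, gen$truth, genes)
  # with enrichment equal to background, planted pairs look like random
  # pairs: compare planted frequency to random-pair frequency
  planted_freq <- cofeature_frequency(gen$truth$cofeature_pairs,
                                      feats$tf_targets, "co_tf")
  set.seed(9)
  rnd <- data.frame(gene_a = sample(genes, 4000L, replace = TRUE),
                    gene_b = sample(genes, 4000L, replace = TRUE))
  rnd <- rnd[rnd$gene_a != rnd$gene_b, ]
  rnd_freq <- cofeature_frequency(rnd, feats$tf_targets, "co_tf")
  n <- nrow(gen$truth$cofeature_pairs)
  expect_lt(abs(planted_freq - rnd_freq),
            3 * sqrt(rnd_freq * (1 - rnd_freq) / n) + 0.05)
  # determinism
  feats2 <- simulate_features(cfg, gen$truth, genes)
  expect_identical(feats$tf_targets$sets, feats2$tf_targets$sets)
  expect_identical(feats$network$edges, feats2$network$edges)
})

test_that("essential-gene planting follows per-group probabilities", {
  cfg <- synth_config(genes_per_genome = 1600L, n_chromosomes = 16L,
                      n_planted_ecns_pairs = 60L,
                      n_planted_single_species_pairs = 60L,
                      n_conditions = 4L, seed = 131L)
  gen <- simulate_genomes(cfg)
  genes <- gen$annotations[[1L]]$gene_index$gene
  feats <- simulate_features(cfg, gen$truth, genes)
  ess <- feats$essential$sets$essential
  f_ecns <- set_fraction(gen$truth$ecns_genes, ess)
  f_necns <- set_fraction(gen$truth$necns_genes, ess)
  # 120 genes per group: binomial 3-sigma bands around 0.22 and 0.07
  expect_lt(abs(f_ecns - 0.22), 3 * sqrt(0.22 * 0.78 / 120))
  expect_lt(abs(f_necns - 0.07), 3 * sqrt(0.07 * 0.93 / 120))
  expect_gt(f_ecns, f_necns)
})

test_that("infeasible planting is rejected before emission", {
  expect_error(
    synth_config(seed = 1, n_species = 5L), "at least 8")
  cfg <- small_config(1, genes_per_genome = 130L, n_chromosomes = 4L,
                      n_planted_ecns_pairs = 30L,
                      n_planted_single_species_pairs = 30L)
  expect_error(simulate_genomes(cfg), "infeasible planting")
})
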
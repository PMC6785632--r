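test_that("annotation reader orders by start with lexicographic tie-break", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstart\tend\tstrand",
               "g1\tchrA\t100\t150\t+",
               "g2\tchrA\t50\t90\t-",
               "g3\tchrA\t200\t260\t+"), tsv)
  ann <- read_annotation(tsv, "tsv", species_id = "sp")
  expect_equal(ann$chromosomes$chrA, c("g2", "g1", "g3"))
  expect_equal(ann$gene_index["g2", "index"], 0L)
  expect_equal(ann$gene_index["g1", "index"], 1L)
  expect_equal(ann$gene_index["g3", "index"], 2L)

  # identical start: smaller gene ID gets the lower index
  writeLines(c("gene\tchrom\tstart\tend\tstrand",
               "gb\tchrA\t100\t150\t+",
               "ga\tchrA\t100\t150\t+"), tsv)
  ann2 <- read_annotation(tsv, "tsv")
  expect_equal(ann2$chromosomes$chrA, c("ga", "gb"))
})

test_that("annotation reader is permutation-invariant and validates input", {
  base <- data.frame(gene = sprintf("g%02d", 1:12),
                     chrom = rep(c("c1", "c2"), each = 6),
                     start = rep(c(10, 40, 70, 20, 55, 90), 2),
                     end = rep(c(30, 60, 95, 35, 70, 110), 2),
                     strand = "+")
  f1 <- tempfile(); f2 <- tempfile()
  write.table(base, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  set.seed(1)
  write.table(base[sample(nrow(base)), ], f2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  a1 <- read_annotation(f1, "tsv", "sp")
  a2 <- read_annotation(f2, "tsv", "sp")
  expect_identical(a1, a2)

  dup <- rbind(base, base[1, ])
  write.table(dup, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(f1, "tsv"), "duplicate gene ID.*g01")

  bad <- base; bad$start[3] <- "xx"
  write.table(bad, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(f1, "tsv"), "line 4")
})

test_that("GFF3 and TSV encodings of the same genome agree", {
  ann <- make_annotation(list(c1 = c("gA", "gB"), c2 = c("gC")), "sp")
  tsv <- tempfile(fileext = ".tsv")
  write_annotation(ann, tsv)
  gff <- tempfile(fileext = ".gff3")
  gi <- ann$gene_index
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       gi$chrom, gi$start, gi$end, gi$strand, gi$gene)),
             gff)
  from_tsv <- read_annotation(tsv, "tsv", "sp")
  from_gff <- read_annotation(gff, "gff3", "sp")
  expect_equal(from_gff$chromosomes, from_tsv$chromosomes)
  expect_equal(from_gff$gene_index[, c("chrom", "index", "start", "end")],
               from_tsv$gene_index[, c("chrom", "index", "start", "end")])
})

test_that("orthology reader unions one-to-many rows and round-trips", {
  f <- tempfile()
  writeLines(c("focal_gene\tspecies\tortholog_gene",
               "gA\ts1\tx1", "gA\ts1\tx2", "gB\ts2\ty1"), f)
  om <- read_orthology(f, "sp00")
  expect_setequal(orthologs_of(om, "gA", "s1"), c("x1", "x2"))
  expect_true(om$presence["gA", "s1"])
  expect_false(om$presence["gA", "s2"])

  # focal species named as ortholog species is fatal
  writeLines(c("focal_gene\tspecies\tortholog_gene", "gA\tsp00\tz"), f)
  expect_error(read_orthology(f, "sp00"), "focal species")

  # empty file gives a valid empty mapping
  writeLines("focal_gene\tspecies\tortholog_gene", f)
  empty <- read_orthology(f, "sp00")
  expect_equal(nrow(empty$table), 0L)

  # write + read is the identity on a 4-species fixture
  set.seed(11)
  rows <- expand.grid(focal_gene = sprintf("g%02d", 1:10),
                      species = sprintf("s%d", 1:4),
                      stringsAsFactors = FALSE)
  rows <- rows[sample(nrow(rows), 25), ]
  rows$ortholog_gene <- paste0(rows$species, "_", rows$focal_gene)
  om1 <- orthology_map(rows, "sp00", sprintf("s%d", 1:4))
  f2 <- tempfile()
  write_orthology(om1, f2)
  om2 <- read_orthology(f2, "sp00", sprintf("s%d", 1:4))
  expect_equal(om2$table, om1$table[order(focal_gene, species,
                                          ortholog_gene)])
  expect_identical(om2$presence, om1$presence)
})

test_that("expression reader handles NA tokens and rejects bad input", {
  f <- tempfile()
  writeLines(c("gene\tcondA\tcondB\tcondC",
               "g1\t1.5\tNA\t-0.25",
               "g2\t0\t2\t3"), f)
  em <- read_expression(f, "sp")
  expect_equal(dim(em$values), c(2L, 3L))
  expect_true(is.na(em$values["g1", "condB"]))
  expect_equal(em$values["g2", ], c(condA = 0, condB = 2, condC = 3))

  writeLines(c("gene\ta\tb", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_expression(f), "duplicate gene row")

  writeLines(c("gene\ta\tb", "g1\t1\t2\t3"), f)
  expect_error(read_expression(f), "ragged row at line 2")

  # round trip preserves values including NA
  vals <- matrix(c(1.25, NA, -3, 0.5), 2, 2,
                 dimnames = list(c("g1", "g2"), c("x.r1", "x.r2")))
  em1 <- expression_matrix(vals, "sp", infer_replicate_groups(colnames(vals)))
  f2 <- tempfile()
  write_expression(em1, f2)
  em2 <- read_expression(f2, "sp", replicate_groups = "infer")
  expect_equal(em2$values, em1$values)
  expect_equal(em2$replicate_groups, em1$replicate_groups)
})

test_that("GMT reader builds collections, deduplicates and validates", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg4\tg5"), f)
  gc <- read_gene_sets(f, "tf_targets")
  expect_length(gc$sets, 2L)
  expect_equal(gc$kind, "tf_targets")

  writeLines("setA\tdesc\tg1\tg1\tg2", f)
  expect_setequal(read_gene_sets(f, "tf_targets")$sets$setA, c("g1", "g2"))

  writeLines(c("setA\tdesc\tg1", "lonely"), f)
  expect_error(read_gene_sets(f, "tf_targets"), "malformed GMT line 2")

  writeLines(c("setA\tdesc\tg1", "empty\tdesc"), f)
  expect_warning(gc2 <- read_gene_sets(f, "tf_targets"), "empty")
  expect_length(gc2$sets, 1L)

  # essential gene list as a single-set GMT
  writeLines("essential\tdesc\tg1\tg2\tg3", f)
  ess <- read_gene_sets(f, "essential")
  expect_equal(ess$kind, "essential")
  expect_length(ess$sets, 1L)

  f3 <- tempfile(fileext = ".gmt")
  write_gene_sets(gc, f3)
  expect_equal(read_gene_sets(f3, "tf_targets")$sets, gc$sets)
})

test_that("interaction reader collapses symmetric duplicates, skips self-edges", {
  f <- tempfile()
  writeLines(c("gene1\tgene2\ttype",
               "a\tb\tppi", "b\ta\tppi",
               "a\tc\tnegative_genetic",
               "c\td\tpositive_genetic",
               "b\td\tppi"), f)
  net <- read_interactions(f)
  counts <- table(net$edges$type)
  expect_equal(as.integer(counts[["ppi"]]), 2L)
  expect_equal(as.integer(counts[["negative_genetic"]]), 1L)
  expect_equal(as.integer(counts[["positive_genetic"]]), 1L)

  writeLines(c("gene1\tgene2\ttype", "a\ta\tppi"), f)
  expect_warning(net2 <- read_interactions(f), "self-edge")
  expect_equal(nrow(net2$edges), 0L)

  writeLines(c("gene1\tgene2\ttype", "a\tb\tweird"), f)
  expect_error(suppressWarnings(read_interactions(f)), "unknown interaction type")

  f2 <- tempfile()
  write_interactions(net, f2)
  expect_equal(read_interactions(f2)$edges, net$edges)
})

test_that("simulated datasets round-trip through every file format", {
  ds <- simulate_dataset(small_config(301, n_species = 8L,
                                      n_conditions = 6L))
  dir <- tempfile("roundtrip")
  write_dataset(ds, dir)
  for (s in names(ds$annotations)) {
    back <- read_annotation(file.path(dir, paste0("annotation_", s, ".tsv")),
                            "tsv", species_id = s)
    expect_identical(back$chromosomes, ds$annotations[[s]]$chromosomes)
    emb <- read_expression(file.path(dir, paste0("expression_", s, ".tsv")),
                           species_id = s, replicate_groups = "infer")
    expect_equal(emb$values, ds$expression[[s]]$values, tolerance = 1e-12)
  }
  om <- read_orthology(file.path(dir, "orthology.tsv"), "sp00",
                       ds$orthomap$species_universe)
  expect_identical(om$presence, ds$orthomap$presence)
  tf <- read_gene_sets(file.path(dir, "tf_targets.gmt"), "tf_targets")
  expect_equal(tf$sets, ds$features$tf_targets$sets)
  net <- read_interactions(file.path(dir, "interactions.tsv"))
  expect_equal(net$edges, ds$features$network$edges)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
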
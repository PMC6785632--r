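# Readers/writers for every external format the pipeline touches, plus the
# validated in-memory containers they produce.  All tabular files are
# UTF-8, tab-delimited, with a header line.

# ---------------------------------------------------------------------------
# genome_annotation ---------------------------------------------------------

#' Construct a genome annotation from a gene table
#'
#' A `genome_annotation` holds one species' gene order: per-chromosome
#' ordered gene lists plus a gene-level index with coordinates.  Gene order
#' is the rank of the start coordinate within each chromosome (0-based);
#' ties are broken by lexicographic gene ID.  Strand is stored but plays no
#' role in ordering.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (coordinates 1-based inclusive).
#' @param species_id Species label.
#' @return An object of class `genome_annotation` with fields `species_id`,
#'   `chromosomes` (named list of ordered gene ID vectors) and `gene_index`
#'   (data.frame keyed by gene with `chrom`, `index`, `start`, `end`,
#'   `strand`).
#' @export
genome_annotation <- function(genes, species_id) {
  required <- c("gene", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  genes <- as.data.frame(genes)[, required]
  genes$gene <- as.character(genes$gene)
  genes$chrom <- as.character(genes$chrom)
  dup <- genes$gene[duplicated(genes$gene)]
  if (length(dup)) {
    stop("duplicate gene ID in annotation: ", dup[[1L]], call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene[which(genes$start > genes$end)[1L]]
    stop("gene with start > end: ", bad, call. = FALSE)
  }
  if (any(grepl("\t", genes$gene, fixed = TRUE))) {
    stop("gene IDs must not contain tab characters", call. = FALSE)
  }
  ord <- order(genes$chrom, genes$start, genes$gene)
  genes <- genes[ord, , drop = FALSE]
  genes$index <- stats::ave(genes$start, genes$chrom,
                            FUN = function(x) seq_along(x) - 1L)
  genes$index <- as.integer(genes$index)
  chromosomes <- split(genes$gene, genes$chrom)
  gene_index <- data.frame(
    gene = genes$gene, chrom = genes$chrom, index = genes$index,
    start = genes$start, end = genes$end, strand = genes$strand,
    row.names = genes$gene, stringsAsFactors = FALSE
  )
  structure(
    list(species_id = species_id, chromosomes = chromosomes,
         gene_index = gene_index),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %s — %d genes on %d chromosome(s)\n",
              x$species_id, nrow(x$gene_index), length(x$chromosomes)))
  invisible(x)
}

#' Read a genome annotation from TSV or GFF3
#'
#' The TSV dialect has columns `gene`, `chrom`, `start`, `end`, `strand`.
#' GFF3 input is parsed with rtracklayer; only features of type `gene` are
#' used and each must carry an `ID` attribute.  Both encodings of the same
#' genome yield identical objects.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gff3"`.
#' @param species_id Species label recorded on the result.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("tsv", "gff3"),
                            species_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(!nzchar(ids))) {
      stop("GFF3 gene feature without an ID attribute", call. = FALSE)
    }
    df <- data.frame(
      gene = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    df$strand[df$strand == "*"] <- "."
    return(genome_annotation(df, species_id))
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  required <- c("gene", "chrom", "start", "end", "strand")
  if (!all(required %in% names(dt))) {
    stop("annotation TSV must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  start_num <- suppressWarnings(as.numeric(dt$start))
  end_num <- suppressWarnings(as.numeric(dt$end))
  bad <- which(is.na(start_num) | is.na(end_num))
  if (length(bad)) {
    stop("unparseable coordinates at line ", bad[[1L]] + 1L, " of ", path,
         call. = FALSE)
  }
  df <- data.frame(gene = dt$gene, chrom = dt$chrom, start = start_num,
                   end = end_num, strand = dt$strand,
                   stringsAsFactors = FALSE)
  genome_annotation(df, species_id)
}

#' Write a genome annotation to the TSV dialect
#'
#' @param annot A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  stopifnot(inherits(annot, "genome_annotation"))
  gi <- annot$gene_index
  out <- data.frame(gene = gi$gene, chrom = gi$chrom,
                    start = format(gi$start, scientific = FALSE, trim = TRUE),
                    end = format(gi$end, scientific = FALSE, trim = TRUE),
                    strand = gi$strand, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# orthology_map --------------------------------------------------------------

#' Construct an orthology map
#'
#' Maps focal-species genes to their (possibly one-to-many) orthologs in
#' each non-focal species.  Absence of a (gene, species) entry means "no
#' ortholog"; empty ortholog sets are never stored.
#'
#' @param table data.frame with columns `focal_gene`, `species`,
#'   `ortholog_gene`, one row per assignment.
#' @param focal_species Focal species label; must not occur in `species`.
#' @param species_universe Ordered non-focal species labels.  Defaults to
#'   the sorted species observed in `table`.
#' @return An object of class `orthology_map` with the assignment table, a
#'   gene-by-species presence matrix and a per-species reverse index.
#' @export
orthology_map <- function(table, focal_species, species_universe = NULL) {
  dt <- data.table::as.data.table(table)
  needed <- c("focal_gene", "species", "ortholog_gene")
  if (!all(needed %in% names(dt))) {
    stop("orthology table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  dt <- data.table::data.table(
    focal_gene = as.character(dt$focal_gene),
    species = as.character(dt$species),
    ortholog_gene = as.character(dt$ortholog_gene))
  if (any(dt$species == focal_species)) {
    stop("orthology row names the focal species (", focal_species,
         ") as ortholog species", call. = FALSE)
  }
  dt <- unique(dt)
  if (is.null(species_universe)) {
    species_universe <- sort(unique(dt$species))
  } else if (length(extra <- setdiff(unique(dt$species), species_universe))) {
    stop("orthology table names species outside the universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(dt$focal_gene))
  presence <- matrix(FALSE, nrow = length(genes),
                     ncol = length(species_universe),
                     dimnames = list(genes, species_universe))
  if (nrow(dt)) {
    pres_idx <- unique(dt[, c("focal_gene", "species")])
    presence[cbind(pres_idx$focal_gene, pres_idx$species)] <- TRUE
  }
  structure(
    list(focal_species = focal_species, table = dt,
         species_universe = species_universe, presence = presence),
    class = "orthology_map"
  )
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf(
    "orthology_map: %d focal genes of %s across %d species (%d assignments)\n",
    nrow(x$presence), x$focal_species, length(x$species_universe),
    nrow(x$table)))
  invisible(x)
}

#' Orthologs of one focal gene in one species
#'
#' @param orthomap An [orthology_map()].
#' @param gene Focal gene ID.
#' @param species Non-focal species label.
#' @return Character vector of ortholog gene IDs (possibly empty).
#' @export
orthologs_of <- function(orthomap, gene, species) {
  stopifnot(inherits(orthomap, "orthology_map"))
  tab <- orthomap$table
  tab[tab$focal_gene == gene & tab$species == species]$ortholog_gene
}

#' Read an orthology map from long-format TSV
#'
#' Expects columns `focal_gene`, `species`, `ortholog_gene`; one row per
#' ortholog assignment, one-to-many assignments on separate rows.
#'
#' @param path File path.
#' @param focal_species Focal species label; rows naming it as the ortholog
#'   species are a hard error.
#' @param species_universe Optional ordered non-focal species labels.
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path, focal_species, species_universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(focal_gene = character(),
                                 species = character(),
                                 ortholog_gene = character())
  }
  orthology_map(dt, focal_species, species_universe)
}

#' Write an orthology map to long-format TSV
#'
#' @param orthomap An [orthology_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthology <- function(orthomap, path) {
  stopifnot(inherits(orthomap, "orthology_map"))
  tab <- orthomap$table[order(focal_gene, species, ortholog_gene)]
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# expression_matrix ----------------------------------------------------------

#' Construct an expression matrix
#'
#' Genes-by-conditions matrix of (log-scale) expression values.  Missing
#' values are explicit `NA`s, never silent zeros.
#'
#' @param values Numeric matrix with gene IDs as row names and condition
#'   labels as column names.
#' @param species_id Species label.
#' @param replicate_groups Optional named character vector mapping each
#'   condition label to a replicate-group label (used for the intraspecies
#'   divergence baseline).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, species_id, replicate_groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and condition column names",
         call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate gene ID in expression matrix: ", dup[[1L]], call. = FALSE)
  }
  if (!is.null(replicate_groups)) {
    if (is.null(names(replicate_groups)) ||
        !all(colnames(values) %in% names(replicate_groups))) {
      stop("`replicate_groups` must name every condition", call. = FALSE)
    }
    replicate_groups <- replicate_groups[colnames(values)]
  }
  structure(
    list(species_id = species_id, values = values,
         genes = rownames(values), conditions = colnames(values),
         replicate_groups = replicate_groups),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %s — %d genes x %d conditions (%d NA)\n",
              x$species_id, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Infer replicate groups from condition labels
#'
#' Conditions named `<group>.r<k>` (the simulator's convention) are grouped
#' by stripping the replicate suffix; any other label forms its own group.
#'
#' @param conditions Character vector of condition labels.
#' @return Named character vector mapping condition to group.
#' @export
infer_replicate_groups <- function(conditions) {
  groups <- sub("\\.r[0-9]+$", "", conditions)
  stats::setNames(groups, conditions)
}

#' Read an expression matrix from TSV
#'
#' First column is the gene ID, header row holds condition labels.  `NA`
#' tokens become explicit missing values.
#'
#' @param path File path.
#' @param species_id Species label.
#' @param replicate_groups Optional condition-to-group map; the string
#'   `"infer"` applies [infer_replicate_groups()].
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, species_id = basename(path),
                            replicate_groups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty expression file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    stop("ragged row at line ", ragged[[1L]], " of ", path, call. = FALSE)
  }
  header <- fields[[1L]]
  conditions <- header[-1L]
  body <- fields[-1L]
  genes <- vapply(body, `[[`, character(1L), 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene row in expression matrix: ", dup[[1L]],
         call. = FALSE)
  }
  values <- matrix(NA_real_, nrow = length(genes), ncol = length(conditions),
                   dimnames = list(genes, conditions))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    x <- suppressWarnings(as.numeric(raw))
    unparsed <- is.na(x) & raw != "NA"
    if (any(unparsed)) {
      stop("unparseable expression value at line ", i + 1L, " of ", path,
           call. = FALSE)
    }
    values[i, ] <- x
  }
  if (identical(replicate_groups, "infer")) {
    replicate_groups <- infer_replicate_groups(conditions)
  }
  expression_matrix(values, species_id, replicate_groups)
}

#' Write an expression matrix to TSV
#'
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  out <- data.table::data.table(gene = mat$genes)
  for (j in seq_along(mat$conditions)) {
    data.table::set(out, j = mat$conditions[[j]], value = mat$values[, j])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# gene_set_collection --------------------------------------------------------

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene IDs); every set must be
#'   non-empty and names unique.
#' @param kind One of `"tf_targets"`, `"cellular_component"`, `"essential"`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets,
                                kind = c("tf_targets", "cellular_component",
                                         "essential")) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set name: ",
         names(sets)[duplicated(names(sets))][[1L]], call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][[1L]],
         call. = FALSE)
  }
  structure(list(sets = sets, kind = kind), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets, %d distinct genes\n",
              x$kind, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `set-name <TAB> description <TAB> member...`.  Lines with
#' fewer than two fields are a hard error; sets with zero members are
#' dropped with a warning; duplicate members are deduplicated.
#'
#' @param path File path.
#' @param kind Passed to [gene_set_collection()].
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path, kind = c("tf_targets", "cellular_component",
                                          "essential")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nfields <- lengths(strsplit(readLines(path, encoding = "UTF-8"), "\t",
                              fixed = TRUE))
  short <- which(nfields < 2L)
  if (length(short)) {
    stop("malformed GMT line ", short[[1L]], " in ", path,
         " (fewer than 2 fields)", call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  gene_set_collection(sets, kind)
}

#' Write gene sets to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$kind, collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# interaction_network --------------------------------------------------------

INTERACTION_TYPES <- c("negative_genetic", "positive_genetic", "ppi")

#' Construct an interaction network
#'
#' Stores unordered, typed gene-pair edges.  Self-edges are rejected and
#' `(a,b)` is identified with `(b,a)`; duplicate edges collapse.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `type` where
#'   `type` is one of `negative_genetic`, `positive_genetic`, `ppi`.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(edges) {
  dt <- data.table::as.data.table(edges)
  needed <- c("gene_a", "gene_b", "type")
  if (!all(needed %in% names(dt))) {
    stop("edge table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[, needed, with = FALSE]
  for (cn in needed) data.table::set(dt, j = cn, value = as.character(dt[[cn]]))
  bad_type <- setdiff(unique(dt$type), INTERACTION_TYPES)
  if (length(bad_type)) {
    stop("unknown interaction type: ", bad_type[[1L]], call. = FALSE)
  }
  if (any(dt$gene_a == dt$gene_b)) {
    stop("self-edge in interaction network: ",
         dt$gene_a[dt$gene_a == dt$gene_b][[1L]], call. = FALSE)
  }
  swap <- dt$gene_a > dt$gene_b
  tmp <- dt$gene_a[swap]
  data.table::set(dt, which(swap), "gene_a", dt$gene_b[swap])
  data.table::set(dt, which(swap), "gene_b", tmp)
  dt <- unique(dt)
  data.table::setkeyv(dt, needed)
  structure(list(edges = dt), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  counts <- table(factor(x$edges$type, levels = INTERACTION_TYPES))
  cat("interaction_network:",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read an interaction network from TSV
#'
#' Columns `gene1`, `gene2`, `type`.  Self-edge rows are skipped with a
#' warning; unknown types are a hard error.
#'
#' @param path File path.
#' @return An [interaction_network()].
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (!all(c("gene1", "gene2", "type") %in% names(dt))) {
    stop("interaction TSV must have columns gene1, gene2, type",
         call. = FALSE)
  }
  self <- dt$gene1 == dt$gene2
  if (any(self)) {
    warning("skipping ", sum(self), " self-edge row(s) (e.g. ",
            dt$gene1[self][[1L]], ")", call. = FALSE)
    dt <- dt[!self]
  }
  interaction_network(data.frame(gene_a = dt$gene1, gene_b = dt$gene2,
                                 type = dt$type, stringsAsFactors = FALSE))
}

#' Write an interaction network to TSV
#'
#' @param network An [interaction_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  out <- data.table::data.table(gene1 = network$edges$gene_a,
                                gene2 = network$edges$gene_b,
                                type = network$edges$type)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
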
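# Stage orchestration: simulate -> identify -> classify -> exprstats ->
# permtest -> report, driven by a single YAML config.  Results go to files
# under the configured output directory; logs go to stderr.

PIPELINE_STAGES <- c("simulate", "identify", "classify", "exprstats",
                     "permtest", "report")
COFEATURES <- c(co_tf = "tf_targets", negative_genetic = "network",
                positive_genetic = "network", ppi = "network",
                co_component = "cellular_component")

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML document (or an equivalent R list) with
#' top-level keys `focal_species`, `out_dir`, `seed`, optional `simulate`
#' (passed to [synth_config()]), optional `inputs` (paths to annotation,
#' orthology, expression, gene-set and interaction files) and optional
#' `thresholds` (`eligibility_fraction`, `min_intervening`, `n_iter`).
#' Every violation found is reported in one error.
#'
#' @param x Path to a YAML file, or a list.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  problems <- character(0)
  need <- function(field) {
    if (is.null(cfg[[field]])) {
      problems <<- c(problems, paste0("missing required field: ", field))
    }
  }
  need("focal_species"); need("out_dir"); need("seed")
  th <- cfg$thresholds %||% list()
  th$eligibility_fraction <- th$eligibility_fraction %||% 0.6
  th$min_intervening <- th$min_intervening %||% 15L
  th$n_iter <- th$n_iter %||% 100000L
  if (th$eligibility_fraction < 0 || th$eligibility_fraction > 1) {
    problems <- c(problems, "eligibility_fraction must lie in [0, 1]")
  }
  if (th$min_intervening < 0) {
    problems <- c(problems, "min_intervening must be >= 0")
  }
  if (th$n_iter < 1) problems <- c(problems, "n_iter must be >= 1")
  cfg$thresholds <- th
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    problems <- c(problems,
                  "either `simulate` or `inputs` must be provided")
  }
  if (!is.null(cfg$inputs)) {
    flat <- unlist(cfg$inputs)
    missing_paths <- flat[!file.exists(flat)]
    if (length(missing_paths)) {
      problems <- c(problems,
                    paste0("input path does not exist: ", missing_paths))
    }
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(cfg)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

# Artifact TSVs carry one provenance comment line, then a normal header.
write_artifact <- function(dt, path, cfg, stage) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(sprintf("# config_hash=%s seed=%s stage=%s version=%s",
                     config_hash(cfg), cfg$seed, stage,
                     as.character(utils::packageVersion("neighborsep"))),
             con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

read_artifact <- function(path) {
  if (!file.exists(path)) return(NULL)
  data.table::fread(path, sep = "\t", header = TRUE, skip = 1L)
}

# Gather pipeline inputs, either from configured paths or from the
# simulate stage's output directory.
load_pipeline_inputs <- function(cfg) {
  sim_dir <- file.path(cfg$out_dir, "inputs")
  if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    annots <- lapply(names(ip$annotations), function(s) {
      fmt <- if (grepl("\\.gff3?$", ip$annotations[[s]])) "gff3" else "tsv"
      read_annotation(ip$annotations[[s]], format = fmt, species_id = s)
    })
    names(annots) <- names(ip$annotations)
    orthomap <- read_orthology(ip$orthology, cfg$focal_species,
                               setdiff(names(annots), cfg$focal_species))
    expr <- lapply(names(ip$expression), function(s) {
      read_expression(ip$expression[[s]], species_id = s,
                      replicate_groups = "infer")
    })
    names(expr) <- names(ip$expression)
    feats <- list(
      tf_targets = read_gene_sets(ip$tf_targets, "tf_targets"),
      cellular_component = read_gene_sets(ip$cellular_component,
                                          "cellular_component"),
      essential = read_gene_sets(ip$essential, "essential"),
      network = read_interactions(ip$interactions)
    )
  } else if (dir.exists(sim_dir)) {
    files <- list.files(sim_dir, pattern = "^annotation_", full.names = TRUE)
    species <- sub("^annotation_(.*)\\.tsv$", "\\1", basename(files))
    annots <- stats::setNames(lapply(seq_along(files), function(i) {
      read_annotation(files[[i]], "tsv", species_id = species[[i]])
    }), species)
    orthomap <- read_orthology(file.path(sim_dir, "orthology.tsv"),
                               cfg$focal_species,
                               setdiff(species, cfg$focal_species))
    expr <- stats::setNames(lapply(species, function(s) {
      read_expression(file.path(sim_dir, paste0("expression_", s, ".tsv")),
                      species_id = s, replicate_groups = "infer")
    }), species)
    feats <- list(
      tf_targets = read_gene_sets(file.path(sim_dir, "tf_targets.gmt"),
                                  "tf_targets"),
      cellular_component =
        read_gene_sets(file.path(sim_dir, "cellular_component.gmt"),
                       "cellular_component"),
      essential = read_gene_sets(file.path(sim_dir, "essential.gmt"),
                                 "essential"),
      network = read_interactions(file.path(sim_dir, "interactions.tsv"))
    )
  } else {
    stop("no inputs configured and no simulated inputs found; ",
         "run the `simulate` stage first", call. = FALSE)
  }
  if (!cfg$focal_species %in% names(annots)) {
    stop("focal species ", cfg$focal_species, " has no annotation",
         call. = FALSE)
  }
  list(annots = annots, orthomap = orthomap, expr = expr, feats = feats)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order.  Each stage writes
#' its artifacts under `out_dir`; artifact TSVs carry a provenance comment
#' (config hash, seed, stage, package version).  Rerunning with an
#' identical config and seed reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or path/list coercible to one).
#' @param stages Subset of `simulate`, `identify`, `classify`,
#'   `exprstats`, `permtest`, `report`.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- list()
  th <- config$thresholds

  if ("simulate" %in% stages) {
    ns_log("stage simulate: generating synthetic dataset")
    sc_args <- config$simulate %||% list()
    sc_args$seed <- sc_args$seed %||% config$seed
    sc_args$min_intervening <- sc_args$min_intervening %||%
      th$min_intervening
    sim <- do.call(synth_config, sc_args)
    dataset <- simulate_dataset(sim)
    write_dataset(dataset, out("inputs"))
    artifacts$inputs <- out("inputs")
  }

  needs_inputs <- intersect(stages,
                            c("identify", "classify", "exprstats",
                              "permtest"))
  if (length(needs_inputs)) {
    inputs <- load_pipeline_inputs(config)
    focal_annot <- inputs$annots[[config$focal_species]]
    nf_annots <- inputs$annots[names(inputs$annots) != config$focal_species]
  }

  if ("identify" %in% stages) {
    ns_log("stage identify: classifying candidate pairs")
    pairs <- classify_pairs(nf_annots, inputs$orthomap,
                            eligibility_fraction = th$eligibility_fraction)
    write_artifact(pairs, out("pairs.tsv"), config, "identify")
    artifacts$pairs <- out("pairs.tsv")
  }

  if ("classify" %in% stages) {
    pairs <- read_artifact(out("pairs.tsv"))
    if (is.null(pairs)) {
      stop("missing artifact pairs.tsv; run the `identify` stage first",
           call. = FALSE)
    }
    ns_log("stage classify: deriving gene groups")
    assignment <- derive_groups(pairs, focal_annot,
                                min_intervening = th$min_intervening)
    groups_dt <- data.table::rbindlist(list(
      data.table::data.table(
        gene = assignment$ecns, group = "ecns",
        n_before_partners =
          lengths(assignment$before_partners[assignment$ecns]),
        exclusion_reason = ""),
      data.table::data.table(
        gene = assignment$necns, group = "necns",
        n_before_partners =
          lengths(assignment$before_partners[assignment$necns]),
        exclusion_reason = ""),
      data.table::data.table(
        gene = names(assignment$exclusion_log) %||% character(0),
        group = rep("excluded", length(assignment$exclusion_log)),
        n_before_partners = rep(0L, length(assignment$exclusion_log)),
        exclusion_reason = unname(assignment$exclusion_log))
    ))
    write_artifact(groups_dt, out("groups.tsv"), config, "classify")
    cp_all <- data.table::rbindlist(lapply(c("ecns", "necns"), function(g) {
      cp <- cross_pairs(assignment, g, focal_annot, inputs$orthomap,
                        nf_annots)
      if (!nrow(cp)) return(cp)
      mult <- unique_cross_pairs(cp)
      key <- pair_key(cp$before_gene, cp$after_gene)
      cp$multiplicity <- mult$multiplicity[match(
        key, pair_key(mult$before_gene, mult$after_gene))]
      cp
    }))
    write_artifact(cp_all, out("cross_pairs.tsv"), config, "classify")
    artifacts$groups <- out("groups.tsv")
    artifacts$cross_pairs <- out("cross_pairs.tsv")
  }

  if ("exprstats" %in% stages) {
    groups_dt <- read_artifact(out("groups.tsv"))
    cp_all <- read_artifact(out("cross_pairs.tsv"))
    if (is.null(groups_dt) || is.null(cp_all)) {
      stop("missing artifact groups.tsv/cross_pairs.tsv; run the ",
           "`classify` stage first", call. = FALSE)
    }
    ns_log("stage exprstats: divergence, coexpression and contrasts")
    prof <- expression_divergence(inputs$expr, inputs$orthomap,
                                  config$focal_species)
    div_dt <- data.table::data.table(gene = names(prof$divergence),
                                     divergence = unname(prof$divergence))
    write_artifact(div_dt, out("divergence.tsv"), config, "exprstats")

    ecns <- groups_dt$gene[groups_dt$group == "ecns"]
    necns <- groups_dt$gene[groups_dt$group == "necns"]
    fm <- inputs$expr[[config$focal_species]]
    rho_of_pairs <- function(pp) {
      if (is.null(pp) || !nrow(pp)) return(numeric(0))
      ok <- pp$before_gene %in% fm$genes & pp$after_gene %in% fm$genes
      pp <- pp[ok]
      vapply(seq_len(nrow(pp)), function(i) {
        spearman_coexpression(fm$values[pp$before_gene[[i]], ],
                              fm$values[pp$after_gene[[i]], ])
      }, numeric(1L))
    }
    coex <- list(
      ecns_cross = rho_of_pairs(unique_cross_pairs(
        cp_all[cp_all$group == "ecns", ])),
      necns_cross = rho_of_pairs(unique_cross_pairs(
        cp_all[cp_all$group == "necns", ])),
      background = coexpression_background(fm, n_pairs = 1e4L,
                                           seed = config$seed + 30L)
    )
    div_groups <- list(
      ecns_divergence = prof$divergence[names(prof$divergence) %in% ecns],
      necns_divergence = prof$divergence[names(prof$divergence) %in% necns]
    )
    contrast_row <- function(name, va, vb) {
      cg <- compare_groups(va, vb)
      ci_a <- bootstrap_median_ci(va, seed = config$seed + 10L)
      ci_b <- bootstrap_median_ci(vb, seed = config$seed + 11L)
      data.table::data.table(
        contrast = name, n_a = length(va), n_b = length(vb),
        median_a = stats::median(va, na.rm = TRUE),
        median_b = stats::median(vb, na.rm = TRUE),
        ci_a_low = ci_a[[1L]], ci_a_high = ci_a[[2L]],
        ci_b_low = ci_b[[1L]], ci_b_high = ci_b[[2L]],
        U = cg$U, p_value = cg$p_value)
    }
    contrasts <- data.table::rbindlist(list(
      contrast_row("divergence_ecns_vs_necns",
                   div_groups$ecns_divergence,
                   div_groups$necns_divergence),
      contrast_row("coexpression_ecns_cross_vs_necns_cross",
                   coex$ecns_cross[!is.na(coex$ecns_cross)],
                   coex$necns_cross[!is.na(coex$necns_cross)]),
      contrast_row("coexpression_ecns_cross_vs_background",
                   coex$ecns_cross[!is.na(coex$ecns_cross)],
                   coex$background)
    ))
    write_artifact(contrasts, out("contrasts.tsv"), config, "exprstats")
    dist_dt <- data.table::rbindlist(lapply(names(coex), function(g) {
      data.table::data.table(group = g, value = coex[[g]])
    }))
    write_artifact(dist_dt, out("distributions.tsv"), config, "exprstats")
    artifacts$divergence <- out("divergence.tsv")
    artifacts$contrasts <- out("contrasts.tsv")
    artifacts$distributions <- out("distributions.tsv")
  }

  if ("permtest" %in% stages) {
    cp_all <- read_artifact(out("cross_pairs.tsv"))
    if (is.null(cp_all)) {
      stop("missing artifact cross_pairs.tsv; run the `classify` stage ",
           "first", call. = FALSE)
    }
    ns_log("stage permtest: chromosome-matched randomization")
    pairs <- unique_cross_pairs(cp_all[cp_all$group == "ecns", ])
    rows <- lapply(seq_along(COFEATURES), function(i) {
      feature <- names(COFEATURES)[[i]]
      feats <- inputs$feats[[COFEATURES[[i]]]]
      seed_i <- config$seed + 20L + i
      res <- permutation_test(pairs, feats, feature, focal_annot,
                              n_iter = th$n_iter, seed = seed_i,
                              keep_null = FALSE)
      data.table::data.table(
        feature = feature, observed = res$observed_frequency,
        empirical_p = res$empirical_p,
        empirical_p_addone = res$empirical_p_addone,
        n_iter = res$n_iter, seed = seed_i)
    })
    write_artifact(data.table::rbindlist(rows),
                   out("permutation_report.tsv"), config, "permtest")
    artifacts$permutation_report <- out("permutation_report.tsv")
  }

  if ("report" %in% stages) {
    ns_log("stage report: JSON summary")
    groups_dt <- read_artifact(out("groups.tsv"))
    contrasts <- read_artifact(out("contrasts.tsv"))
    perm <- read_artifact(out("permutation_report.tsv"))
    if (is.null(groups_dt)) {
      stop("missing artifact groups.tsv; run the `classify` stage first",
           call. = FALSE)
    }
    report <- list(
      n_ecns = sum(groups_dt$group == "ecns"),
      n_necns = sum(groups_dt$group == "necns"),
      n_excluded = sum(groups_dt$group == "excluded"),
      contrasts = contrasts,
      permutation = perm,
      seed = config$seed
    )
    jsonlite::write_json(report, out("report.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
    artifacts$report <- out("report.json")
  }

  invisible(artifacts)
}
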
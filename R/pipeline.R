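#' Default end-to-end run configuration
#'
#' A nested parameter list driving [run_pipeline()] on fully synthetic
#' data: a toy genome and gene models, two ditag libraries of unequal
#' depth, and the packaged cross-platform panel. Every block can be
#' overridden; file-based inputs (existing FASTQ/FASTA/GFF3, domain or
#' homology tables) can be supplied instead of the simulation block.
#'
#' @param outdir output directory for all stage results.
#' @param seed global seed; each stochastic stage derives its own seed
#'   from it by a fixed offset.
#' @return nested configuration list.
#' @export
default_run_config <- function(outdir, seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = c("Myc", "S1-Pri"),
    simulate = list(
      genome = list(n_chromosomes = 3L, chromosome_length = 35000L,
                    n_genes = 30L, gene_length_range = c(900L, 2100L),
                    intergenic_min = 1100L, gc_content = 0.5,
                    duplicated_region_fraction = 0),
      truth = list(deg_fraction = 1/3, fold_range = c(3, 8),
                   antisense_fraction = 0.15),
      reads = list(n_reads_per_stage = c(2000L, 3000L), error_rate = 0,
                   degraded_read_fraction = 0.02)
    ),
    layout = list(),                      # ditag_layout() overrides
    quality = list(min_mean_q = 20, min_base_q = 10),
    extraction = list(drop_singletons = TRUE),
    de = list(alpha = 0.05, pseudo_tphk = 1.0, fold_threshold = 3,
              adjust = "none"),
    enrichment = list(max_e = 1e-20),
    validation = list(panel = NULL)       # NULL: packaged 18-gene panel
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_run_config()];
#'   unspecified blocks fall back to the defaults.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$outdir)) stopf("config must set outdir")
  base <- default_run_config(user$outdir, seed = user$seed %||% 1L)
  cfg <- utils::modifyList(base, user)
  validate_run_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  for (p in c(cfg$genome_fasta, cfg$models_gff3, cfg$reads_fastq,
              cfg$domains_tsv, unlist(cfg$homology_reports),
              cfg$validation$panel)) {
    if (!is.null(p) && !file.exists(p)) stopf("input path does not exist: %s", p)
  }
  if (!is.null(cfg$de)) do.call(de_config, cfg$de)        # validates
  if (!is.null(cfg$layout)) do.call(ditag_layout, cfg$layout)
  invisible(cfg)
}

#' Run the full 5'-SAGE analysis pipeline
#'
#' Executes the stages in dependency order -- simulate (unless read/genome
#' files are supplied), extract, map, annotate, quantify/test, enrich
#' (when domain or homology inputs are configured) and validate -- writing
#' every stage's tables under `config$outdir` together with a JSON
#' manifest recording the package version, seed, parameters, per-stage
#' row counts and output checksums. A rerun over an existing manifest
#' skips stages whose outputs are present with unchanged checksums.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly (list; element `stages` holds per-stage
#'   status, row counts and checksums).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest_path <- file.path(outdir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else NULL
  cfg_digest <- digest_config(config)
  resume <- !is.null(prev) && identical(prev$config_digest, cfg_digest)
  manifest <- list(package = "sagetag",
                   version = as.character(utils::packageVersion("sagetag")),
                   seed = config$seed, config_digest = cfg_digest,
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, outputs, fun) {
    if (resume && stage_intact(prev, name, outdir, outputs)) {
      say("stage %-9s: reusing previous outputs", name)
      fun(reuse = TRUE)
      manifest$stages[[name]] <<- prev$stages[[name]]
      return(invisible())
    }
    say("stage %-9s: running", name)
    info <- tryCatch(fun(reuse = FALSE), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    files <- file.path(outdir, outputs)
    manifest$stages[[name]] <<- list(
      status = "completed", outputs = outputs,
      checksums = as.list(stats::setNames(unname(tools::md5sum(files)), outputs)),
      rows = info %||% list())
    write_manifest(manifest, manifest_path)
  }

  layout <- do.call(ditag_layout, config$layout %||% list())

  ## ---- simulate -------------------------------------------------------
  sim_outputs <- c("genome.fa", "models.gff3", "reads_Myc.fastq",
                   "reads_S1-Pri.fastq", "truth.tsv")
  run_stage("simulate", sim_outputs, function(reuse) {
    if (reuse) {
      state$genome <- Biostrings::readDNAStringSet(file.path(outdir, "genome.fa"))
      names(state$genome) <- sub(" .*", "", names(state$genome))
      state$models <- read_models_gff3(file.path(outdir, "models.gff3"))
      state$reads <- lapply(stats::setNames(config$stages, config$stages),
        function(s) read_fastq(file.path(outdir, sprintf("reads_%s.fastq", s))))
      state$truth <- utils::read.delim(file.path(outdir, "truth.tsv"),
                                       stringsAsFactors = FALSE)
      return(NULL)
    }
    if (!is.null(config$genome_fasta)) {
      state$genome <- Biostrings::readDNAStringSet(config$genome_fasta)
      names(state$genome) <- sub(" .*", "", names(state$genome))
      state$models <- read_models_gff3(config$models_gff3)
      state$reads <- lapply(stats::setNames(config$reads_fastq, config$stages),
                            read_fastq)
      state$truth <- data.frame()
    } else {
      g <- config$simulate$genome
      spec <- genome_spec(
        n_chromosomes = g$n_chromosomes,
        chromosome_length = g$chromosome_length, n_genes = g$n_genes,
        gene_length_range = g$gene_length_range,
        intergenic_min = g$intergenic_min, gc_content = g$gc_content,
        duplicated_region_fraction = g$duplicated_region_fraction,
        seed = config$seed)
      gen <- generate_genome(spec)
      tr <- config$simulate$truth
      truths <- simulate_truth(gen$models, deg_fraction = tr$deg_fraction,
                               fold_range = tr$fold_range,
                               seed = config$seed + 1L,
                               antisense_fraction = tr$antisense_fraction)
      rd <- config$simulate$reads
      sim <- simulate_reads(gen$genome, gen$models, truths, layout,
                            n_reads_per_stage = rd$n_reads_per_stage,
                            error_rate = rd$error_rate,
                            seed = config$seed + 2L,
                            stages = config$stages,
                            degraded_read_fraction = rd$degraded_read_fraction)
      state$genome <- gen$genome
      state$models <- gen$models
      state$reads <- sim$reads
      state$truth <- sim$truth
      state$truths <- truths
    }
    write_genome_fasta(state$genome, file.path(outdir, "genome.fa"))
    write_models_gff3(state$models, state$genome, file.path(outdir, "models.gff3"))
    for (s in names(state$reads)) {
      write_fastq(state$reads[[s]], file.path(outdir, sprintf("reads_%s.fastq", s)))
    }
    utils::write.table(state$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(genes = nrow(state$models),
         reads = vapply(state$reads, nrow, 0L))
  })

  ## ---- extract --------------------------------------------------------
  tag_files <- sprintf("tags_%s.tsv", config$stages)
  run_stage("extract", tag_files, function(reuse) {
    if (reuse) {
      state$tables <- lapply(stats::setNames(config$stages, config$stages),
        function(s) read_tag_table(file.path(outdir, sprintf("tags_%s.tsv", s)), s))
      return(NULL)
    }
    state$tables <- list()
    info <- list()
    for (s in config$stages) {
      pl <- process_library(state$reads[[s]], layout, s,
                            min_mean_q = config$quality$min_mean_q,
                            min_base_q = config$quality$min_base_q,
                            drop_singletons = config$extraction$drop_singletons)
      state$tables[[s]] <- pl$table
      write_tag_table(pl$table, file.path(outdir, sprintf("tags_%s.tsv", s)))
      info[[s]] <- pl$stats
    }
    jsonlite::write_json(info, file.path(outdir, "extraction_stats.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    lapply(info, function(x) x[c("n_in", "n_retained", "total_valid_tags")])
  })

  ## ---- map ------------------------------------------------------------
  hit_files <- sprintf("hits_%s.tsv", config$stages)
  run_stage("map", c(hit_files, "mapping_summary.tsv"), function(reuse) {
    lens <- sort(unique(nchar(unlist(lapply(state$tables,
                                            function(t) t$entries$tag)))))
    index <- build_index(state$genome, lens)
    state$mappings <- lapply(state$tables, function(t) map_tags(t, index))
    for (s in config$stages) {
      utils::write.table(
        cbind(state$mappings[[s]]$unique_hits,
              class = "unique")[, c("tag", "count", "chrom", "pos", "strand", "class")],
        file.path(outdir, sprintf("hits_%s.tsv", s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summ <- do.call(mapping_summary, unname(state$mappings))
    utils::write.table(summ, file.path(outdir, "mapping_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lapply(state$mappings, function(m) list(
      total = m$total_valid_tags,
      unique = m$summary$tag_occurrences[m$summary$class == "unique"]))
  })

  ## ---- annotate -------------------------------------------------------
  class_files <- sprintf("classification_%s.tsv", config$stages)
  run_stage("annotate", c(class_files, "category_summary.tsv",
                          "tss_catalog.tsv", "tss_sites.bed"), function(reuse) {
    lens <- chrom_lengths(state$genome)
    state$annotations <- lapply(
      stats::setNames(config$stages, config$stages), function(s) {
        annotate_library(state$mappings[[s]]$unique_hits, state$models,
                         lens, stage = s)
      })
    for (s in config$stages) {
      utils::write.table(state$annotations[[s]]$classified,
                         file.path(outdir, sprintf("classification_%s.tsv", s)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summ <- do.call(rbind, lapply(state$annotations, function(a) {
      cbind(stage = a$stage, a$summary)
    }))
    utils::write.table(summ, file.path(outdir, "category_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    all_class <- do.call(rbind, lapply(state$annotations, `[[`, "classified"))
    state$catalog <- build_tss_catalogs(all_class)
    utils::write.table(state$catalog, file.path(outdir, "tss_catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_tss_bed(state$catalog, all_class, file.path(outdir, "tss_sites.bed"))
    list(tss_sites = nrow(state$catalog))
  })

  ## ---- de -------------------------------------------------------------
  run_stage("de", c("expression.tsv", "deg_summary.tsv"), function(reuse) {
    s1 <- config$stages[1]; s2 <- config$stages[2]
    counts <- gene_counts(state$annotations[[s1]]$classified,
                          state$annotations[[s2]]$classified)
    tot1 <- state$annotations[[s1]]$total_unique_mapped
    tot2 <- state$annotations[[s2]]$total_unique_mapped
    expr <- quantify(counts, tot1, tot2)
    cfg <- do.call(de_config, config$de)
    state$de <- call_degs(expr, tot1, tot2, cfg)
    utils::write.table(state$de$genes, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(state$de$summary, file.path(outdir, "deg_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(assessed = state$de$n_assessed,
         deg = sum(state$de$genes$is_deg))
  })

  ## ---- enrich (optional) ---------------------------------------------
  if (!is.null(config$domains_tsv) || !is.null(config$homology_reports)) {
    run_stage("enrich", c("enrichment.tsv", "lineage.tsv"), function(reuse) {
      g <- state$de$genes
      info <- list()
      enr <- data.frame()
      if (!is.null(config$domains_tsv)) {
        asg <- read_domain_table(config$domains_tsv,
                                 max_e = config$enrichment$max_e)
        universe <- state$models$gene_id
        for (dir in c("myc_up", "pri_up")) {
          deg <- g$gene_id[g$deg_direction == dir]
          if (length(deg) == 0L) next
          res <- domain_enrichment(asg, deg, universe)
          if (nrow(res)) enr <- rbind(enr, cbind(deg_set = dir, res))
        }
        info$enriched <- sum(enr$enriched)
      }
      utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lin <- data.frame()
      if (!is.null(config$homology_reports)) {
        reports <- lapply(config$homology_reports, read_blast_tab)
        for (sp in names(reports)) reports[[sp]]$species <- sp
        bh <- best_hits(reports)
        degs <- g$gene_id[g$is_deg]
        lin <- classify_lineage(degs, bh, config$fbf_species,
                                config$outgroup_species)
        info$lineage_classified <- nrow(lin)
      }
      utils::write.table(lin, file.path(outdir, "lineage.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      info
    })
  }

  ## ---- validate -------------------------------------------------------
  run_stage("validate", "validation.json", function(reuse) {
    panel <- if (is.null(config$validation$panel)) validation_panel()
             else read_platform_table(config$validation$panel)
    rep <- validate_report(panel)
    jsonlite::write_json(rep$correlations,
                         file.path(outdir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(pairs = nrow(rep$correlations))
  })

  write_manifest(manifest, manifest_path)
  say("pipeline completed: %d stages", length(manifest$stages))
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$outdir <- NULL
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_intact <- function(prev, name, outdir, outputs) {
  st <- prev$stages[[name]]
  if (is.null(st) || !identical(st$status, "completed")) return(FALSE)
  if (!setequal(unlist(st$outputs), outputs)) return(FALSE)
  files <- file.path(outdir, outputs)
  if (!all(file.exists(files))) return(FALSE)
  sums <- unname(tools::md5sum(files))
  all(vapply(seq_along(outputs), function(i) {
    identical(st$checksums[[outputs[i]]], sums[i])
  }, logical(1)))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
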
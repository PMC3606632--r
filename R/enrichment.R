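#' Read and filter a domain-assignment table
#'
#' @param path TSV with columns orf_id, domain_id, e_value.
#' @param max_e retain assignments with e-value strictly below this
#'   threshold (the study assigned conserved domains at e < 1e-20).
#' @return data.frame of retained assignments.
#' @export
read_domain_table <- function(path, max_e = 1e-20) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("orf_id", "domain_id", "e_value") %in% names(df)))
  filter_domain_assignments(df, max_e)
}

#' @rdname read_domain_table
#' @param assignments data.frame with orf_id, domain_id, e_value.
#' @export
filter_domain_assignments <- function(assignments, max_e = 1e-20) {
  assignments[assignments$e_value < max_e, , drop = FALSE]
}

#' Protein-domain enrichment of a DEG set
#'
#' One-sided (over-representation) Fisher exact test per domain:
#' domain-bearing ORFs inside and outside the DEG set against the ORF
#' universe. ORF-level presence/absence is counted, so an ORF carrying a
#' domain twice contributes once. A domain is enriched when its p-value is
#' below `alpha`.
#'
#' @param assignments filtered domain assignments (orf_id, domain_id).
#' @param deg_set character vector of DEG ORF ids; must be contained in
#'   `universe`.
#' @param universe character vector of all ORF ids.
#' @param alpha enrichment threshold (default 0.05, unadjusted, as in the
#'   study).
#' @return data.frame: domain_id, k_deg, n_deg, k_all, n_all, p_value,
#'   enriched; one row per domain present in the universe.
#' @export
domain_enrichment <- function(assignments, deg_set, universe, alpha = 0.05) {
  deg_set <- unique(deg_set)
  universe <- unique(universe)
  missing <- setdiff(deg_set, universe)
  if (length(missing)) {
    stopf("DEG gene(s) absent from the universe: %s",
          paste(missing, collapse = ", "))
  }
  asg <- unique(assignments[assignments$orf_id %in% universe,
                            c("orf_id", "domain_id")])
  n_all <- length(universe)
  n_deg <- length(deg_set)
  if (nrow(asg) == 0L) {
    return(data.frame(domain_id = character(0), k_deg = integer(0),
                      n_deg = integer(0), k_all = integer(0),
                      n_all = integer(0), p_value = numeric(0),
                      enriched = logical(0)))
  }
  k_all <- tapply(asg$orf_id, asg$domain_id, function(x) length(unique(x)))
  in_deg <- asg[asg$orf_id %in% deg_set, , drop = FALSE]
  k_deg <- tapply(in_deg$orf_id, in_deg$domain_id,
                  function(x) length(unique(x)))
  domains <- sort(names(k_all))
  kd <- ifelse(domains %in% names(k_deg), k_deg[domains], 0L)
  ka <- as.integer(k_all[domains])
  # P(X >= k_deg), X ~ Hypergeometric(k_all, n_all - k_all, n_deg)
  p <- stats::phyper(kd - 1L, ka, n_all - ka, n_deg, lower.tail = FALSE)
  data.frame(domain_id = domains, k_deg = as.integer(kd), n_deg = n_deg,
             k_all = ka, n_all = n_all, p_value = p,
             enriched = p < alpha, stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a 12-column tabular homology report
#'
#' Standard tabular best-hit output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, q.start, q.end, s.start,
#' s.end, e-value, bit score).
#'
#' @param path report file (tab-separated, no header).
#' @param species label attached to every hit.
#' @return data.frame: gene_id, subject_id, e_value, species.
#' @export
read_blast_tab <- function(path, species = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(0), subject_id = character(0),
                      e_value = numeric(0), species = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    stopf("malformed homology report %s: line %d has %d fields (12 expected)",
          path, which(nf != 12L)[1], nf[nf != 12L][1])
  }
  ev <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 11L)))
  if (anyNA(ev)) {
    stopf("malformed homology report %s: non-numeric e-value at line %d",
          path, which(is.na(ev))[1])
  }
  data.frame(gene_id = vapply(parts, `[[`, "", 1L),
             subject_id = vapply(parts, `[[`, "", 2L),
             e_value = ev, species = species, stringsAsFactors = FALSE)
}

#' Per-species best e-values from a set of homology reports
#'
#' @param reports named list of report data.frames (from
#'   [read_blast_tab()]); names are species labels.
#' @return data.frame: gene_id, species, e_value (best, i.e. minimum,
#'   per gene and species).
#' @export
best_hits <- function(reports) {
  parts <- lapply(names(reports), function(sp) {
    df <- reports[[sp]]
    if (nrow(df) == 0L) return(NULL)
    best <- stats::aggregate(e_value ~ gene_id, data = df, FUN = min)
    best$species <- sp
    best
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), e_value = numeric(0),
                      species = character(0))
  }
  out[, c("gene_id", "species", "e_value")]
}

#' Classify DEGs by lineage specificity
#'
#' Applies the study's homology filters to per-species best hits:
#' hits with e > `e_weak` (default 1e-2) are too dissimilar to count as
#' homology signals, and e < `e_strong` (default 1e-10) indicates a
#' homolog. A gene is `basidiomycete_unique` when it has homologs
#' (e < `e_strong`) in at least two fruiting-body-forming basidiomycetes
#' and no hit at all (e <= `e_weak`) outside them; `species_unique` when
#' no species shows a homolog below `e_strong`; otherwise `neither`. Any
#' outgroup hit at e <= `e_weak` forces `neither`. The query genome itself
#' is not among the reports, so self-hits never count.
#'
#' @param gene_ids genes to classify (DEGs, typically).
#' @param hits best-hit data.frame from [best_hits()].
#' @param fbf_species labels of the fruiting-body-forming species.
#' @param outgroup_species labels of all other species in the reports.
#' @param e_strong,e_weak homology and dissimilarity thresholds.
#' @return data.frame: gene_id, n_fbf_strong, outgroup_hit,
#'   classification (`basidiomycete_unique | species_unique | neither`).
#' @export
classify_lineage <- function(gene_ids, hits, fbf_species, outgroup_species,
                             e_strong = 1e-10, e_weak = 1e-2) {
  extra <- setdiff(unique(hits$species), c(fbf_species, outgroup_species))
  if (length(extra)) {
    stopf("hit species not declared as fruiting-body-forming or outgroup: %s",
          paste(extra, collapse = ", "))
  }
  out <- lapply(gene_ids, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    fbf_strong <- sum(h$species %in% fbf_species & h$e_value < e_strong)
    outgroup_hit <- any(h$species %in% outgroup_species & h$e_value <= e_weak)
    any_strong <- any(h$e_value < e_strong)
    cls <- if (outgroup_hit) {
      "neither"
    } else if (fbf_strong >= 2L) {
      "basidiomycete_unique"
    } else if (!any_strong) {
      "species_unique"
    } else {
      "neither"
    }
    data.frame(gene_id = g, n_fbf_strong = fbf_strong,
               outgroup_hit = outgroup_hit, classification = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
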
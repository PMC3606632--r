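hit <- function(pos, strand, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count = 1L, stringsAsFactors = FALSE)
}

test_that("window classification follows category and offset definitions", {
  models <- two_gene_models()
  cl <- function(pos, strand) {
    classify_hits(hit(pos, strand), models, two_gene_chrom_len)
  }
  # plus-strand gene GA: coding 1000-1999
  r <- cl(950, "+")
  expect_identical(as.character(r$category), "utr5_sense")
  expect_identical(r$gene_id, "GA")
  expect_equal(r$offset, -50L)
  expect_identical(as.character(cl(950, "-")$category), "utr5_antisense")
  expect_identical(as.character(cl(1500, "+")$category), "cds_sense")
  expect_identical(as.character(cl(1500, "-")$category), "cds_antisense")
  r3 <- cl(2100, "+")
  expect_identical(as.character(r3$category), "utr3_sense")
  expect_equal(r3$offset, 101L)
  # window boundaries: -500 in, -501 out
  expect_identical(as.character(cl(500, "+")$category), "utr5_sense")
  expect_identical(as.character(cl(499, "+")$category), "unclassified")
  expect_true(is.na(cl(499, "+")$gene_id))

  # minus-strand gene GB: coding_start 3999, coding_end 3000
  r4 <- cl(4049, "-")
  expect_identical(as.character(r4$category), "utr5_sense")
  expect_identical(r4$gene_id, "GB")
  expect_equal(r4$offset, -50L)
  expect_identical(as.character(cl(3500, "+")$category), "cds_antisense")
  r5 <- cl(2950, "-")
  expect_identical(as.character(r5$category), "utr3_sense")
  expect_equal(r5$offset, 50L)
  expect_identical(as.character(cl(4499, "-")$category), "utr5_sense")
  expect_identical(as.character(cl(4500, "-")$category), "unclassified")
})

test_that("overlapping windows resolve by category priority, then proximity", {
  # two plus-strand genes whose 5'-UTR windows overlap the same position
  models <- data.frame(
    gene_id = c("near", "far"), chrom = "chr1", strand = "+",
    gene_left = c(1000L, 1300L), gene_right = c(1099L, 1399L),
    coding_start = c(1000L, 1300L), coding_end = c(1099L, 1399L),
    stringsAsFactors = FALSE)
  r <- classify_hits(hit(960, "+"), models, c(chr1 = 3000L))
  expect_identical(r$gene_id, "near")       # 40 bp vs 340 bp to start codon
  expect_identical(as.character(r$category), "utr5_sense")
  # inside gene "near" and upstream of "far": sense CDS outranks utr5 of
  # the farther gene only through the utr5-first priority, so utr5 wins
  r2 <- classify_hits(hit(1050, "+"), models, c(chr1 = 3000L))
  expect_identical(as.character(r2$category), "utr5_sense")
  expect_identical(r2$gene_id, "far")
  # antisense never outranks a sense category at the same position
  r3 <- classify_hits(hit(1050, "-"), models, c(chr1 = 3000L))
  expect_identical(as.character(r3$category), "utr5_antisense")
})

test_that("windows clip at chromosome ends but keep their category", {
  models <- data.frame(gene_id = "edge", chrom = "chr1", strand = "+",
                       gene_left = 100L, gene_right = 399L,
                       coding_start = 100L, coding_end = 399L,
                       stringsAsFactors = FALSE)
  r <- classify_hits(hit(10, "+"), models, c(chr1 = 600L))
  expect_identical(as.character(r$category), "utr5_sense")
  expect_equal(r$offset, -90L)
  r2 <- classify_hits(hit(550, "+"), models, c(chr1 = 600L))
  expect_identical(as.character(r2$category), "utr3_sense")
})

test_that("library annotation partitions the unique-mapped total", {
  fx <- errorfree_sim()
  for (s in names(fx$anns)) {
    ann <- fx$anns[[s]]
    expect_equal(sum(ann$summary$tag_occurrences), ann$total_unique_mapped)
    expect_equal(sum(ann$summary$percent), 100)
  }
})

test_that("flipping every gene strand swaps sense and antisense counts exactly", {
  fx <- errorfree_sim()
  ann <- fx$anns[[1]]
  flipped_models <- fx$gen$models
  flipped_models$strand <- ifelse(flipped_models$strand == "+", "-", "+")
  tmp <- flipped_models$coding_start
  flipped_models$coding_start <- flipped_models$coding_end
  flipped_models$coding_end <- tmp
  # keep the same windows: for the flipped gene the utr5 window lies where
  # the utr3 window was, so only sense<->antisense within the cds region is
  # an exact swap; check that one directly
  ann_f <- annotate_library(fx$maps[[1]]$unique_hits, flipped_models,
                            fx$chrom_len)
  get <- function(a, cat) a$summary$tag_occurrences[a$summary$category == cat]
  expect_equal(get(ann_f, "cds_sense"), get(ann, "cds_antisense"))
  expect_equal(get(ann_f, "cds_antisense"), get(ann, "cds_sense"))
})

test_that("antisense-free simulations produce empty antisense rows", {
  gen <- generate_genome(genome_spec(n_chromosomes = 1L,
                                     chromosome_length = 20000L,
                                     n_genes = 5L, seed = 61L))
  truths <- simulate_truth(gen$models, deg_fraction = 0, seed = 62L,
                           antisense_fraction = 0)
  sim <- simulate_reads(gen$genome, gen$models, truths, ditag_layout(),
                        n_reads_per_stage = c(400L, 400L), seed = 63L,
                        degraded_read_fraction = 0)
  lib <- process_library(sim$reads[[1]], ditag_layout(), "Myc",
                         drop_singletons = FALSE)
  idx <- build_index(gen$genome, 15:20)
  mp <- map_tags(lib$table, idx)
  ann <- annotate_library(mp$unique_hits, gen$models,
                          sagetag:::chrom_lengths(gen$genome))
  anti <- grepl("antisense", ann$summary$category)
  expect_true(all(ann$summary$tag_occurrences[anti] == 0L))
  # with every profile offset <= 500, all sense tags land in the 5'-UTR
  expect_equal(ann$summary$tag_occurrences[ann$summary$category == "utr5_sense"],
               ann$total_unique_mapped)
})

test_that("TSS catalogues recover preferred sites and conserve occurrences", {
  cl1 <- data.frame(chrom = "chr1", pos = 900L, strand = "+",
                    count = 7L, category = factor("utr5_sense",
                                                  levels = sagetag:::CATEGORY_LEVELS),
                    gene_id = "solo", offset = -100L)
  cat1 <- build_tss_catalogs(cl1)
  expect_equal(nrow(cat1), 1L)
  expect_true(cat1$preferred)

  # two-site profile 0.6/0.4 over 500 tags: both sites become preferred
  models <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                       gene_left = 1000L, gene_right = 1999L,
                       coding_start = 1000L, coding_end = 1999L,
                       stringsAsFactors = FALSE)
  truths <- data.frame(gene_id = "G1", abundance_myc = 1, abundance_pri = 1,
                       antisense_fraction = 0, stringsAsFactors = FALSE)
  truths$tss_profile <- list(data.frame(offset = c(30L, 80L),
                                        weight = c(0.6, 0.4)))
  genome <- stats::setNames(withr::with_seed(64L,
                                             sagetag:::random_dna(3000L, 0.5)), "chr1")
  sim <- simulate_reads(genome, models, truths, ditag_layout(),
                        n_reads_per_stage = c(250L, 10L), seed = 65L,
                        degraded_read_fraction = 0)
  lib <- process_library(sim$reads[[1]], ditag_layout(), "Myc",
                         drop_singletons = FALSE)
  idx <- build_index(genome, 15:20)
  ann <- annotate_library(map_tags(lib$table, idx)$unique_hits, models,
                          c(chr1 = 3000L))
  cat2 <- build_tss_catalogs(ann$classified)
  expect_setequal(cat2$tss[cat2$preferred], c(970L, 920L))
  # conservation: catalogued occurrences equal the utr5_sense occurrences
  expect_equal(sum(cat2$count),
               ann$summary$tag_occurrences[ann$summary$category == "utr5_sense"])

  # the runner-up is only preferred at >= half the top count
  cl3 <- data.frame(chrom = "chr1", pos = c(900L, 950L), strand = "+",
                    count = c(10L, 4L),
                    category = factor(rep("utr5_sense", 2),
                                      levels = sagetag:::CATEGORY_LEVELS),
                    gene_id = "G2", offset = c(-100L, -50L))
  cat3 <- build_tss_catalogs(cl3)
  expect_equal(cat3$preferred, c(TRUE, FALSE))
})

test_that("catalogued TSS coordinates are generator TSSs in error-free runs", {
  fx <- errorfree_sim()
  all_class <- do.call(rbind, lapply(fx$anns, `[[`, "classified"))
  catalog <- build_tss_catalogs(all_class)
  truth_tss <- unique(fx$sim$truth$tss[!fx$sim$truth$antisense])
  expect_true(all(catalog$tss %in% truth_tss))
})
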
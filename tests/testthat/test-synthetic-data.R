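test_that("genome generation is deterministic and handles the gene-free case", {
  spec0 <- genome_spec(n_chromosomes = 1L, chromosome_length = 5000L,
                       n_genes = 0L, seed = 11L)
  g0 <- generate_genome(spec0)
  expect_equal(nrow(g0$models), 0L)
  expect_equal(unname(Biostrings::width(g0$genome)), 5000L)

  spec <- genome_spec(seed = 7L)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models, b$models)
})

test_that("gene packing respects windows, spacing and chromosome bounds", {
  for (seed in c(1L, 23L, 99L)) {
    gen <- generate_genome(genome_spec(seed = seed))
    m <- gen$models
    expect_true(all(m$gene_left - 500L >= 1L))
    expect_true(all(m$gene_right + 500L <=
                      sagetag:::chrom_lengths(gen$genome)[m$chrom]))
    for (ch in unique(m$chrom)) {
      mc <- m[m$chrom == ch, ]
      mc <- mc[order(mc$gene_left), ]
      if (nrow(mc) > 1L) {
        gaps <- mc$gene_left[-1] - mc$gene_right[-nrow(mc)] - 1L
        expect_true(all(gaps >= 1100L))
      }
    }
  }
  expect_error(generate_genome(genome_spec(n_chromosomes = 1L,
                                           chromosome_length = 3000L,
                                           n_genes = 5L, seed = 1L)),
               "cannot pack")
})

test_that("duplicated-region fraction creates repeated 20-mers (k-mer scan oracle)", {
  gen <- generate_genome(genome_spec(n_chromosomes = 1L,
                                     chromosome_length = 20000L,
                                     n_genes = 4L,
                                     duplicated_region_fraction = 0.1,
                                     seed = 5L))
  s <- as.character(gen$genome[[1]])
  starts <- seq_len(nchar(s) - 19L)
  kmers <- substring(s, starts, starts + 19L)
  expect_gte(max(table(kmers)), 2L)

  # and without duplication the same scan finds none (random 20-mers in a
  # 20 kb chromosome collide with probability ~ 2e-7)
  gen0 <- generate_genome(genome_spec(n_chromosomes = 1L,
                                      chromosome_length = 20000L,
                                      n_genes = 4L,
                                      duplicated_region_fraction = 0,
                                      seed = 5L))
  s0 <- as.character(gen0$genome[[1]])
  kmers0 <- substring(s0, starts, starts + 19L)
  expect_equal(max(table(kmers0)), 1L)
})

test_that("expression truth satisfies its share and fold invariants", {
  models <- fake_models(300L)

  null_truth <- simulate_truth(models, deg_fraction = 0, seed = 31L)
  expect_false(any(null_truth$is_deg))
  expect_equal(null_truth$abundance_myc, null_truth$abundance_pri)
  expect_equal(sum(null_truth$abundance_myc), 1)

  tr <- simulate_truth(models, deg_fraction = 1/3, fold_range = c(3, 8),
                       seed = 32L)
  expect_equal(sum(tr$is_deg), 100L)
  expect_equal(sum(tr$abundance_myc), 1)
  expect_equal(sum(tr$abundance_pri), 1)
  nd <- !tr$is_deg
  expect_equal(tr$abundance_myc[nd], tr$abundance_pri[nd])
  expect_equal(tr$true_log2_fold[nd], rep(0, sum(nd)))
  lfc <- abs(tr$true_log2_fold[tr$is_deg])
  expect_true(all(lfc >= log2(3) - 1e-12 & lfc <= 3 + 1e-12))
  # realised fold equals the recorded truth exactly
  expect_equal(log2(tr$abundance_myc / tr$abundance_pri), tr$true_log2_fold)
  # TSS profiles: weights sum to 1, offsets within the promoter window
  for (p in tr$tss_profile[1:20]) {
    expect_equal(sum(p$weight), 1)
    expect_true(all(p$offset >= 1 & p$offset <= 500))
  }
})

test_that("an odd DEG count is balanced without distorting folds", {
  tr <- simulate_truth(fake_models(40L), deg_fraction = 5 / 40,
                       fold_range = c(3, 8), seed = 33L)
  expect_equal(sum(tr$is_deg), 5L)
  expect_equal(sum(tr$abundance_myc), 1)
  expect_equal(sum(tr$abundance_pri), 1)
  expect_equal(tr$abundance_myc[!tr$is_deg], tr$abundance_pri[!tr$is_deg])
  lfc <- abs(tr$true_log2_fold[tr$is_deg])
  expect_true(all(lfc >= log2(3) - 1e-12 & lfc <= 3 + 1e-12))
  expect_error(simulate_truth(fake_models(10L), deg_fraction = 0.1),
               "single DEG")
})

test_that("error-free reads reproduce genome substrings at recorded TSSs", {
  fx <- errorfree_sim()
  tr <- fx$sim$truth
  expect_equal(nrow(tr), 2L * (1200L + 1800L))
  genome <- as.character(fx$gen$genome)
  sense <- tr[!tr$antisense, ][1:200, ]
  m <- fx$gen$models[match(sense$gene_id, fx$gen$models$gene_id), ]
  for (i in seq_len(nrow(sense))) {
    L <- nchar(sense$tag[i])
    if (sense$strand[i] == "+") {
      expect_identical(sense$tag[i],
                       substr(genome[[m$chrom[i]]], sense$tss[i],
                              sense$tss[i] + L - 1L))
    } else {
      expect_identical(sense$tag[i],
                       sagetag:::revcomp(substr(genome[[m$chrom[i]]],
                                                sense$tss[i] - L + 1L,
                                                sense$tss[i])))
    }
  }
  # sense TSSs sit 1-500 bp upstream of the start codon on the gene strand
  off <- ifelse(m$strand == "+", m$coding_start - sense$tss,
                sense$tss - m$coding_start)
  expect_true(all(off >= 1L & off <= 500L))
})

test_that("tag sampling follows the stage abundances (binomial bound)", {
  truths <- data.frame(gene_id = c("G1", "G2"),
                       abundance_myc = c(0.8, 0.2),
                       abundance_pri = c(0.8, 0.2),
                       antisense_fraction = 0, stringsAsFactors = FALSE)
  truths$tss_profile <- list(data.frame(offset = 100L, weight = 1),
                             data.frame(offset = 100L, weight = 1))
  models <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                       strand = "+", gene_left = c(1000L, 4000L),
                       gene_right = c(1999L, 4999L),
                       coding_start = c(1000L, 4000L),
                       coding_end = c(1999L, 4999L), stringsAsFactors = FALSE)
  genome <- stats::setNames(
    withr::with_seed(1L, sagetag:::random_dna(6000L, 0.5)), "chr1")
  sim <- simulate_reads(genome, models, truths, ditag_layout(),
                        n_reads_per_stage = c(5000L, 100L), seed = 55L,
                        degraded_read_fraction = 0)
  tr <- sim$truth[sim$truth$stage == "Myc", ]
  frac <- mean(tr$gene_id == "G1")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(tr)))
})

test_that("simulated FASTQ/FASTA/GFF bytes are seed-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    gen <- generate_genome(genome_spec(n_chromosomes = 1L,
                                       chromosome_length = 15000L,
                                       n_genes = 4L, seed = 77L))
    truths <- simulate_truth(gen$models, deg_fraction = 0.5, seed = 78L)
    sim <- simulate_reads(gen$genome, gen$models, truths, ditag_layout(),
                          n_reads_per_stage = c(100L, 100L), seed = 79L)
    write_genome_fasta(gen$genome, file.path(d, "g.fa"))
    write_models_gff3(gen$models, gen$genome, file.path(d, "m.gff3"))
    write_fastq(sim$reads[[1]], file.path(d, "r.fastq"))
  }
  for (f in c("g.fa", "m.gff3", "r.fastq")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
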
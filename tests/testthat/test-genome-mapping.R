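test_that("index queries agree with a brute-force scan of a tiny genome", {
  genome <- c(chr1 = "ACGTACGT")
  idx <- build_index(genome, 4L)
  got <- query_index(idx, "ACGT")
  want <- naive_scan(genome, "ACGT")
  expect_equal(got$pos, want$pos)
  expect_equal(got$strand, want$strand)
  # ACGT is its own reverse complement: forward at 1,5; minus 5' ends at 4,8
  expect_setequal(paste(got$pos, got$strand), c("1 +", "5 +", "4 -", "8 -"))

  expect_equal(nrow(query_index(build_index(c(chr1 = strrep("T", 30)), 4L),
                                "ACGT")), 0L)
})

test_that("every genome substring finds its own coordinate (self-query oracle)", {
  genome <- c(chrA = withr::with_seed(13L, sagetag:::random_dna(1000L, 0.5)))
  idx <- build_index(genome, 15L)
  positions <- seq(1L, 986L, by = 7L)
  tags <- substring(genome[["chrA"]], positions, positions + 14L)
  hits <- query_index(idx, tags)
  for (i in seq_along(positions)) {
    h <- hits[hits$tag == tags[i], ]
    expect_true(any(h$pos == positions[i] & h$strand == "+"))
  }
})

test_that("index agrees with the naive matcher on random queries of a 10 kb genome", {
  genome <- c(c1 = withr::with_seed(14L, sagetag:::random_dna(6000L, 0.4)),
              c2 = withr::with_seed(15L, sagetag:::random_dna(4000L, 0.6)))
  idx <- build_index(genome, c(15L, 16L))
  queries <- withr::with_seed(16L, c(
    # genuine substrings, some reverse-complemented
    substring(genome[["c1"]], s <- sample(5000L, 5L), s + 14L),
    sagetag:::revcomp(substring(genome[["c2"]], s2 <- sample(3000L, 5L), s2 + 15L)),
    # and near-certainly absent random tags
    replicate(3, paste(sample(c("A", "C", "G", "T"), 16L, replace = TRUE),
                       collapse = ""))))
  got <- query_index(idx, queries)
  want <- do.call(rbind, lapply(unique(queries), naive_scan, genome_chr = genome))
  rownames(got) <- rownames(want) <- NULL
  got <- got[order(got$tag, got$chrom, got$pos, got$strand), ]
  want <- want[order(want$tag, want$chrom, want$pos, want$strand), ]
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$pos, want$pos)
  expect_equal(got$strand, want$strand)
})

test_that("mapping the reverse complement flips strands but keeps loci", {
  genome <- c(chrA = withr::with_seed(17L, sagetag:::random_dna(2000L, 0.5)))
  idx <- build_index(genome, 15L)
  tags <- substring(genome[["chrA"]], c(10L, 500L, 1200L), c(24L, 514L, 1214L))
  for (tg in tags) {
    fwd <- query_index(idx, tg)
    rev <- query_index(idx, sagetag:::revcomp(tg))
    # a + hit at p corresponds to a - hit whose 5' end is p + L - 1
    L <- nchar(tg)
    fwd_plus <- fwd[fwd$strand == "+", ]
    rev_minus <- rev[rev$strand == "-", ]
    expect_setequal(rev_minus$pos, fwd_plus$pos + L - 1L)
    expect_setequal(rev[rev$strand == "+", "pos"],
                    fwd[fwd$strand == "-", "pos"] - L + 1L)
  }
})

test_that("multiplicity classes follow hit counts and bar repeats from downstream", {
  # construct a chromosome carrying one 20-mer exactly three times
  seg <- withr::with_seed(18L, sagetag:::random_dna(20L, 0.5))
  spacer <- function() withr::with_seed(sample.int(1e6, 1L),
                                        sagetag:::random_dna(200L, 0.5))
  withr::with_seed(19L, {
    genome <- c(chr1 = paste0(sagetag:::random_dna(200L, 0.5), seg,
                              sagetag:::random_dna(200L, 0.5), seg,
                              sagetag:::random_dna(200L, 0.5), seg,
                              sagetag:::random_dna(200L, 0.5)))
    unique_tag <- substr(genome[["chr1"]], 50L, 69L)
    absent <- "ACGTACGTACGTACGTACGT"
  })
  idx <- build_index(genome, 20L)
  table <- structure(list(
    stage = "Myc",
    entries = data.frame(tag = c(seg, unique_tag, absent),
                         count = c(6L, 3L, 2L)),
    total_valid_tags = 11L, n_singletons_dropped = 0L),
    class = "tag_count_table")
  mp <- map_tags(table, idx)
  cls <- setNames(as.character(mp$tag_classes$class), mp$tag_classes$tag)
  expect_identical(unname(cls[seg]), "multi_2_4")
  expect_identical(unname(cls[unique_tag]), "unique")
  expect_identical(unname(cls[absent]), "unmapped")
  expect_false(seg %in% mp$unique_hits$tag)
  # occurrence-weighted partition equals the library total
  expect_equal(sum(mp$summary$tag_occurrences), mp$total_valid_tags)
  expect_equal(sum(mp$summary$percent), 100)
})

test_that("simulated unique tags map back to their recorded origins", {
  fx <- errorfree_sim()
  for (s in names(fx$maps)) {
    mp <- fx$maps[[s]]
    expect_equal(sum(mp$summary$tag_occurrences), mp$total_valid_tags)
    truth <- fx$sim$truth[fx$sim$truth$stage == s, ]
    uh <- mp$unique_hits
    # every uniquely mapped tag's hit coincides with a recorded origin
    key_truth <- unique(paste(truth$tag, truth$tss, truth$strand))
    expect_true(all(paste(uh$tag, uh$pos, uh$strand) %in% key_truth))
  }
})

test_that("short chromosomes are skipped without failing the build", {
  genome <- c(tiny = "ACGT", big = withr::with_seed(20L,
                                                   sagetag:::random_dna(100L, 0.5)))
  expect_message(idx <- build_index(genome, 15L), "shorter")
  hits <- query_index(idx, substring(genome[["big"]], 1L, 15L))
  expect_true(all(hits$chrom == "big"))
})
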
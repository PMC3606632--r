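# Shared fixtures, built in code. The heavyweight error-free simulation is
# memoised so several test files can reuse it.

# Compact layout for hand-constructed reads: short adapters keep examples
# readable while exercising the same extraction logic.
toy_layout <- function() {
  ditag_layout(adapter_5 = "ACGTACCA", linker = "TTGGCCAATTGG",
               adapter_3 = "TCCGGATA", tag_length_range = c(4L, 6L),
               ditag_total_length = 38L)
}

# A ditag read following a layout, with constant quality.
make_read <- function(tag1, tag2, layout, read_id = "r1", q = 40L) {
  seq <- paste0(layout$adapter_5, tag1, layout$linker,
                sagetag:::revcomp(tag2), layout$adapter_3)
  data.frame(read_id = read_id, sequence = seq,
             qualities = sagetag:::encode_phred(rep(q, nchar(seq))),
             stringsAsFactors = FALSE)
}

# Minimal gene-model table (gene ids only matter for truth simulation).
fake_models <- function(n) {
  data.frame(gene_id = sprintf("G%04d", seq_len(n)), stringsAsFactors = FALSE)
}

# Two hand-placed genes on one 5 kb chromosome, used by the annotation
# tests: a plus-strand gene at 1000-1999 and a minus-strand gene at
# 3000-3999 (coding_start 3999 in transcript orientation).
two_gene_models <- function() {
  data.frame(
    gene_id = c("GA", "GB"), chrom = "chr1", strand = c("+", "-"),
    gene_left = c(1000L, 3000L), gene_right = c(1999L, 3999L),
    coding_start = c(1000L, 3999L), coding_end = c(1999L, 3000L),
    stringsAsFactors = FALSE)
}

two_gene_chrom_len <- c(chr1 = 5000L)

# Error-free end-to-end simulation shared across test files.
.sim_cache <- new.env(parent = emptyenv())
errorfree_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  spec <- genome_spec(n_chromosomes = 2L, chromosome_length = 35000L,
                      n_genes = 18L, duplicated_region_fraction = 0,
                      seed = 401L)
  gen <- generate_genome(spec)
  truths <- simulate_truth(gen$models, deg_fraction = 1/3,
                           fold_range = c(3, 8), seed = 402L)
  layout <- ditag_layout()
  sim <- simulate_reads(gen$genome, gen$models, truths, layout,
                        n_reads_per_stage = c(1200L, 1800L),
                        error_rate = 0, seed = 403L,
                        degraded_read_fraction = 0)
  libs <- lapply(stats::setNames(names(sim$reads), names(sim$reads)),
    function(s) process_library(sim$reads[[s]], layout, s,
                                drop_singletons = FALSE))
  index <- build_index(gen$genome, 15:20)
  maps <- lapply(libs, function(l) map_tags(l$table, index))
  lens <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  anns <- lapply(maps, function(m) {
    annotate_library(m$unique_hits, gen$models, lens)
  })
  .sim_cache$sim <- list(gen = gen, truths = truths, layout = layout,
                         sim = sim, libs = libs, index = index,
                         maps = maps, anns = anns, chrom_len = lens)
  .sim_cache$sim
}

# Independent brute-force oracles -----------------------------------------

# Naive full-scan exact matcher: every position on both strands, reporting
# the 5'-end coordinate in transcript orientation.
naive_scan <- function(genome_chr, tag) {
  hits <- NULL
  L <- nchar(tag)
  rc <- sagetag:::revcomp(tag)  # sub == rc(tag)  <=>  rc(sub) == tag
  for (ch in names(genome_chr)) {
    s <- genome_chr[[ch]]
    n <- nchar(s) - L + 1L
    if (n < 1L) next
    subs <- substring(s, seq_len(n), seq_len(n) + L - 1L)
    fwd <- which(subs == tag)
    rev <- which(subs == rc)
    if (length(fwd)) {
      hits <- rbind(hits, data.frame(tag = tag, chrom = ch, pos = fwd,
                                     strand = "+"))
    }
    if (length(rev)) {
      hits <- rbind(hits, data.frame(tag = tag, chrom = ch,
                                     pos = rev + L - 1L, strand = "-"))
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(tag = character(0), chrom = character(0),
                       pos = integer(0), strand = character(0))
  }
  hits[order(hits$tag, hits$chrom, hits$pos, hits$strand), , drop = FALSE]
}

# Exhaustive two-sided Fisher probability by direct enumeration with
# binomial coefficients (minimum-likelihood tie rule).
enum_fisher <- function(a, b, c, d, tie_tol = 1e-7) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  x <- max(0, k - n):min(k, m)
  probs <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
  p0 <- probs[x == a]
  min(1, sum(probs[probs <= p0 * (1 + tie_tol)]))
}

# One-sided (over-representation) hypergeometric tail by enumeration.
enum_enrich <- function(k_deg, n_deg, k_all, n_all) {
  x <- k_deg:min(k_all, n_deg)
  sum(choose(k_all, x) * choose(n_all - k_all, n_deg - x) /
        choose(n_all, n_deg))
}
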
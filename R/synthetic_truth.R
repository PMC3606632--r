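#' Simulate per-gene expression ground truth for two stages
#'
#' Assigns every gene an expected tag share in each of the two libraries
#' (vegetative mycelium, "Myc", and stage 1 primordium, "S1-Pri"), a TSS
#' profile concentrated within 500 bp upstream of the start codon with one
#' or two preferred sites, and an antisense fraction. A designated subset
#' of genes is differentially expressed with known fold changes.
#'
#' Baseline abundances are log-normal (digital tag libraries are strongly
#' skewed). Differentially expressed genes are constructed in pairs -- one
#' up in each stage, sharing a baseline weight and a fold -- so the two
#' stages' expected shares each sum to exactly 1 while non-DEG genes keep
#' exactly equal shares and every DEG's realised log2 fold equals its drawn
#' fold. An odd DEG is balanced by skewing the baseline split inside one
#' pair (ratios are preserved).
#'
#' @param models gene-model data.frame from [generate_genome()].
#' @param deg_fraction fraction of genes that are differentially expressed;
#'   `round(deg_fraction * n)` genes are flagged.
#' @param fold_range linear fold-change range `(low, high)`; `low` must be
#'   at least `2^deg_lfc_threshold`.
#' @param seed integer seed.
#' @param antisense_fraction probability that an emitted tag for a gene is
#'   antisense (drawn from the gene body on the opposite strand). The two
#'   libraries in the study carried ~14-17% antisense tags.
#' @param deg_lfc_threshold |log2 fold| at or above which a gene counts as
#'   differentially expressed.
#' @param base_sdlog log-sd of the log-normal baseline abundances.
#' @return data.frame with one row per gene: `gene_id`, `abundance_myc`,
#'   `abundance_pri` (shares summing to 1 per stage), `is_deg`,
#'   `true_log2_fold` (Myc over S1-Pri), `antisense_fraction`, and a
#'   `tss_profile` list-column of data.frames `(offset, weight)` with
#'   offsets in bases upstream of the start codon (1..500).
#' @export
simulate_truth <- function(models, deg_fraction = 1/3, fold_range = c(3, 8),
                           seed = 1L, antisense_fraction = 0.15,
                           deg_lfc_threshold = log2(3), base_sdlog = 1.2) {
  if (deg_fraction < 0 || deg_fraction > 1) {
    stopf("deg_fraction must lie in [0, 1]")
  }
  if (fold_range[1] > fold_range[2] ||
      fold_range[1] < 2^deg_lfc_threshold) {
    stopf("fold_range low must be >= 2^deg_lfc_threshold and <= fold_range high")
  }
  if (antisense_fraction < 0 || antisense_fraction > 1) {
    stopf("antisense_fraction must lie in [0, 1]")
  }
  n <- nrow(models)
  if (n == 0L) {
    return(data.frame(gene_id = character(0), abundance_myc = numeric(0),
                      abundance_pri = numeric(0), is_deg = logical(0),
                      true_log2_fold = numeric(0),
                      antisense_fraction = numeric(0)))
  }
  withr::with_seed(seed, {
    base <- stats::rlnorm(n, meanlog = 0, sdlog = base_sdlog)
    n_deg <- round(deg_fraction * n)
    if (n_deg == 1L) {
      stopf("deg_fraction yields a single DEG, which cannot be depth-balanced; use 0 or >= 2")
    }
    deg_idx <- if (n_deg > 0L) sample.int(n, n_deg) else integer(0)

    w_myc <- base
    w_pri <- base
    tlf <- numeric(n)
    if (n_deg > 0L) {
      ord <- sample(deg_idx)
      n_pairs <- n_deg %/% 2L
      leftover <- if (n_deg %% 2L == 1L) ord[n_deg] else NA_integer_
      pair_up <- ord[seq_len(n_pairs) * 2L - 1L]
      pair_dn <- ord[seq_len(n_pairs) * 2L]
      # Shared baseline per pair (geometric mean of the members' draws)
      # and a shared fold: the pair's contribution to each stage's total
      # is b * (sqrt(f) + 1/sqrt(f)) in both stages.
      b_pair <- sqrt(base[pair_up] * base[pair_dn])
      f_pair <- stats::runif(n_pairs, fold_range[1], fold_range[2])
      b_up <- b_pair
      b_dn <- b_pair

      if (!is.na(leftover)) {
        f_l <- stats::runif(1L, fold_range[1], fold_range[2])
        up_l <- sample(c(TRUE, FALSE), 1L)
        b_l <- base[leftover]
        delta <- b_l * (sqrt(f_l) - 1 / sqrt(f_l)) * if (up_l) 1 else -1
        # Compensate the imbalance inside the first pair by shifting
        # baseline mass from the up member to the down member (or back);
        # each member's Myc/Pri ratio is untouched.
        g <- f_pair[1L]
        shift <- delta / (sqrt(g) - 1 / sqrt(g))
        if (shift >= 0) b_dn[1L] <- b_dn[1L] + shift
        else b_up[1L] <- b_up[1L] - shift
        w_myc[leftover] <- b_l * if (up_l) sqrt(f_l) else 1 / sqrt(f_l)
        w_pri[leftover] <- b_l * if (up_l) 1 / sqrt(f_l) else sqrt(f_l)
        tlf[leftover] <- if (up_l) log2(f_l) else -log2(f_l)
      }
      w_myc[pair_up] <- b_up * sqrt(f_pair)
      w_pri[pair_up] <- b_up / sqrt(f_pair)
      w_myc[pair_dn] <- b_dn / sqrt(f_pair)
      w_pri[pair_dn] <- b_dn * sqrt(f_pair)
      tlf[pair_up] <- log2(f_pair)
      tlf[pair_dn] <- -log2(f_pair)
    }
    stopifnot(abs(sum(w_myc) - sum(w_pri)) < 1e-8 * sum(w_myc))
    z <- sum(w_myc)

    profiles <- lapply(seq_len(n), function(i) {
      n_sites <- sample(1:2, 1L)
      if (n_sites == 1L) {
        data.frame(offset = sample(20:200, 1L), weight = 1)
      } else {
        offs <- c(sample(20:200, 1L), sample(201:500, 1L))
        w1 <- stats::runif(1L, 0.55, 0.85)
        data.frame(offset = offs, weight = c(w1, 1 - w1))
      }
    })

    truth <- data.frame(gene_id = models$gene_id,
                        abundance_myc = w_myc / z,
                        abundance_pri = w_pri / z,
                        is_deg = seq_len(n) %in% deg_idx,
                        true_log2_fold = tlf,
                        antisense_fraction = antisense_fraction,
                        stringsAsFactors = FALSE)
    truth$tss_profile <- profiles
    truth
  })
}

#' Draw per-gene tag counts for two libraries of fixed depth
#'
#' Multinomial sampling of 5'-UTR tag counts directly at the count level:
#' each library's depth (its genome-mapped tag total) is distributed over
#' genes according to the stage's expected shares. This is the
#' distributional model implied by tag sampling once mapping and
#' annotation are error-free, and is the right scale for calibration
#' studies (type-I error, power) that need thousands of genes and tens of
#' thousands of tags without simulating individual reads.
#'
#' @param truths truth table from [simulate_truth()].
#' @param depth_myc,depth_pri library depths in tags.
#' @param seed integer seed.
#' @return data.frame: gene_id, count_myc, count_pri, plus the truth
#'   columns is_deg and true_log2_fold.
#' @export
simulate_tag_counts <- function(truths, depth_myc, depth_pri, seed = 1L) {
  stopifnot(depth_myc > 0, depth_pri > 0, nrow(truths) > 0)
  withr::with_seed(seed, {
    cm <- stats::rmultinom(1L, depth_myc, truths$abundance_myc)[, 1L]
    cp <- stats::rmultinom(1L, depth_pri, truths$abundance_pri)[, 1L]
    data.frame(gene_id = truths$gene_id, count_myc = as.integer(cm),
               count_pri = as.integer(cp), is_deg = truths$is_deg,
               true_log2_fold = truths$true_log2_fold,
               stringsAsFactors = FALSE)
  })
}
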
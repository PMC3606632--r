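#' Differential-expression configuration
#'
#' @param alpha unadjusted significance level for the pairwise Fisher
#'   exact test (the study used 0.05 without correction).
#' @param pseudo_tphk value substituted for a zero tags-per-100,000 entry
#'   before forming log2 ratios. The default 1.0 reproduces the published
#'   log2 ratios of zero-count genes (e.g. log2(879.2/1) = 9.78).
#' @param fold_threshold linear fold change above which a DEG counts as
#'   ">n-fold" in the summary (default 3).
#' @param adjust multiple-testing adjustment: `"none"` (default, matching
#'   the study's unadjusted calls) or `"benjamini_hochberg"`.
#' @return list of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, pseudo_tphk = 1.0, fold_threshold = 3,
                      adjust = c("none", "benjamini_hochberg")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (pseudo_tphk <= 0) stopf("pseudo_tphk must be positive")
  structure(list(alpha = alpha, pseudo_tphk = pseudo_tphk,
                 fold_threshold = fold_threshold, adjust = adjust),
            class = "de_config")
}

#' Per-gene tag counts from two classified libraries
#'
#' Sums utr5_sense tag occurrences per gene in each stage; the 5'-UTR
#' window is the expression signal, all other categories are excluded.
#'
#' @param classified_myc,classified_pri classification frames (the
#'   `classified` element of [annotate_library()]) for the two stages.
#' @return data.frame: gene_id, count_myc, count_pri (genes with at least
#'   one utr5_sense tag in either stage).
#' @export
gene_counts <- function(classified_myc, classified_pri) {
  per_stage <- function(cl) {
    u5 <- cl[cl$category == "utr5_sense", , drop = FALSE]
    if (nrow(u5) == 0L) return(stats::setNames(integer(0), character(0)))
    tapply(u5$count, u5$gene_id, sum)
  }
  a <- per_stage(classified_myc)
  b <- per_stage(classified_pri)
  genes <- sort(union(names(a), names(b)))
  data.frame(gene_id = genes,
             count_myc = as.integer(ifelse(genes %in% names(a), a[genes], 0L)),
             count_pri = as.integer(ifelse(genes %in% names(b), b[genes], 0L)),
             stringsAsFactors = FALSE)
}

#' Normalise tag counts to tags per 100,000
#'
#' Expression of a gene is the occurrence sum of all tags in its putative
#' 5'-UTR divided by the library's genome-mapped tag total, times 100,000.
#' The denominator is the uniquely genome-mapped occurrence total of the
#' stage. Genes with zero counts in both stages are excluded from the
#' assessed-gene list.
#'
#' @param counts data.frame from [gene_counts()].
#' @param total_myc,total_pri library denominators (uniquely genome-mapped
#'   tag occurrences per stage); must be positive.
#' @return data.frame: gene_id, count_myc, count_pri, tphk_myc, tphk_pri.
#' @export
quantify <- function(counts, total_myc, total_pri) {
  if (total_myc <= 0 || total_pri <= 0) {
    stopf("library totals must be positive (got %s, %s)", total_myc, total_pri)
  }
  out <- counts[counts$count_myc + counts$count_pri > 0L, , drop = FALSE]
  out$tphk_myc <- out$count_myc / total_myc * 1e5
  out$tphk_pri <- out$count_pri / total_pri * 1e5
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact probability of a 2x2 table
#'
#' Probability, under fixed margins, of observing a table at most as
#' likely as `(a, b; c, d)`: the sum of hypergeometric point
#' probabilities not exceeding the observed one (minimum-likelihood rule,
#' with a relative tolerance of 1e-7 for ties). Degenerate tables with a
#' zero margin have probability 1.
#'
#' @param a,b,c,d non-negative integer cell counts; rows are the two
#'   stages, columns tag successes/failures.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(5, 95, 5, 95)   # identical proportions: 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("cell counts must be non-negative")
  m <- a + b   # row 1
  n <- c + d   # row 2
  k <- a + c   # column 1
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Log2 expression ratio with zero replacement
#'
#' Forms `log2(myc / pri)` on tags-per-100,000 values after replacing any
#' zero by `pseudo_tphk`, the convention that reproduces the published
#' ratios of genes silent in one stage.
#'
#' @param tphk_myc,tphk_pri non-negative expression values (vectorised).
#' @param pseudo_tphk zero-replacement value.
#' @return numeric vector of log2 ratios (Myc over S1-Pri).
#' @examples
#' log2_ratio(879.2, 0)    # 9.78
#' log2_ratio(0, 620.5)    # -9.28
#' @export
log2_ratio <- function(tphk_myc, tphk_pri, pseudo_tphk = 1.0) {
  if (any(tphk_myc < 0) || any(tphk_pri < 0)) stopf("tphk values must be >= 0")
  if (pseudo_tphk <= 0) stopf("pseudo_tphk must be positive")
  x <- ifelse(tphk_myc == 0, pseudo_tphk, tphk_myc)
  y <- ifelse(tphk_pri == 0, pseudo_tphk, tphk_pri)
  log2(x / y)
}

#' Call differentially expressed genes between two stages
#'
#' For every assessed gene, tests the 2x2 table (gene tags vs all other
#' genome-mapped tags, per stage) with the two-sided Fisher exact test and
#' flags genes below `alpha` as differentially expressed, with a direction
#' given by the stage proportions and a log2 ratio under the
#' zero-replacement convention.
#'
#' @param expr data.frame from [quantify()].
#' @param total_myc,total_pri library denominators (as in [quantify()]).
#' @param config a [de_config()].
#' @return list of class `de_result`: `genes` (per-gene frame with
#'   p_value, adjusted p where requested, log2_ratio, is_deg,
#'   deg_direction, fold_flag) and `summary` (per-stage assessed and DEG
#'   counts in the layout of the study's DEG statistics table).
#' @export
call_degs <- function(expr, total_myc, total_pri, config = de_config()) {
  stopifnot(inherits(config, "de_config"))
  g <- expr
  g$p_value <- mapply(function(cm, cp) {
    fisher_exact_2x2(cm, total_myc - cm, cp, total_pri - cp)
  }, g$count_myc, g$count_pri)
  p_eff <- g$p_value
  if (config$adjust == "benjamini_hochberg") {
    g$p_adjusted <- stats::p.adjust(g$p_value, method = "BH")
    p_eff <- g$p_adjusted
  }
  g$log2_ratio <- log2_ratio(g$tphk_myc, g$tphk_pri, config$pseudo_tphk)
  g$is_deg <- p_eff < config$alpha
  prop_diff <- g$count_myc / total_myc - g$count_pri / total_pri
  g$deg_direction <- ifelse(!g$is_deg, "none",
                            ifelse(prop_diff > 0, "myc_up", "pri_up"))
  g$fold_flag <- g$is_deg & (2^abs(g$log2_ratio) > config$fold_threshold)

  per_stage <- function(detected, up) {
    n_det <- sum(detected)
    n_deg <- sum(g$deg_direction == up)
    n_fold <- sum(g$fold_flag & g$deg_direction == up)
    data.frame(n_detected = n_det, n_deg = n_deg,
               pct_deg = if (n_det > 0) 100 * n_deg / n_det else 0,
               n_deg_over_fold = n_fold,
               pct_deg_over_fold = if (n_deg > 0) 100 * n_fold / n_deg else 0)
  }
  summary <- rbind(cbind(stage = "Myc", per_stage(g$count_myc > 0, "myc_up")),
                   cbind(stage = "S1-Pri", per_stage(g$count_pri > 0, "pri_up")))
  structure(list(genes = g, summary = summary,
                 n_assessed = nrow(g), config = config),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("differential expression: %d assessed genes\n", x$n_assessed))
  print(x$summary)
  invisible(x)
}
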
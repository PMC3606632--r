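#' Read a cross-platform expression panel
#'
#' @param path TSV with columns gene_id, log2_ratio_sage,
#'   log2_ratio_microarray, log2_ratio_qpcr (cells may be empty / NA).
#' @return data.frame with unique gene ids.
#' @export
read_platform_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_ratio_sage", "log2_ratio_microarray",
            "log2_ratio_qpcr")
  if (!all(need %in% names(df))) {
    stopf("platform table must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stopf("gene ids in the panel must be unique")
  df
}

#' The packaged 18-gene cross-platform validation panel
#'
#' Log2 ratios (Myc over S1-Pri) of 18 genes measured by 5'-SAGE,
#' oligonucleotide microarray and real-time RT-PCR, shipped as a fixture
#' so validation runs offline.
#'
#' @return the panel data.frame (see [read_platform_table()]).
#' @export
validation_panel <- function() {
  read_platform_table(system.file("extdata", "platform_panel_18genes.tsv",
                                  package = "sagetag", mustWork = TRUE))
}

#' Pearson correlation with complete-case handling
#'
#' @param x,y equal-length numeric vectors; pairs with any missing value
#'   are dropped, and at least 3 complete pairs with nonzero variance are
#'   required.
#' @return the product-moment correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs (have %d)", length(x))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stopf("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Cross-platform agreement report
#'
#' All three pairwise Pearson correlations over a platform panel, with
#' the complete-case n used for each pair; a pair with fewer than 3
#' complete observations is flagged unavailable.
#'
#' @param table platform panel data.frame (see [read_platform_table()]).
#' @return list of class `validation_report`: `correlations` (pair, n, r,
#'   available) and `data` (the panel).
#' @export
validate_report <- function(table) {
  cols <- c(sage = "log2_ratio_sage", microarray = "log2_ratio_microarray",
            qpcr = "log2_ratio_qpcr")
  pairs <- list(c("sage", "qpcr"), c("sage", "microarray"),
                c("microarray", "qpcr"))
  rows <- lapply(pairs, function(p) {
    x <- table[[cols[[p[1]]]]]
    y <- table[[cols[[p[2]]]]]
    n <- sum(stats::complete.cases(x, y))
    if (n >= 3L) {
      data.frame(pair = paste(p, collapse = "_vs_"), n = n,
                 r = pearson_correlation(x, y), available = TRUE)
    } else {
      data.frame(pair = paste(p, collapse = "_vs_"), n = n,
                 r = NA_real_, available = FALSE)
    }
  })
  structure(list(correlations = do.call(rbind, rows), data = table),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("cross-platform agreement (Pearson, complete-case):\n")
  print(x$correlations)
  invisible(x)
}
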
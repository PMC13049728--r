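#' Filter differentially expressed genes
#'
#' Keeps genes with adjusted p-value at or below `padj_max` and absolute
#' fold change strictly above `fc_min` (fold change = 2^|log2fc|, applied
#' symmetrically to both tails). The defaults are the thresholds used for
#' the transcriptome contrasts: padj <= 0.105 and FC > 1.5 - the
#' unusual-looking 0.105 cutoff is deliberate and kept verbatim as the
#' default.
#'
#' @param table Data frame with a `gene_id` column plus the named
#'   log2-fold-change and adjusted-p columns. Rows with a `measure` column
#'   are restricted to `measure == "rna"`.
#' @param padj_max Adjusted p-value ceiling, default 0.105.
#' @param fc_min Fold-change threshold (exclusive), default 1.5.
#' @param log2fc_col,padj_col Column names, defaults `"log2fc"`, `"padj"`.
#' @return Character vector of surviving `gene_id`s.
#' @export
filter_degs <- function(table, padj_max = 0.105, fc_min = 1.5,
                        log2fc_col = "log2fc", padj_col = "padj") {
  need <- c("gene_id", log2fc_col, padj_col)
  if (!all(need %in% names(table)))
    stop("table lacks required columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if ("measure" %in% names(table)) table <- table[table$measure == "rna", ]
  if (nrow(table) == 0L) return(character())
  fc <- 2^abs(table[[log2fc_col]])
  keep <- !is.na(table[[padj_col]]) & table[[padj_col]] <= padj_max &
    is.finite(fc) & fc > fc_min
  table$gene_id[keep]
}

#' Filter differentially expressed proteins
#'
#' Keeps proteins with per-row t-test p-value below `alpha` and absolute
#' fold change at or above `fc_min` (default the 1.2-fold proteome
#' threshold). The t-test is performed upstream on replicate intensities
#' (see [protein_ttest()]) or supplied directly.
#'
#' @param table Data frame with `gene_id`, a log2-fold-change column and a
#'   raw p-value column. Rows with a `measure` column are restricted to
#'   `measure == "protein"`.
#' @param fc_min Fold-change threshold (inclusive), default 1.2.
#' @param alpha Significance level on the raw t-test p, default 0.05.
#' @param log2fc_col,p_col Column names, defaults `"log2fc"`, `"p"`.
#' @return Character vector of surviving `gene_id`s.
#' @export
filter_deps <- function(table, fc_min = 1.2, alpha = 0.05,
                        log2fc_col = "log2fc", p_col = "p") {
  need <- c("gene_id", log2fc_col, p_col)
  if (!all(need %in% names(table)))
    stop("table lacks required columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if ("measure" %in% names(table))
    table <- table[table$measure == "protein", ]
  if (nrow(table) == 0L) return(character())
  fc <- 2^abs(table[[log2fc_col]])
  keep <- !is.na(table[[p_col]]) & table[[p_col]] < alpha &
    is.finite(fc) & fc >= fc_min
  table$gene_id[keep]
}

#' Read or write a gene/protein table as CSV
#'
#' Plain CSV with a mandatory `gene_id` column; remaining columns
#' (log2 fold changes, p-values, `measure`) pass through unchanged.
#'
#' @param path CSV file.
#' @return A data frame suitable for the filter and ranking functions.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab))
    stop("gene table must have a 'gene_id' column: ", path)
  tab
}

#' @param table Data frame with a `gene_id` column.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(table, path) {
  stopifnot("gene_id" %in% names(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a target list (one identifier per line)
#'
#' @param path Text file, one gene identifier per line; blank lines and
#'   `#` comments are skipped.
#' @return Character vector of identifiers.
#' @export
read_target_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Per-protein t-tests on replicate log2 intensities
#'
#' Row-wise Welch t-test between two replicate matrices of log2
#' label-free-quantification intensities, yielding the inputs
#' [filter_deps()] expects.
#'
#' @param ids Protein identifiers (one per row).
#' @param a,b Numeric matrices, rows = proteins, columns = replicates.
#' @return Data frame with `gene_id`, `log2fc` (mean of `b` minus mean of
#'   `a`), `p`, `measure = "protein"`.
#' @export
protein_ttest <- function(ids, a, b) {
  stopifnot(nrow(a) == nrow(b), length(ids) == nrow(a))
  p <- vapply(seq_len(nrow(a)), function(i)
    t.test(b[i, ], a[i, ])$p.value, numeric(1))
  data.frame(gene_id = ids, log2fc = rowMeans(b) - rowMeans(a), p = p,
             measure = "protein", stringsAsFactors = FALSE)
}

#' Exact hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two gene sets drawn from a common universe: with k = |A intersect B|,
#' P(X >= k) for X hypergeometric with |A| marked elements among
#' |universe|, drawing |B|. Computed by exact summation of the point
#' probabilities - no normal approximation. Symmetric in the two sets.
#'
#' @param set_a,set_b Character vectors; must be subsets of `universe`.
#' @param universe Character vector of all eligible identifiers. Supplied
#'   explicitly by design: the tested universe (e.g. all genes measured)
#'   changes the p-value and silently defaulting it would hide that choice.
#' @return An object of class `overlap_result`: `universe_size`,
#'   `set_a_size`, `set_b_size`, `overlap_size`, `p_value`, `overlap_ids`.
#' @examples
#' u <- letters[1:10]
#' hypergeometric_overlap(u[1:5], u[2:5], u)  # overlap 4, p = 5/210
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe)) stop("set_a is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of the universe")
  U <- length(universe); A <- length(set_a); B <- length(set_b)
  ov <- intersect(set_a, set_b)
  k <- length(ov)
  kmax <- min(A, B)
  p <- if (k == 0L) 1 else sum(dhyper(k:kmax, A, U - A, B))
  p <- min(p, 1)
  structure(list(universe_size = U, set_a_size = A, set_b_size = B,
                 overlap_size = k, p_value = p, overlap_ids = sort(ov)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Set overlap: |universe| = %d, |A| = %d, |B| = %d, overlap = %d\n",
              x$universe_size, x$set_a_size, x$set_b_size, x$overlap_size))
  cat(sprintf("  hypergeometric P(X >= %d) = %.4g\n", x$overlap_size,
              x$p_value))
  invisible(x)
}

#' Rank genes by mean fold change across two contrasts
#'
#' Scores each gene in `gene_subset` by the mean of its log2 fold changes
#' in the two contrasts and returns the top-k up-regulated (largest score)
#' and down-regulated (smallest score) genes, with ties broken
#' lexicographically by `gene_id` so the ranking is deterministic.
#'
#' @param table Data frame with `gene_id` and the two log2fc columns.
#' @param gene_subset Genes to rank; every member must carry both
#'   contrasts.
#' @param k Number of genes per direction, default 25. When fewer genes
#'   are available all are returned and the result is flagged `truncated`.
#' @param log2fc_cols The two contrast columns, default
#'   `c("log2fc_mac", "log2fc_bac")`.
#' @return List with data frames `up` and `down` (`gene_id`, the two
#'   log2fc values, `score`), and `truncated`.
#' @export
rank_top_migration <- function(table, gene_subset, k = 25,
                               log2fc_cols = c("log2fc_mac", "log2fc_bac")) {
  need <- c("gene_id", log2fc_cols)
  if (!all(need %in% names(table)))
    stop("table lacks required columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  tab <- table[table$gene_id %in% gene_subset,
               c("gene_id", log2fc_cols), drop = FALSE]
  miss <- setdiff(gene_subset, tab$gene_id)
  if (length(miss))
    stop("genes absent from the table: ", paste(head(miss, 3), collapse = ", "))
  if (anyNA(tab[log2fc_cols]))
    stop("both contrasts must be present for every gene in the subset")
  tab$score <- rowMeans(tab[log2fc_cols])
  truncated <- k > nrow(tab)
  kk <- min(k, nrow(tab))
  up <- tab[order(-tab$score, tab$gene_id), ][seq_len(kk), ]
  down <- tab[order(tab$score, tab$gene_id), ][seq_len(kk), ]
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down, truncated = truncated)
}
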
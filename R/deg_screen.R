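check_counts <- function(counts) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_contract("'counts' must be a numeric genes x cells matrix")
  if (any(counts < 0)) stop_contract("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%05d", seq_len(ncol(counts)))
  counts
}

check_cell_meta <- function(meta, cell_ids = NULL) {
  need <- c("cell_id", "condition", "cell_type")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop_contract("cell metadata must have columns: %s",
                  paste(need, collapse = ", "))
  if (anyDuplicated(meta$cell_id))
    stop_contract("cell ids in metadata must be unique")
  if (!is.null(cell_ids) && !all(cell_ids %in% meta$cell_id))
    stop_contract("%d cells in the count matrix lack metadata",
                  sum(!(cell_ids %in% meta$cell_id)))
  meta
}

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to a common total (`target_sum`) and applies
#' `log(1 + x)`.  This is the package's normalization for the rank-based
#' DEG screen: the Wilcoxon statistic depends on normalization only
#' through the per-cell scaling, so total-count scaling is sufficient for
#' it.
#'
#' @param counts genes x cells matrix (base or `Matrix`) of non-negative
#'   counts with no all-zero cells (filter first, e.g. with
#'   [filter_zero_cells()]).
#' @param target_sum per-cell total after scaling.
#' @return A dense genes x cells matrix of log-normalized expression.
#' @examples
#' normalize_counts(matrix(c(10, 30, 5, 15), 2,
#'                         dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' @export
normalize_counts <- function(counts, target_sum = 10000) {
  counts <- check_counts(counts)
  check_number(target_sum, "target_sum", min = 0, strict_min = TRUE)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop_contract("%d all-zero cell(s); remove them before normalizing",
                  sum(totals == 0))
  log1p(sweep(counts, 2L, totals / target_sum, "/"))
}

#' Drop cells with zero total counts
#'
#' @param counts genes x cells count matrix.
#' @param meta optional cell metadata to subset in step.
#' @return `counts` (and `meta`, if given, as a list) restricted to cells
#'   with at least one count.
#' @export
filter_zero_cells <- function(counts, meta = NULL) {
  counts <- check_counts(counts)
  keep <- colSums(counts) > 0
  if (any(!keep))
    message(sprintf("filter_zero_cells: dropping %d all-zero cell(s)",
                    sum(!keep)))
  counts <- counts[, keep, drop = FALSE]
  if (is.null(meta)) return(counts)
  meta <- check_cell_meta(meta)
  list(counts = counts,
       meta = meta[meta$cell_id %in% colnames(counts), , drop = FALSE])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_contract("p-values must all lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-cell-type Wilcoxon differential-expression screen
#'
#' For one cell type and one condition contrast, tests every gene with a
#' two-sided Wilcoxon rank-sum test on log-normalized expression (exact
#' enumeration when both arms have <= 10 cells and no ties; normal
#' approximation with tie correction otherwise), computes the log2 fold
#' change on de-logged group means with a small epsilon guard, adjusts
#' p-values across genes with Benjamini-Hochberg, and flags genes passing
#' `p_adj < 0.05` and `|log2FC| > 0.25`.
#'
#' @param norm genes x cells matrix of log-normalized expression (see
#'   [normalize_counts()]).
#' @param meta cell metadata data frame (`cell_id`, `condition`,
#'   `cell_type`).
#' @param cell_type cell type to screen.
#' @param contrast character vector `c(A, B)`; fold changes are A over B.
#' @param min_cells minimum cells required in each arm.
#' @param p_adj_cutoff,lfc_cutoff significance cut-offs.
#' @param eps epsilon guard in the fold-change ratio.
#' @return A `deg_table` data frame: `gene`, `cell_type`, `contrast_a`,
#'   `contrast_b`, `log2fc`, `p`, `p_adj`, `significant`.
#' @export
wilcoxon_deg <- function(norm, meta, cell_type, contrast,
                         min_cells = 3L, p_adj_cutoff = 0.05,
                         lfc_cutoff = 0.25, eps = 1e-9) {
  if (!is.matrix(norm)) norm <- as.matrix(norm)
  meta <- check_cell_meta(meta, colnames(norm))
  if (length(contrast) != 2L)
    stop_contract("'contrast' must name exactly 2 conditions")
  if (!(cell_type %in% meta$cell_type))
    stop_contract("unknown cell type '%s'; available: %s", cell_type,
                  paste(unique(meta$cell_type), collapse = ", "))
  missing_cond <- setdiff(contrast, meta$condition)
  if (length(missing_cond))
    stop_contract("unknown condition '%s'; available: %s", missing_cond[1],
                  paste(unique(meta$condition), collapse = ", "))
  meta_idx <- meta[match(colnames(norm), meta$cell_id), ]
  a_cols <- which(meta_idx$cell_type == cell_type &
                  meta_idx$condition == contrast[1])
  b_cols <- which(meta_idx$cell_type == cell_type &
                  meta_idx$condition == contrast[2])
  if (length(a_cols) < min_cells || length(b_cols) < min_cells)
    stop_contract("each arm needs >= %d cells of type '%s' (got %d and %d)",
                  min_cells, cell_type, length(a_cols), length(b_cols))
  A <- norm[, a_cols, drop = FALSE]
  B <- norm[, b_cols, drop = FALSE]
  exact <- ncol(A) <= 10L && ncol(B) <= 10L
  p <- vapply(seq_len(nrow(norm)), function(g) {
    a <- A[g, ]; b <- B[g, ]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    suppressWarnings(wilcox.test(a, b, exact = exact)$p.value)
  }, numeric(1))
  mean_a <- rowMeans(expm1(A))
  mean_b <- rowMeans(expm1(B))
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  p_adj <- bh_adjust(p)
  out <- data.frame(
    gene = rownames(norm), cell_type = cell_type,
    contrast_a = contrast[1], contrast_b = contrast[2],
    log2fc = log2fc, p = p, p_adj = p_adj,
    significant = p_adj < p_adj_cutoff & abs(log2fc) > lfc_cutoff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf(
    "<deg_table> %s: %s vs %s — %d genes tested, %d significant (p_adj < 0.05, |log2FC| > 0.25)\n",
    x$cell_type[1], x$contrast_a[1], x$contrast_b[1], nrow(x),
    sum(x$significant)))
  NextMethod()
}

#' Cell-type proportion comparison across conditions
#'
#' For every cell type and every pair of conditions, compares the cell
#' type's share of cells between the two conditions with a two-proportion
#' chi-square test (without continuity correction), then adjusts across
#' all (cell type, pair) tests with Benjamini-Hochberg.
#'
#' @param meta cell metadata data frame (`cell_id`, `condition`,
#'   `cell_type`); every condition must contain cells.
#' @return A data frame with one row per (cell_type, condition pair):
#'   counts, proportions, chi-square statistic, raw and adjusted p.
#' @export
cluster_proportion_test <- function(meta) {
  meta <- check_cell_meta(meta)
  conds <- sort(unique(meta$condition))
  if (length(conds) < 2L)
    stop_contract("need at least 2 conditions, got %d", length(conds))
  n_cond <- table(meta$condition)
  if (any(n_cond == 0)) stop_contract("a condition has zero cells")
  types <- sort(unique(meta$cell_type))
  pairs <- utils::combn(conds, 2L)
  rows <- list()
  for (ct in types) {
    for (k in seq_len(ncol(pairs))) {
      ca <- pairs[1L, k]; cb <- pairs[2L, k]
      na <- n_cond[[ca]]; nb <- n_cond[[cb]]
      xa <- sum(meta$cell_type == ct & meta$condition == ca)
      xb <- sum(meta$cell_type == ct & meta$condition == cb)
      tab <- rbind(c(xa, na - xa), c(xb, nb - xb))
      res <- if (any(colSums(tab) == 0)) {
        list(statistic = c(0), p.value = 1)
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, cond_a = ca, cond_b = cb,
        count_a = xa, n_a = na, prop_a = xa / na,
        count_b = xb, n_b = nb, prop_b = xb / nb,
        statistic = unname(res$statistic), p = res$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Read / write counts as an MTX triplet
#'
#' The on-disk layout is the conventional trio `matrix.mtx` (MatrixMarket
#' sparse genes x cells), `genes.tsv` and `barcodes.tsv`, plus an optional
#' metadata CSV (`barcode, condition, cell_type`).
#'
#' @param counts genes x cells matrix.
#' @param dir directory to write into (created if needed).
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- check_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @return `read_counts_mtx` returns a genes x cells integer matrix with
#'   gene and barcode dimnames.
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_contract("missing file(s): %s", paste(missing, collapse = ", "))
  m <- as.matrix(Matrix::readMM(paths[1]))
  genes <- readLines(paths[2])
  barcodes <- readLines(paths[3])
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop_contract("matrix dimensions (%d x %d) do not match label files",
                  nrow(m), ncol(m))
  dimnames(m) <- list(genes, barcodes)
  storage.mode(m) <- "integer"
  m
}

#' Read / write cell metadata CSV
#'
#' @param meta data frame with `cell_id`, `condition`, `cell_type`.
#' @param path CSV file path.
#' @export
write_cell_meta <- function(meta, path) {
  meta <- check_cell_meta(meta)
  write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_meta
#' @export
read_cell_meta <- function(path) {
  if (!file.exists(path)) stop_contract("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("barcode" %in% names(df) && !("cell_id" %in% names(df)))
    names(df)[names(df) == "barcode"] <- "cell_id"
  check_cell_meta(df)
}

#' Per-condition cell tallies
#'
#' @param meta cell metadata data frame.
#' @return Named integer vector of cells per condition, plus attribute
#'   `"total"`.
#' @export
condition_cell_counts <- function(meta) {
  meta <- check_cell_meta(meta)
  tab <- table(meta$condition)
  out <- setNames(as.integer(tab), names(tab))
  attr(out, "total") <- sum(out)
  out
}
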
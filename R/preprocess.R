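#' Depth-normalize single-cell expression counts
#'
#' Counts-per-`scale` normalization: each cell's counts are divided by the
#' cell total and multiplied by `scale` (default 10,000; set
#' `scale = 1e6` for counts per million).
#'
#' @param raw_counts Cell-by-gene count matrix (dense or sparse).
#' @param scale Target per-cell total (default 10,000).
#' @return Matrix of the same shape and class family with normalized values.
#' @export
normalize_expression <- function(raw_counts, scale = 1e4) {
  totals <- Matrix::rowSums(raw_counts)
  if (any(totals == 0)) {
    bad <- rownames(raw_counts)[which(totals == 0)[1]] %||%
      as.character(which(totals == 0)[1])
    abort(sprintf("cell '%s' has zero total counts; exclude it before normalizing",
                  bad))
  }
  out <- Matrix::Diagonal(x = scale / totals) %*% raw_counts |>
    as_same_kind(raw_counts)
  dimnames(out) <- dimnames(raw_counts)
  out
}

as_same_kind <- function(m, template) {
  if (is.matrix(template)) as.matrix(m) else methods::as(m, "CsparseMatrix")
}

#' Depth-normalize tile accessibility by ReadsInTSS
#'
#' Divides each cell's tile counts by its ReadsInTSS value and rescales by
#' the median ReadsInTSS so magnitudes stay comparable across datasets
#' (the rescaling constant cancels in the subsequent per-tile min-max
#' scaling).
#'
#' @param counts Cell-by-tile count matrix.
#' @param reads_in_tss Positive per-cell vector, aligned to the rows.
#' @return Normalized matrix of the same shape.
#' @export
normalize_accessibility <- function(counts, reads_in_tss) {
  stopifnot(length(reads_in_tss) == nrow(counts))
  if (any(reads_in_tss <= 0)) abort("reads_in_tss must be positive")
  med <- median(reads_in_tss)
  out <- Matrix::Diagonal(x = med / reads_in_tss) %*% counts |>
    as_same_kind(counts)
  dimnames(out) <- dimnames(counts)
  out
}

#' Select highly variable genes by dispersion
#'
#' Ranks genes by dispersion (variance / mean) of log1p-transformed,
#' depth-normalized expression and returns the top `n`. Genes with zero
#' variance are never selected; ties break lexicographically by gene id.
#'
#' @param raw_counts Cell-by-gene count matrix with column names.
#' @param n Number of genes to keep (default 5,000). When fewer than `n`
#'   genes have nonzero variance, all of them are returned.
#' @param scale Depth-normalization target used internally.
#' @return Character vector of selected gene ids, ranked.
#' @export
select_variable_genes <- function(raw_counts, n = 5000L, scale = 1e4) {
  stopifnot(!is.null(colnames(raw_counts)))
  norm <- normalize_expression(raw_counts, scale = scale)
  lg <- log1p(as.matrix(norm))
  mu <- colMeans(lg)
  v <- apply(lg, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # a gene constant in raw counts is never variable, whatever the
  # depth-normalized values do
  v_raw <- apply(as.matrix(raw_counts), 2, var)
  keep <- which(v > 0 & v_raw > 0)
  ord <- keep[order(-disp[keep], colnames(raw_counts)[keep])]
  colnames(raw_counts)[utils::head(ord, n)]
}

#' Filter genes whose expression is too sparse
#'
#' Keeps genes whose fraction of zero-count cells is at most
#' `max_zero_fraction` (default 0.9, i.e. genes expressed in at least 10%
#' of cells survive; the boundary value itself is kept).
#'
#' @param raw_counts Cell-by-gene count matrix with column names.
#' @param genes Optional character vector restricting the genes tested.
#' @param max_zero_fraction Maximum tolerated zero fraction (default 0.9).
#' @return Character vector of retained gene ids.
#' @export
sparsity_filter <- function(raw_counts, genes = colnames(raw_counts),
                            max_zero_fraction = 0.9) {
  m <- raw_counts[, genes, drop = FALSE]
  zero_frac <- 1 - Matrix::colSums(m > 0) / nrow(m)
  genes[zero_frac <= max_zero_fraction]
}

#' Fit a per-tile min-max scaler on training cells
#'
#' @param x_train Training-cell block of the (normalized) tile matrix.
#' @return A `tile_scaler` holding per-tile min and max.
#' @export
fit_scaler <- function(x_train) {
  x_train <- as.matrix(x_train)
  structure(
    list(min = apply(x_train, 2, min),
         max = apply(x_train, 2, max),
         n_train = nrow(x_train)),
    class = "tile_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Applies the affine rule learned on the training cells:
#' `(x - min) / (max - min)`. Tiles that were constant in training map to
#' 0 everywhere; values outside the training range are NOT clipped, so
#' test cells can fall outside `[0, 1]`.
#'
#' @param scaler A `tile_scaler` from [fit_scaler()].
#' @param x Matrix with the same tile columns.
#' @return Dense scaled matrix.
#' @export
apply_scaler <- function(scaler, x) {
  if (!inherits(scaler, "tile_scaler"))
    abort("`scaler` must be fitted with fit_scaler() before applying")
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$min))
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' Split cells into train/test sets with cross-validation folds
#'
#' Uniform random split holding out `test_fraction` of cells, with the
#' remaining training cells partitioned into `k_folds` balanced folds.
#'
#' @param n Number of cells (must be at least 8).
#' @param test_fraction Held-out fraction (default 0.25).
#' @param k_folds Number of cross-validation folds (default 4).
#' @param seed Integer seed; the same seed reproduces the split.
#' @return A `cell_split`: list with `train_idx`, `test_idx`, `folds`
#'   (list of `k_folds` index vectors partitioning `train_idx`), `seed`.
#' @export
split_cells <- function(n, test_fraction = 0.25, k_folds = 4L, seed = 1L) {
  if (n < 8) abort("need at least 8 cells to split")
  stopifnot(test_fraction > 0, test_fraction < 1, k_folds >= 2)
  perm <- withr::with_seed(seed, sample.int(n))
  n_test <- round(n * test_fraction)
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[-seq_len(n_test)])
  fold_of <- withr::with_seed(
    seed + 1L,
    sample(rep_len(seq_len(k_folds), length(train_idx)))
  )
  folds <- lapply(seq_len(k_folds), function(k) train_idx[fold_of == k])
  structure(
    list(train_idx = train_idx, test_idx = test_idx, folds = folds,
         seed = as.integer(seed)),
    class = "cell_split"
  )
}

#' Binomially thin a count matrix
#'
#' Each count is independently thinned `Binomial(count, fraction)`, so the
#' expected per-cell total is `fraction` times the original total and no
#' entry ever exceeds its original value.
#'
#' @param m Count matrix (dense or sparse, non-negative integers).
#' @param fraction Retention fraction in (0, 1].
#' @param seed Integer seed.
#' @return Thinned integer matrix of the same shape and class family.
#' @export
downsample_counts <- function(m, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    abort("`fraction` must be in (0, 1]")
  if (fraction == 1) return(m)
  if (inherits(m, "sparseMatrix")) {
    mm <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    mm@x <- withr::with_seed(
      seed, as.numeric(rbinom(length(mm@x), size = as.integer(mm@x),
                              prob = fraction)))
    Matrix::drop0(mm)
  } else {
    out <- m
    out[] <- withr::with_seed(
      seed, rbinom(length(m), size = as.integer(m), prob = fraction))
    out
  }
}

#' Subsample cells uniformly at random
#'
#' @param cells Cell table (tibble) or integer cell count.
#' @param fraction Fraction of cells to keep, in (0, 1].
#' @param seed Integer seed.
#' @return When `cells` is a table: the subsampled table. When a count:
#'   sorted integer indices of retained cells.
#' @export
downsample_cells <- function(cells, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    abort("`fraction` must be in (0, 1]")
  n <- if (is.data.frame(cells)) nrow(cells) else as.integer(cells)
  keep <- sort(withr::with_seed(seed, sample.int(n, round(n * fraction))))
  if (is.data.frame(cells)) cells[keep, , drop = FALSE] else keep
}
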
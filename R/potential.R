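#' Latent semantic indexing embedding of accessibility counts
#'
#' TF-IDF weighting (term frequency per cell times log inverse document
#' frequency per feature), `log1p` transform, and truncated SVD. The sign
#' of each component is fixed so the loading with the largest magnitude
#' is positive, making the embedding deterministic.
#'
#' @param counts Cell-by-feature non-negative count matrix.
#' @param n_dims Number of dimensions to keep (default 20; reduced with a
#'   warning when it reaches the matrix rank).
#' @return Cell-by-`n_dims` embedding matrix.
#' @export
lsi_embedding <- function(counts, n_dims = 20L) {
  m <- as.matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  depth <- pmax(rowSums(m), 1)
  tf <- m / depth
  idf <- log(1 + nrow(m) / (1 + colSums(m > 0)))
  x <- log1p(sweep(tf, 2, idf, "*") * 1e4)
  max_d <- min(dim(x))
  if (n_dims >= max_d) {
    warn(sprintf("n_dims reduced from %d to %d (matrix rank limit)",
                 n_dims, max_d - 1L))
    n_dims <- max_d - 1L
  }
  s <- svd(x, nu = n_dims, nv = n_dims)
  emb <- s$u %*% diag(s$d[seq_len(n_dims)], n_dims)
  # fix component signs for determinism
  for (j in seq_len(n_dims)) {
    if (emb[which.max(abs(emb[, j])), j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- rownames(counts)
  emb
}

#' Smooth expression over a k-nearest-neighbour graph
#'
#' Replaces each cell's expression by the mean over its `k` nearest
#' neighbours (Euclidean distance in the embedding, the cell itself
#' included, so `k = 1` is the identity).
#'
#' @param expr Cell-by-gene matrix to smooth.
#' @param embedding Cell-by-dimension embedding with the same row order.
#' @param k Neighbourhood size (default 50; clamped to the number of
#'   cells with a warning).
#' @return Smoothed dense matrix of the same shape.
#' @export
knn_smooth <- function(expr, embedding, k = 50L) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) == nrow(embedding))
  n <- nrow(expr)
  if (k > n) {
    warn(sprintf("k = %d clamped to the number of cells (%d)", k, n))
    k <- n
  }
  d <- as.matrix(stats::dist(embedding))
  out <- matrix(0, n, ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[seq_len(k)]
    out[i, ] <- colMeans(expr[nn, , drop = FALSE])
  }
  out
}

#' Keep genes whose predicted expression tracks observation
#'
#' @param pred,obs Matched cell-by-gene matrices (e.g. smoothed predicted
#'   and observed expression).
#' @return Character vector (or integer indices when unnamed) of genes
#'   with strictly positive Spearman correlation between the columns.
#' @export
filter_genes_by_correlation <- function(pred, obs) {
  stopifnot(all(dim(pred) == dim(obs)))
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  rho <- vapply(seq_len(ncol(pred)), function(g) {
    if (sd(pred[, g]) == 0 || sd(obs[, g]) == 0) return(0)
    suppressWarnings(cor(pred[, g], obs[, g], method = "spearman"))
  }, numeric(1))
  keep <- which(rho > 0)
  if (!is.null(colnames(pred))) colnames(pred)[keep] else keep
}

# per-gene min-max scaling over all cells (no train/test split here)
minmax_by_gene <- function(m) {
  m <- as.matrix(m)
  rng <- apply(m, 2, function(v) diff(range(v)))
  lo <- apply(m, 2, min)
  out <- sweep(m, 2, lo, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' Chromatin potential vector field
#'
#' For each "source" cell, finds the `k_target` cells whose (smoothed,
#' per-gene min-max scaled) observed expression vectors correlate best
#' (Pearson) with the source cell's predicted expression vector, and
#' draws an arrow from the source cell's 2D layout position to the mean
#' layout position of those target cells. Self-matches are allowed, so a
#' stationary terminal state yields a near-zero arrow. Cells whose
#' predicted vector is constant get a zero arrow and a degenerate flag.
#'
#' @param pred Cell-by-gene predicted expression (smoothed; scaled
#'   internally per gene unless `scaled = TRUE`).
#' @param obs Cell-by-gene observed expression (same treatment).
#' @param layout Two-column matrix or data frame of 2D positions (FDL or
#'   UMAP), same row order.
#' @param k_target Number of target cells (default 10).
#' @param cell_types Optional per-cell labels carried into the result.
#' @param scaled Whether `pred`/`obs` are already min-max scaled per gene.
#' @return A `potential_field` tibble: one row per cell with `cell`,
#'   `x`, `y`, `dx`, `dy`, `degenerate`, and `cell_type` if given.
#' @export
potential_vectors <- function(pred, obs, layout, k_target = 10L,
                              cell_types = NULL, scaled = FALSE) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  layout <- as.matrix(layout)[, 1:2, drop = FALSE]
  stopifnot(nrow(pred) == nrow(obs), nrow(pred) == nrow(layout))
  if (ncol(pred) < 2)
    abort("chromatin potential needs at least 2 genes (per-cell expression vectors must support a correlation)")
  n <- nrow(pred)
  k_target <- min(k_target, n)
  if (!scaled) {
    pred <- minmax_by_gene(pred)
    obs <- minmax_by_gene(obs)
  }

  pred_sd <- apply(pred, 1, sd)
  obs_sd <- apply(obs, 1, sd)
  degenerate <- pred_sd == 0
  # Pearson correlation between each predicted row and every observed row
  cors <- suppressWarnings(cor(t(pred), t(obs)))
  cors[degenerate, ] <- -Inf
  cors[, obs_sd == 0] <- -Inf

  target_mean <- t(vapply(seq_len(n), function(i) {
    if (degenerate[i]) return(layout[i, ])
    top <- order(cors[i, ], decreasing = TRUE)[seq_len(k_target)]
    colMeans(layout[top, , drop = FALSE])
  }, numeric(2)))

  out <- tibble::tibble(
    cell = rownames(pred) %||% as.character(seq_len(n)),
    x = layout[, 1], y = layout[, 2],
    dx = target_mean[, 1] - layout[, 1],
    dy = target_mean[, 2] - layout[, 2],
    degenerate = degenerate
  )
  if (!is.null(cell_types)) out$cell_type <- cell_types
  structure(out, class = c("potential_field", class(out)),
            k_target = k_target)
}

#' Average a potential field over a 2D grid
#'
#' Partitions the layout bounding box into `grid_size` by `grid_size`
#' cells and averages the member arrows in each; empty grid cells are
#' omitted.
#'
#' @param field A `potential_field`.
#' @param grid_size Number of grid cells per axis (default 30).
#' @return Tibble with one row per occupied grid cell: `grid_x`,
#'   `grid_y` (cell centers), `dx`, `dy` (mean arrow), `n_cells`.
#' @export
grid_smooth <- function(field, grid_size = 30L) {
  stopifnot(grid_size >= 2)
  rx <- range(field$x); ry <- range(field$y)
  if (diff(rx) == 0 || diff(ry) == 0)
    abort("layout bounding box is degenerate")
  bx <- pmin(1L + as.integer((field$x - rx[1]) / diff(rx) * grid_size),
             grid_size)
  by <- pmin(1L + as.integer((field$y - ry[1]) / diff(ry) * grid_size),
             grid_size)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(bx = bx, by = by,
                                   dx = field$dx, dy = field$dy),
                    .data$bx, .data$by),
    dx = mean(.data$dx), dy = mean(.data$dy), n_cells = dplyr::n(),
    .groups = "drop") |>
    dplyr::transmute(
      grid_x = rx[1] + (.data$bx - 0.5) * diff(rx) / grid_size,
      grid_y = ry[1] + (.data$by - 0.5) * diff(ry) / grid_size,
      dx = .data$dx, dy = .data$dy, n_cells = .data$n_cells)
}

#' Compare two vector fields cell by cell
#'
#' Cosine similarity of the per-cell arrows (undefined and flagged when
#' either arrow is zero) and, when cell types are available, the per-type
#' mean difference in arrow magnitude.
#'
#' @param field_a,field_b `potential_field` tibbles over the same cells
#'   (matched by row order).
#' @return List with `cells` (tibble: `cell`, `cosine`, `magnitude_a`,
#'   `magnitude_b`, `undefined`) and `by_cell_type` (tibble of mean
#'   magnitude difference per type, or NULL).
#' @export
cosine_compare <- function(field_a, field_b) {
  stopifnot(nrow(field_a) == nrow(field_b))
  va <- cbind(field_a$dx, field_a$dy)
  vb <- cbind(field_b$dx, field_b$dy)
  na <- sqrt(rowSums(va^2)); nb <- sqrt(rowSums(vb^2))
  undefined <- na == 0 | nb == 0
  cosine <- rowSums(va * vb) / (na * nb)
  cosine[undefined] <- NA_real_
  cells <- tibble::tibble(
    cell = field_a$cell, cosine = cosine,
    magnitude_a = na, magnitude_b = nb, undefined = undefined)
  by_type <- NULL
  if ("cell_type" %in% names(field_a)) {
    cells$cell_type <- field_a$cell_type
    by_type <- dplyr::summarise(
      dplyr::group_by(cells, .data$cell_type),
      mean_cosine = mean(.data$cosine, na.rm = TRUE),
      mean_magnitude_diff = mean(.data$magnitude_a - .data$magnitude_b),
      n = dplyr::n(), .groups = "drop")
  }
  list(cells = cells, by_cell_type = by_type)
}

#' End-to-end chromatin potential from fitted models
#'
#' Smooths predicted and observed expression over the accessibility
#' embedding, drops genes with non-positive predicted/observed
#' correlation, min-max scales per gene, and computes the potential
#' field.
#'
#' @param pred Cell-by-gene predicted expression (unsmoothed).
#' @param obs Cell-by-gene observed expression (unsmoothed).
#' @param embedding Low-dimensional accessibility embedding (e.g. from
#'   [lsi_embedding()]).
#' @param layout 2D layout for the arrows.
#' @param k_smooth kNN smoothing neighbourhood (default 50).
#' @param k_target Target-cell count for the arrows (default 10).
#' @param cell_types Optional per-cell labels.
#' @return A `potential_field` (see [potential_vectors()]); the retained
#'   genes are stored in `attr(, "genes_used")`.
#' @export
chromatin_potential <- function(pred, obs, embedding, layout,
                                k_smooth = 50L, k_target = 10L,
                                cell_types = NULL) {
  pred_s <- knn_smooth(pred, embedding, k = k_smooth)
  obs_s <- knn_smooth(obs, embedding, k = k_smooth)
  keep <- filter_genes_by_correlation(pred_s, obs_s)
  if (length(keep) == 0) abort("no gene with positive predicted/observed correlation")
  field <- potential_vectors(pred_s[, keep, drop = FALSE],
                             obs_s[, keep, drop = FALSE],
                             layout, k_target = k_target,
                             cell_types = cell_types)
  attr(field, "genes_used") <- keep
  field
}
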
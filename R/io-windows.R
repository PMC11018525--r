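#' Construct the tiled genomic window for a gene
#'
#' Lays non-overlapping, fixed-width tiles across a gene's regulatory
#' context: `flank` bases upstream of the gene start, the gene body, and
#' `flank` bases downstream of the gene end. Tiles are anchored at
#' `gene start - flank` (window-relative, not genome-grid-anchored), so the
#' number of tiles depends only on gene length:
#' `n_tiles = 2 * flank / tile_size + ceiling(gene_length / tile_size)`.
#'
#' @param gene A one-row data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open coordinates).
#' @param flank Flanking distance in bp on each side (default 250,000).
#' @param tile_size Tile width in bp (default 500). `flank` must be a
#'   multiple of `tile_size`.
#' @return A `gene_window` object: list with `gene_id`, `chrom`, `strand`,
#'   `gene_start`, `gene_end`, `window_start`, `window_end`, `tile_size`,
#'   `flank`, `n_tiles`.
#' @examples
#' gene <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'                        start = 1e6, end = 1e6 + 11703, strand = "+")
#' make_gene_window(gene)$n_tiles  # 1024
#' @export
make_gene_window <- function(gene, flank = 250000L, tile_size = 500L) {
  stopifnot(is.data.frame(gene), nrow(gene) == 1)
  flank <- as.integer(flank); tile_size <- as.integer(tile_size)
  if (flank <= 0 || tile_size <= 0)
    abort("`flank` and `tile_size` must be positive")
  if (flank %% tile_size != 0)
    abort("`flank` must be divisible by `tile_size`")
  if (gene$end <= gene$start)
    abort(sprintf("gene %s has end <= start", gene$gene_id))
  if (!gene$strand %in% c("+", "-"))
    abort(sprintf("gene %s has invalid strand '%s'", gene$gene_id, gene$strand))

  gene_len <- as.integer(gene$end - gene$start)
  n_flank <- flank %/% tile_size
  n_body <- as.integer(ceiling(gene_len / tile_size))
  structure(
    list(
      gene_id = gene$gene_id,
      chrom = gene$chrom,
      strand = gene$strand,
      gene_start = as.integer(gene$start),
      gene_end = as.integer(gene$end),
      window_start = as.integer(gene$start) - flank,
      window_end = as.integer(gene$start) - flank +
        as.integer(2L * n_flank + n_body) * tile_size,
      tile_size = tile_size,
      flank = flank,
      n_flank_tiles = n_flank,
      n_body_tiles = n_body,
      n_tiles = as.integer(2L * n_flank + n_body)
    ),
    class = "gene_window"
  )
}

#' @export
#' @method print gene_window
print.gene_window <- function(x, ...) {
  cat(sprintf(
    "<gene_window> %s (%s%s) %s:%d-%d | %d tiles of %d bp (flank %d bp)\n",
    x$gene_id, x$chrom, x$strand, x$chrom, x$window_start, x$window_end,
    x$n_tiles, x$tile_size, x$flank))
  invisible(x)
}

#' Tile coordinates of a gene window
#'
#' @param window A `gene_window`.
#' @return A tibble with one row per tile: `tile` (1-based index),
#'   `chrom`, `start`, `end` (0-based half-open genomic coordinates).
#' @export
tile_coords <- function(window) {
  stopifnot(inherits(window, "gene_window"))
  starts <- window$window_start +
    (seq_len(window$n_tiles) - 1L) * window$tile_size
  tibble::tibble(
    tile = seq_len(window$n_tiles),
    chrom = window$chrom,
    start = starts,
    end = starts + window$tile_size
  )
}

#' Build the cell-by-tile insertion count matrix for a gene window
#'
#' Counts Tn5 insertions per cell in each tile of the window. Insertions
#' outside the window are ignored. Tiles overlapping a blacklist interval
#' by at least 1 bp are zeroed.
#'
#' @param insertions Tibble of insertion events with columns `barcode`,
#'   `chrom`, `pos` (as produced by [read_fragments()]).
#' @param window A `gene_window`.
#' @param cells Cell table (tibble with a `barcode` column) fixing the row
#'   order of the matrix.
#' @param blacklist Optional data frame of excluded regions with columns
#'   `chrom`, `start`, `end` (half-open).
#' @return A sparse `dgCMatrix` of dimension `nrow(cells)` by
#'   `window$n_tiles`, with barcodes as row names.
#' @export
build_tile_matrix <- function(insertions, window, cells, blacklist = NULL) {
  stopifnot(inherits(window, "gene_window"))
  barcodes <- cells$barcode
  if (anyDuplicated(barcodes)) abort("cell barcodes must be unique")

  keep <- insertions$chrom == window$chrom &
    insertions$pos >= window$window_start &
    insertions$pos < window$window_end
  ins <- insertions[keep, , drop = FALSE]
  cell_idx <- match(ins$barcode, barcodes)
  ok <- !is.na(cell_idx)
  tile_idx <- ((ins$pos[ok] - window$window_start) %/% window$tile_size) + 1L

  counts <- Matrix::sparseMatrix(
    i = cell_idx[ok], j = tile_idx, x = 1,
    dims = c(length(barcodes), window$n_tiles),
    dimnames = list(barcodes, NULL)
  )

  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    tc <- tile_coords(window)
    bl <- blacklist[blacklist$chrom == window$chrom, , drop = FALSE]
    if (nrow(bl) > 0) {
      bad <- vapply(seq_len(nrow(tc)), function(i) {
        any(tc$start[i] < bl$end & bl$start < tc$end[i])
      }, logical(1))
      if (any(bad)) counts[, bad] <- 0
    }
  }
  methods::as(Matrix::drop0(counts), "CsparseMatrix")
}
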
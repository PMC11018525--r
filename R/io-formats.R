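#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open, strand `+`/`-`). Gene ids must be unique, `end`
#' must exceed `start`.
#'
#' @param path Path to the TSV.
#' @return A tibble of gene annotations.
#' @export
read_gene_annotation <- function(path) {
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character()
  ), progress = FALSE)
  validate_gene_annotation(genes)
}

validate_gene_annotation <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    abort(paste("gene annotation must have columns:",
                paste(need, collapse = ", ")))
  if (anyDuplicated(genes$gene_id))
    abort("gene ids must be unique")
  if (any(genes$end <= genes$start))
    abort("gene annotation has end <= start")
  if (!all(genes$strand %in% c("+", "-")))
    abort("strand must be '+' or '-'")
  tibble::as_tibble(genes)
}

#' Read cell metadata
#'
#' Expects a TSV with columns `barcode` and `cell_type`, optionally
#' `reads_in_tss` (positive) and `include_flag` (logical; defaults TRUE).
#'
#' @param path Path to the TSV.
#' @return A tibble of cell metadata, one row per barcode.
#' @export
read_cell_metadata <- function(path) {
  cells <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("barcode", "cell_type") %in% names(cells)))
    abort("cell metadata must have columns barcode and cell_type")
  if (anyDuplicated(cells$barcode)) abort("barcodes must be unique")
  if (!"include_flag" %in% names(cells)) cells$include_flag <- TRUE
  if ("reads_in_tss" %in% names(cells) &&
      any(cells$reads_in_tss[cells$include_flag] <= 0))
    abort("reads_in_tss must be positive for included cells")
  tibble::as_tibble(cells)
}

#' Read a BED file of intervals
#'
#' Reads the first three columns (`chrom`, `start`, `end`) of a BED file;
#' a fourth column, when present, is kept as `name`.
#'
#' @param path Path to the BED file.
#' @return A tibble of half-open intervals.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         comment = "#", progress = FALSE)
  if (ncol(bed) < 3) abort("BED file must have at least 3 columns")
  out <- tibble::tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]])
  )
  if (ncol(bed) >= 4) out$name <- as.character(bed[[4]])
  out
}

#' Read a cell-by-gene count matrix in Matrix Market format
#'
#' Reads an MTX triplet file with `barcodes.tsv` and `features.tsv`
#' sidecars. The matrix is oriented features-by-barcodes on disk (the
#' common convention) and returned transposed as cells-by-genes.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param barcodes_path,features_path Paths to the sidecar files; default
#'   to `barcodes.tsv` / `features.tsv` next to the matrix.
#' @return A sparse `dgCMatrix`, cells in rows (barcodes as row names),
#'   genes in columns (feature ids as column names).
#' @export
read_mtx_matrix <- function(mtx_path,
                            barcodes_path = file.path(dirname(mtx_path), "barcodes.tsv"),
                            features_path = file.path(dirname(mtx_path), "features.tsv")) {
  m <- Matrix::readMM(mtx_path)
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              col_types = readr::cols(), progress = FALSE)[[1]]
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              col_types = readr::cols(), progress = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    abort("MTX dimensions do not match sidecar files")
  dimnames(m) <- list(features, barcodes)
  methods::as(Matrix::t(m), "CsparseMatrix")
}

#' Write a cell-by-gene matrix as MTX with sidecars
#'
#' @param m Cell-by-gene matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param name Basename for the matrix file (default `matrix.mtx`).
#' @return Invisibly, the matrix path.
#' @export
write_mtx_matrix <- function(m, dir, name = "matrix.mtx") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(m, sparse = TRUE)),
                              "generalMatrix"),
                  file.path(dir, name))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  invisible(file.path(dir, name))
}

#' Save fitted gene models to a keyed on-disk store
#'
#' One file per gene plus an index; [load_model_store()] round-trips all
#' stored arrays bit-exactly.
#'
#' @param models Named list of `gene_model` objects (names = gene ids) or
#'   a single `gene_model`.
#' @param dir Store directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model_store <- function(models, dir) {
  if (inherits(models, "gene_model"))
    models <- setNames(list(models), models$gene_id)
  stopifnot(all(vapply(models, inherits, logical(1), "gene_model")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(models)) {
    saveRDS(models[[gid]],
            file.path(dir, paste0(gene_store_key(gid), ".rds")))
  }
  writeLines(names(models), file.path(dir, "genes.txt"))
  invisible(dir)
}

#' Load fitted gene models from a store directory
#'
#' @param dir Store directory written by [save_model_store()].
#' @param genes Optional character vector restricting which genes to load.
#' @return Named list of `gene_model` objects.
#' @export
load_model_store <- function(dir, genes = NULL) {
  idx <- readLines(file.path(dir, "genes.txt"))
  if (!is.null(genes)) {
    missing <- setdiff(genes, idx)
    if (length(missing) > 0)
      abort(paste("genes not in store:", paste(missing, collapse = ", ")))
    idx <- genes
  }
  setNames(lapply(idx, function(gid) {
    readRDS(file.path(dir, paste0(gene_store_key(gid), ".rds")))
  }), idx)
}

# filesystem-safe key for a gene id
gene_store_key <- function(gene_id) {
  gsub("[^A-Za-z0-9._-]", "_", gene_id)
}
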
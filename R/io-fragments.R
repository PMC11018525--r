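#' Read a scATAC fragments file into per-cell Tn5 insertion events
#'
#' Fragments files are 5-column TSVs (`chrom`, `start`, `end`, `barcode`,
#' `count`; BED-style 0-based half-open, optionally gzipped). Each fragment
#' contributes two Tn5 insertion events, at `start` and `end - 1`,
#' replicated `count` times. Fragments whose barcode is absent from
#' `cells` are skipped (a count of skipped fragments is reported).
#'
#' @param path Path to the fragments TSV (may be gzipped).
#' @param cells Cell table restricting the barcodes to keep; a tibble with
#'   a `barcode` column.
#' @return A tibble of insertion events: `barcode`, `chrom`, `pos`.
#' @export
read_fragments <- function(path, cells) {
  frags <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "barcode", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      barcode = readr::col_character(),
      count = readr::col_integer()
    ),
    comment = "#", progress = FALSE
  )
  bad <- which(!complete.cases(frags))
  if (length(bad) > 0)
    abort(sprintf("malformed fragment record at line %d of %s",
                  bad[1], path))
  if (any(frags$start >= frags$end))
    abort(sprintf("fragment with start >= end at line %d of %s",
                  which(frags$start >= frags$end)[1], path))
  fragments_to_insertions(frags, cells)
}

#' Expand fragment records into insertion events
#'
#' @param frags Data frame with columns `chrom`, `start`, `end`,
#'   `barcode`, `count`.
#' @inheritParams read_fragments
#' @return A tibble of insertion events: `barcode`, `chrom`, `pos`.
#' @export
fragments_to_insertions <- function(frags, cells) {
  known <- frags$barcode %in% cells$barcode
  n_skip <- sum(!known)
  if (n_skip > 0)
    inform(sprintf("skipped %d fragment(s) with barcodes absent from the cell table",
                   n_skip))
  frags <- frags[known, , drop = FALSE]
  count <- if ("count" %in% names(frags)) frags$count else rep(1L, nrow(frags))
  idx <- rep.int(seq_len(nrow(frags)), count)
  tibble::tibble(
    barcode = rep(frags$barcode[idx], each = 2L),
    chrom = rep(frags$chrom[idx], each = 2L),
    pos = as.vector(rbind(frags$start[idx], frags$end[idx] - 1L))
  )
}

#' Per-cell count of insertions near transcription start sites
#'
#' Fallback depth/quality normalizer when cell metadata does not already
#' carry a ReadsInTSS value: the number of insertions within `window_bp`
#' of any TSS, counting each insertion once even when TSS windows overlap,
#' floored at 1 so downstream normalization never divides by zero.
#'
#' @param insertions Tibble of insertion events (`barcode`, `chrom`, `pos`).
#' @param tss Data frame of TSS positions with columns `chrom`, `pos`.
#' @param cells Cell table fixing the output order.
#' @param window_bp Half-width of the TSS window (default 2,000 bp).
#' @return Named numeric vector of per-cell counts (names = barcodes).
#' @export
compute_reads_in_tss <- function(insertions, tss, cells, window_bp = 2000L) {
  if (nrow(tss) == 0) abort("`tss` must contain at least one site")
  in_tss <- rep(FALSE, nrow(insertions))
  for (chr in unique(tss$chrom)) {
    sel <- insertions$chrom == chr
    if (!any(sel)) next
    centers <- sort(tss$pos[tss$chrom == chr])
    pos <- insertions$pos[sel]
    nearest <- findInterval(pos, centers)
    d <- rep(Inf, length(pos))
    has_left <- nearest >= 1
    d[has_left] <- pos[has_left] - centers[nearest[has_left]]
    has_right <- nearest < length(centers)
    d[has_right] <- pmin(d[has_right],
                         centers[nearest[has_right] + 1] - pos[has_right])
    in_tss[sel] <- d <= window_bp
  }
  counts <- as.numeric(table(factor(insertions$barcode[in_tss],
                                    levels = cells$barcode)))
  setNames(pmax(counts, 1), cells$barcode)
}
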
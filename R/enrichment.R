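#' Distance-based annotation class of a tile
#'
#' Partitions a gene window's tiles into four classes: the gene-body
#' tiles; the `min(20, flank_tiles)` flank tiles immediately upstream of
#' the gene ("promoter-proximal", 10 kb at the default 500 bp tiles); the
#' same number immediately downstream ("downstream"); and everything else
#' ("distal"). Upstream/downstream are resolved by strand: for a minus
#' strand gene the promoter-proximal tiles lie on the right flank.
#'
#' @param tile Integer tile indices (1-based).
#' @param window A `gene_window`.
#' @param n_proximal Width of the promoter-proximal and downstream bands
#'   in tiles (default 20, shrunk to the flank width if smaller).
#' @return Character vector: `"gene_body"`, `"promoter_proximal"`,
#'   `"downstream"` or `"distal"`.
#' @export
distance_class <- function(tile, window, n_proximal = 20L) {
  stopifnot(inherits(window, "gene_window"))
  if (any(tile < 1 | tile > window$n_tiles))
    abort("tile index out of range for this window")
  f <- window$n_flank_tiles
  nb <- window$n_body_tiles
  npp <- min(n_proximal, f)

  left_band <- tile >= f - npp + 1L & tile <= f
  right_band <- tile >= f + nb + 1L & tile <= f + nb + npp
  out <- rep("distal", length(tile))
  out[tile > f & tile <= f + nb] <- "gene_body"
  if (window$strand == "+") {
    out[left_band] <- "promoter_proximal"
    out[right_band] <- "downstream"
  } else {
    out[right_band] <- "promoter_proximal"
    out[left_band] <- "downstream"
  }
  out
}

#' Assign matching keys to variants within gene windows
#'
#' Maps each variant into every supplied gene window it falls in and
#' attaches the matched-background key: MAF bin (`<0.01`, `0.01-0.1`,
#' `>0.1`), LD block, and distance class. Variants outside every LD block
#' get the sentinel block `"no_ld_block"` (reported via a message).
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (0-based),
#'   `maf`, plus any payload columns (e.g. `pip`, `trait`, `gene`,
#'   `is_causal`, `is_common`) that are carried through.
#' @param windows List of `gene_window` objects.
#' @param ld_blocks Tibble of non-overlapping intervals (`chrom`, `start`,
#'   `end`, optional `name`).
#' @return Tibble with one row per (variant, containing gene window):
#'   the input columns plus `gene_id`, `tile`, `maf_bin`, `ld_block`,
#'   `distance_class`, `group` (the concatenated match key).
#' @export
assign_match_groups <- function(variants, windows, ld_blocks) {
  stopifnot(all(c("variant_id", "chrom", "pos", "maf") %in% names(variants)))
  if (!"name" %in% names(ld_blocks))
    ld_blocks$name <- paste0("LD", seq_len(nrow(ld_blocks)))

  out <- purrr::map_dfr(windows, function(w) {
    sel <- variants$chrom == w$chrom &
      variants$pos >= w$window_start & variants$pos < w$window_end
    if (!any(sel)) return(NULL)
    v <- variants[sel, , drop = FALSE]
    v$gene_id <- w$gene_id
    v$tile <- as.integer((v$pos - w$window_start) %/% w$tile_size) + 1L
    v$distance_class <- distance_class(v$tile, w)
    v
  })
  if (nrow(out) == 0) return(out)

  out$maf_bin <- cut(out$maf, breaks = c(0, 0.01, 0.1, 0.5),
                     labels = c("<0.01", "0.01-0.1", ">0.1"),
                     include.lowest = FALSE)
  out$ld_block <- "no_ld_block"
  for (chr in unique(ld_blocks$chrom)) {
    sel <- out$chrom == chr
    if (!any(sel)) next
    bl <- ld_blocks[ld_blocks$chrom == chr, ]
    bl <- bl[order(bl$start), ]
    hit <- findInterval(out$pos[sel], bl$start)
    ok <- hit >= 1 & out$pos[sel] < bl$end[pmax(hit, 1)]
    out$ld_block[sel][ok] <- bl$name[hit[ok]]
  }
  n_out <- sum(out$ld_block == "no_ld_block")
  if (n_out > 0)
    inform(sprintf("%d variant-gene pairs fall outside all LD blocks (sentinel block used)",
                   n_out))
  out$group <- paste(out$maf_bin, out$ld_block, out$distance_class,
                     sep = "|")
  tibble::as_tibble(out)
}

# Per-unit, per-group enrichment of "positive" variants in linked tiles
# relative to the matched background. `unit_col` NULL collapses units so
# the match group itself becomes the resampling unit.
enrichment_by_unit <- function(variants, linked_set, positive_col,
                               unit_col = NULL) {
  stopifnot(all(c("variant_id", "gene_id", "tile", "group", "is_common")
                %in% names(variants)))
  linked_set <- dplyr::distinct(linked_set[c("gene_id", "tile")])
  v <- dplyr::mutate(
    variants,
    in_linked = paste(.data$gene_id, .data$tile) %in%
      paste(linked_set$gene_id, linked_set$tile)
  )
  common <- dplyr::summarise(
    dplyr::group_by(v[v$is_common, ], .data$group),
    common_linked = sum(.data$in_linked), common_all = dplyr::n(),
    .groups = "drop")

  pos <- v[v[[positive_col]], , drop = FALSE]
  if (is.null(unit_col)) {
    pos$..unit <- pos$group
  } else {
    pos$..unit <- pos[[unit_col]]
  }
  pos_counts <- dplyr::summarise(
    dplyr::group_by(pos, .data$..unit, .data$group),
    pos_linked = sum(.data$in_linked), pos_all = dplyr::n(),
    .groups = "drop")

  tab <- dplyr::inner_join(pos_counts, common, by = "group")
  tab <- tab[tab$common_linked > 0 & tab$common_all > 0 & tab$pos_all > 0, ]
  tab$enrichment <- (tab$pos_linked / tab$common_linked) /
    (tab$pos_all / tab$common_all)

  dplyr::summarise(
    dplyr::group_by(tab, unit = .data$..unit),
    n_groups = dplyr::n(), enrichment = mean(.data$enrichment),
    .groups = "drop")
}

new_enrichment_result <- function(by_unit, kind, n_boot, seed) {
  if (nrow(by_unit) == 0) {
    inform("no unit with a valid matched group; enrichment reported as 0")
    return(structure(
      list(kind = kind, by_unit = by_unit, mean = 0,
           ci_lower = NA_real_, ci_upper = NA_real_,
           n_boot = n_boot, seed = seed),
      class = "enrichment_result"))
  }
  boot <- if (nrow(by_unit) >= 2) {
    bootstrap_mean(by_unit$enrichment, n_iter = n_boot, seed = seed)
  } else {
    tibble::tibble(mean = mean(by_unit$enrichment),
                   ci_lower = NA_real_, ci_upper = NA_real_)
  }
  structure(
    list(kind = kind, by_unit = by_unit, mean = mean(by_unit$enrichment),
         ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
         n_boot = n_boot, seed = seed),
    class = "enrichment_result")
}

#' @export
#' @method print enrichment_result
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result: %s> mean enrichment %.3f [95%% CI %.3f, %.3f] over %d units\n",
              x$kind, x$mean, x$ci_lower, x$ci_upper, nrow(x$by_unit)))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) x$by_unit

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, mean_enrichment = x$mean,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 n_units = nrow(x$by_unit), n_boot = x$n_boot)
}

#' Enrichment of fine-mapped GWAS variants in gene-linked tiles
#'
#' For each trait and matched group, precision is the ratio of causal to
#' common variants inside the linked tiles; dividing by the group-wide
#' probability of a causal variant gives the per-group enrichment, which
#' is averaged over valid groups (both denominators positive) and then
#' over traits. Uncertainty comes from bootstrapping traits.
#'
#' @param variants Tibble from [assign_match_groups()] with logical
#'   columns `is_causal` and `is_common` and a `trait` column on causal
#'   rows. Traits with no causal variant in the universe are excluded.
#' @param linked Linked-tile table (needs `gene_id`, `tile`).
#' @param n_boot Bootstrap iterations (default 1,000).
#' @param seed Integer seed for the bootstrap.
#' @return An `enrichment_result` (per-trait table + bootstrap summary).
#' @export
gwas_enrichment <- function(variants, linked, n_boot = 1000L, seed = 1L) {
  by_unit <- enrichment_by_unit(variants, linked, "is_causal", "trait")
  dropped <- setdiff(unique(variants$trait[variants$is_causal]),
                     by_unit$unit)
  dropped <- dropped[!is.na(dropped)]
  if (length(dropped) > 0)
    inform(sprintf("%d trait(s) excluded (no valid matched group): %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  new_enrichment_result(by_unit, "gwas", n_boot, seed)
}

#' Enrichment of fine-mapped eQTLs in gene-linked tiles
#'
#' As [gwas_enrichment()], but the unit is the gene: causal and common
#' counts are restricted to each gene's own window (rows of `variants`
#' are already per variant-gene pair), and the bootstrap resamples genes.
#' Causal rows must carry the target gene in `gene_id` (set
#' `restrict_to_gene = FALSE` to count a causal variant in every window
#' it falls in).
#'
#' @inheritParams gwas_enrichment
#' @param restrict_to_gene Keep only causal rows whose containing window
#'   is the variant's own eQTL gene (requires an `egene` column; default
#'   TRUE when present).
#' @return An `enrichment_result` (per-gene table + bootstrap summary).
#' @export
eqtl_enrichment <- function(variants, linked, n_boot = 1000L, seed = 1L,
                            restrict_to_gene = "egene" %in% names(variants)) {
  if (restrict_to_gene) {
    drop <- variants$is_causal & variants$gene_id != variants$egene
    variants <- variants[!drop, , drop = FALSE]
  }
  by_unit <- enrichment_by_unit(variants, linked, "is_causal", "gene_id")
  new_enrichment_result(by_unit, "eqtl", n_boot, seed)
}

#' Enrichment of regulatory-database variants in gene-linked tiles
#'
#' For curated regulatory variants (e.g. the most stringent
#' rank/probability stratum of a regulatory variant database) there is no
#' trait or gene unit: enrichment is computed per matched group and
#' averaged (and bootstrapped) over groups.
#'
#' @param variants Tibble from [assign_match_groups()] with logical
#'   columns `is_regulatory` and `is_common`.
#' @inheritParams gwas_enrichment
#' @return An `enrichment_result` (per-group table + bootstrap summary).
#' @export
regdb_enrichment <- function(variants, linked, n_boot = 1000L, seed = 1L) {
  by_unit <- enrichment_by_unit(variants, linked, "is_regulatory",
                                unit_col = NULL)
  new_enrichment_result(by_unit, "regdb", n_boot, seed)
}

#' Percentile bootstrap of a mean
#'
#' Resamples the units with replacement and reports the observed mean
#' with a percentile 95% confidence interval.
#'
#' @param values Numeric vector (at least 2 values).
#' @param n_iter Bootstrap iterations (default 1,000).
#' @param seed Integer seed.
#' @return One-row tibble: `mean`, `ci_lower`, `ci_upper`, `n_iter`.
#' @export
bootstrap_mean <- function(values, n_iter = 1000L, seed = 1L) {
  stopifnot(length(values) >= 2)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) mean(sample(values, replace = TRUE)), numeric(1))
  })
  tibble::tibble(mean = mean(values),
                 ci_lower = quantile(boots, 0.025, names = FALSE),
                 ci_upper = quantile(boots, 0.975, names = FALSE),
                 n_iter = n_iter)
}

#' Bootstrap comparison of two paired sets of unit-level values
#'
#' Resamples units with replacement and summarizes the difference in
#' means, with a two-sided bootstrap p-value
#' `2 * min(P(diff <= 0), P(diff >= 0))` floored at `1 / n_iter`.
#'
#' @param values_a,values_b Paired numeric vectors (same units).
#' @param n_iter Bootstrap iterations (default 1,000).
#' @param seed Integer seed.
#' @return One-row tibble: `mean_diff`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n_iter`.
#' @export
bootstrap_difference <- function(values_a, values_b, n_iter = 1000L,
                                 seed = 1L) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) mean(sample(d, replace = TRUE)), numeric(1))
  })
  if (all(d == 0)) {
    p <- 1
  } else {
    p <- max(2 * min(mean(boots <= 0), mean(boots >= 0)), 1 / n_iter)
    p <- min(p, 1)
  }
  tibble::tibble(mean_diff = mean(d),
                 ci_lower = quantile(boots, 0.025, names = FALSE),
                 ci_upper = quantile(boots, 0.975, names = FALSE),
                 p_value = p, n_iter = n_iter)
}

#' Enrichment as a function of the number of top-ranked linked tiles
#'
#' Recomputes the overall mean enrichment on the top-`k` linked tiles
#' (ranked by leave-one-tile-out significance) for a sequence of
#' cutoffs.
#'
#' @param linked Ranked linked-tile table from [linked_tiles()] (must
#'   have `gene_id`, `tile`, `rank`).
#' @param variants Variant table as for the corresponding enrichment kind.
#' @param kind One of `"gwas"`, `"eqtl"`, `"regdb"`.
#' @param step Cutoff step size in tiles (default: 5 evenly spaced cuts).
#' @return Tibble with `n_top_tiles` and `enrichment` (mean over units);
#'   cutoffs whose linked set yields no valid group are dropped.
#' @export
enrichment_recall_curve <- function(linked, variants,
                                    kind = c("gwas", "eqtl", "regdb"),
                                    step = NULL) {
  kind <- match.arg(kind)
  linked <- dplyr::arrange(linked, .data$rank)
  n <- nrow(linked)
  if (n == 0)
    return(tibble::tibble(n_top_tiles = integer(0), enrichment = numeric(0)))
  if (is.null(step)) step <- max(1L, n %/% 5L)
  cuts <- unique(c(seq(step, n, by = step), n))
  positive_col <- if (kind == "regdb") "is_regulatory" else "is_causal"
  unit_col <- switch(kind, gwas = "trait", eqtl = "gene_id", regdb = NULL)
  purrr::map_dfr(cuts, function(k) {
    by_unit <- enrichment_by_unit(variants, linked[seq_len(k), ],
                                  positive_col, unit_col)
    if (nrow(by_unit) == 0) return(NULL)
    tibble::tibble(n_top_tiles = k, enrichment = mean(by_unit$enrichment))
  })
}
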
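# Shared fixtures, built in code. Small scales keep the default suite fast;
# the acceptance tests use the spec-scale study conditions.

tiny_gene <- function(len = 11703L, strand = "+") {
  tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1000000L,
                 end = 1000000L + len, strand = strand)
}

# a small multi-ome simulation reused across test files (lazy singleton)
small_sim_env <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(small_sim_env$sim)) {
    spec <- simulation_spec(n_cells = 600L, n_tiles = 60L, flank_tiles = 15L,
                            n_active = 4L, seed = 42L)
    small_sim_env$sim <- simulate_multiome(spec)
  }
  small_sim_env$sim
}

small_fit <- function() {
  if (is.null(small_sim_env$fit)) {
    sim <- small_sim()
    x <- as.matrix(normalize_accessibility(sim$atac$gene01,
                                           sim$cells$reads_in_tss))
    y <- as.numeric(normalize_expression(sim$rna)[, "gene01"])
    m <- fit_gene_model(x, y, gene_id = "gene01", seed = 7L)
    small_sim_env$fit <- list(sim = sim, x = x, y = y, m = m)
  }
  small_sim_env$fit
}

# hand-built gene model with known coefficients, for arithmetic checks
manual_model <- function(w, epsilon = 0, n_tiles = length(w)) {
  scaler <- structure(list(min = rep(0, n_tiles), max = rep(1, n_tiles),
                           n_train = 1L), class = "tile_scaler")
  structure(
    list(gene_id = "manual", w = w, epsilon = epsilon, alpha = 0,
         scaler = scaler, split = NULL, test_spearman = 1,
         test_degenerate = FALSE, converged = TRUE, n_iter = 0L,
         loss = 0, kkt = 0, cv = NULL, n_tiles = n_tiles),
    class = "gene_model")
}

# independent brute-force counting oracle used across the enrichment tests
oracle_enrichment <- function(variants, linked, positive_col, unit_col) {
  linked_key <- unique(paste(linked$gene_id, linked$tile))
  units <- if (is.null(unit_col)) {
    unique(variants$group[variants[[positive_col]]])
  } else {
    unique(variants[[unit_col]][variants[[positive_col]]])
  }
  units <- units[!is.na(units)]
  per_unit <- c()
  for (u in units) {
    sel_pos <- variants[[positive_col]] &
      (if (is.null(unit_col)) variants$group == u else variants[[unit_col]] == u)
    groups <- unique(variants$group[sel_pos])
    vals <- c()
    for (g in groups) {
      in_l <- paste(variants$gene_id, variants$tile) %in% linked_key
      ncl <- sum(sel_pos & variants$group == g & in_l)
      nca <- sum(sel_pos & variants$group == g)
      nol <- sum(variants$is_common & variants$group == g & in_l)
      noa <- sum(variants$is_common & variants$group == g)
      if (nol > 0 && noa > 0 && nca > 0)
        vals <- c(vals, (ncl / nol) / (nca / noa))
    }
    if (length(vals) > 0) per_unit[u] <- mean(vals)
  }
  per_unit
}
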
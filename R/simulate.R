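#' Specification for a synthetic multi-ome simulation
#'
#' Collects the knobs of the generative model the regression assumes:
#' per-cell-type tile accessibility rates with a handful of planted
#' enhancer tiles per gene, log-normal per-cell depth factors shared by
#' ATAC and RNA, and expression drawn Poisson from the linear model on
#' scaled accessibility. Defaults emulate a moderately sparse multi-ome:
#' a few hundredths of an insertion per 500 bp tile per cell in closed
#' chromatin, an order of magnitude more in open enhancer tiles of the
#' expressing cell type.
#'
#' @param n_cells Number of cells (default 2,000).
#' @param cell_types Named proportions summing to 1
#'   (default `c(A = 0.5, B = 0.3, C = 0.2)`).
#' @param n_genes Number of modelled genes (default 1).
#' @param n_tiles Tiles per gene window (default 200).
#' @param flank_tiles Flank tiles on each side (default 50; the gene body
#'   makes up the rest).
#' @param tile_size Tile width in bp (default 500).
#' @param n_active Planted enhancer tiles per gene (default 5).
#' @param rate_open Insertion rate per cell per active tile when the
#'   enhancer is open in that cell (default 2.5).
#' @param rate_closed Insertion rate for active tiles in non-expressing
#'   types and in expressing-type cells where the enhancer is closed
#'   (default 0.05).
#' @param p_active Probability that an active tile is open in a given
#'   cell of the expressing type (default 0.5). Stochastic per-cell
#'   enhancer activity, independent across cells and tiles, mirrors the
#'   bimodal accessibility of real scATAC data and gives each enhancer
#'   tile its own within-cell-type association with expression.
#' @param rate_bg_range Background per-tile rate range (default
#'   `c(0.02, 0.15)`).
#' @param w_range Range of the planted non-negative coefficients
#'   (default `c(2, 3)`).
#' @param epsilon_star Planted intercept on the log scale
#'   (default `log(2)`).
#' @param depth_sdlog Log-normal sigma of the per-cell depth factor
#'   (default 0.3).
#' @param n_background_genes Unmodelled genes padding the RNA matrix so
#'   per-cell totals are realistic (default 50).
#' @param overdispersion Gamma heterogeneity of tile rates; 0 (default)
#'   gives pure Poisson counts, larger values negative-binomial-like
#'   robustness checks.
#' @param seed Integer seed; fully determines the simulation.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_cells = 2000L,
                            cell_types = c(A = 0.5, B = 0.3, C = 0.2),
                            n_genes = 1L, n_tiles = 200L, flank_tiles = 50L,
                            tile_size = 500L, n_active = 5L,
                            rate_open = 2.5, rate_closed = 0.05,
                            p_active = 0.5,
                            rate_bg_range = c(0.02, 0.15),
                            w_range = c(2, 3), epsilon_star = log(2),
                            depth_sdlog = 0.3, n_background_genes = 50L,
                            overdispersion = 0, seed = 1L) {
  if (abs(sum(cell_types) - 1) > 1e-8)
    abort("cell type proportions must sum to 1")
  if (rate_open < 0 || rate_closed < 0 || any(rate_bg_range < 0))
    abort("rates must be non-negative")
  if (n_tiles <= 2 * flank_tiles)
    abort("n_tiles must exceed 2 * flank_tiles")
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a multi-ome dataset with planted enhancer-gene effects
#'
#' Generates per-gene cell-by-tile insertion counts
#' (`Poisson(cell-type rate x depth factor)`), then expression
#' `Poisson(exp(X_scaled w* + epsilon*))` where `X_scaled` is the
#' ReadsInTSS-normalized, per-tile min-max scaled accessibility and `w*`
#' is sparse and non-negative on the planted enhancer tiles. Each gene is
#' placed on its own chromosome with the window starting at 0. ReadsInTSS
#' is proportional to the depth factor.
#'
#' @param spec A `simulation_spec`.
#' @return A `multiome_sim` list: `cells` (tibble: `barcode`,
#'   `cell_type`, `reads_in_tss`, `depth`), `genes` (annotation tibble),
#'   `windows` (list of `gene_window`), `atac` (named list of sparse
#'   cell-by-tile counts), `rna` (cell-by-gene count matrix including
#'   background genes), `truth` (per-gene list: `active_tiles`, `w_star`,
#'   `epsilon_star`, `expressing_type`, `expected_expression`), and
#'   `expected_rna_total` (per-cell Poisson mean of the RNA total).
#' @export
simulate_multiome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    types <- names(spec$cell_types)
    cell_type <- sample(rep_len(
      rep(types, times = round(spec$cell_types * n)), n))
    depth <- rlnorm(n, meanlog = 0, sdlog = spec$depth_sdlog)
    cells <- tibble::tibble(
      barcode = sprintf("cell%05d", seq_len(n)),
      cell_type = cell_type,
      reads_in_tss = 1000 * depth,
      depth = depth
    )

    body_tiles <- spec$n_tiles - 2L * spec$flank_tiles
    genes <- tibble::tibble(
      gene_id = sprintf("gene%02d", seq_len(spec$n_genes)),
      chrom = sprintf("chrS%d", seq_len(spec$n_genes)),
      start = spec$flank_tiles * spec$tile_size,
      end = (spec$flank_tiles + body_tiles) * spec$tile_size,
      strand = rep(c("+", "-"), length.out = spec$n_genes)
    )
    windows <- lapply(seq_len(spec$n_genes), function(i) {
      make_gene_window(genes[i, ], flank = spec$flank_tiles * spec$tile_size,
                       tile_size = spec$tile_size)
    })
    names(windows) <- genes$gene_id

    atac <- list(); truth <- list()
    rna_model <- matrix(0L, n, spec$n_genes,
                        dimnames = list(cells$barcode, genes$gene_id))
    expected_expr <- matrix(0, n, spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      gid <- genes$gene_id[i]
      active <- sort(sample(spec$n_tiles, spec$n_active))
      expressing <- types[1 + (i - 1) %% length(types)]
      rate_bg <- runif(spec$n_tiles, spec$rate_bg_range[1],
                       spec$rate_bg_range[2])
      rate <- matrix(rate_bg, n, spec$n_tiles, byrow = TRUE)
      rate[, active] <- spec$rate_closed
      # stochastic per-cell enhancer state within the expressing type
      expr_cells <- which(cell_type == expressing)
      open_state <- matrix(
        runif(length(expr_cells) * spec$n_active) < spec$p_active,
        length(expr_cells), spec$n_active)
      rate[expr_cells, active][open_state] <- spec$rate_open
      lam <- rate * depth
      if (spec$overdispersion > 0) {
        shape <- 1 / spec$overdispersion
        lam <- lam * matrix(stats::rgamma(n * spec$n_tiles, shape,
                                          rate = shape),
                            n, spec$n_tiles)
      }
      counts <- matrix(rpois(n * spec$n_tiles, lam), n, spec$n_tiles,
                       dimnames = list(cells$barcode, NULL))
      atac[[gid]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                 "CsparseMatrix")

      x_norm <- as.matrix(normalize_accessibility(counts, cells$reads_in_tss))
      xs <- minmax_by_gene(x_norm)
      w_star <- numeric(spec$n_tiles)
      w_star[active] <- runif(spec$n_active, spec$w_range[1],
                              spec$w_range[2])
      mu <- exp(as.numeric(xs %*% w_star) + spec$epsilon_star)
      rna_model[, i] <- rpois(n, mu)
      expected_expr[, i] <- mu
      truth[[gid]] <- list(active_tiles = active, w_star = w_star,
                           epsilon_star = spec$epsilon_star,
                           expressing_type = expressing,
                           expected_expression = mu)
    }

    bg_rate <- rlnorm(spec$n_background_genes, meanlog = 1, sdlog = 1)
    rna_bg <- matrix(
      rpois(n * spec$n_background_genes, outer(depth, bg_rate)),
      n, spec$n_background_genes,
      dimnames = list(cells$barcode,
                      sprintf("bg%03d", seq_len(spec$n_background_genes))))
    rna <- cbind(rna_model, rna_bg)

    structure(
      list(spec = spec, cells = cells, genes = genes, windows = windows,
           atac = atac, rna = rna, truth = truth,
           expected_rna_total = rowSums(expected_expr) +
             as.numeric(depth * sum(bg_rate))),
      class = "multiome_sim")
  })
}

#' Materialize a simulated gene's counts as fragment records
#'
#' Converts the simulated tile counts into concrete Tn5 insertion
#' positions (spread uniformly within each tile) and pairs consecutive
#' insertions per cell into fragment records, so writing the fragments
#' TSV and re-reading it with [read_fragments()] plus
#' [build_tile_matrix()] reproduces the simulated counts exactly. An odd
#' leftover insertion is paired with a sentinel endpoint beyond the
#' window, which the tile matrix ignores.
#'
#' @param sim A `multiome_sim`.
#' @param gene_id Which gene to materialize.
#' @param seed Seed for placing insertions within tiles.
#' @return List with `fragments` (tibble: `chrom`, `start`, `end`,
#'   `barcode`, `count`) and `insertions` (tibble: `barcode`, `chrom`,
#'   `pos`, in-window events only).
#' @export
sim_fragments <- function(sim, gene_id, seed = 1L) {
  stopifnot(inherits(sim, "multiome_sim"))
  w <- sim$windows[[gene_id]]
  counts <- as.matrix(sim$atac[[gene_id]])
  withr::with_seed(seed, {
    ij <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[ij]
    cell_i <- rep(ij[, 1], reps)
    tile_j <- rep(ij[, 2], reps)
    pos <- w$window_start + (tile_j - 1L) * w$tile_size +
      sample.int(w$tile_size, length(tile_j), replace = TRUE) - 1L
    ins <- tibble::tibble(
      barcode = sim$cells$barcode[cell_i], chrom = w$chrom, pos = pos)
    ins <- ins[order(ins$barcode, ins$pos), ]

    frags <- dplyr::group_modify(
      dplyr::group_by(ins, .data$barcode), function(d, key) {
        p <- d$pos
        n_pairs <- length(p) %/% 2L
        out <- tibble::tibble(chrom = w$chrom, start = integer(0),
                              end = integer(0))
        if (n_pairs > 0) {
          a <- p[seq(1, 2 * n_pairs, by = 2)]
          b <- p[seq(2, 2 * n_pairs, by = 2)]
          out <- tibble::tibble(chrom = w$chrom, start = a, end = b + 1L)
        }
        if (length(p) %% 2L == 1L) {
          out <- dplyr::bind_rows(out, tibble::tibble(
            chrom = w$chrom, start = p[length(p)],
            end = w$window_end + 1000L))
        }
        out
      })
    frags <- dplyr::ungroup(frags)
    frags <- tibble::tibble(chrom = frags$chrom, start = frags$start,
                            end = frags$end, barcode = frags$barcode,
                            count = 1L)
    list(fragments = frags, insertions = ins)
  })
}

#' Write fragment records as a fragments TSV
#'
#' @param fragments Tibble with `chrom`, `start`, `end`, `barcode`,
#'   `count`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[c("chrom", "start", "end", "barcode", "count")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Simulate fine-mapped and common variants over simulated gene windows
#'
#' Common variants are placed uniformly over each window; causal variants
#' are placed with probability proportional to `enrichment_factor` on the
#' planted enhancer tiles and 1 elsewhere, so `enrichment_factor = 1`
#' makes causal and common placement exchangeable. MAF is drawn to
#' populate all three matching bins; causal variants get PIP in
#' (0.5, 1] and a trait label. LD blocks tile each window.
#'
#' @param sim A `multiome_sim`.
#' @param n_common Common variants per gene window (default 400).
#' @param n_causal Causal variants per gene window (default 40).
#' @param enrichment_factor Placement weight of causal variants on
#'   enhancer tiles relative to other tiles (default 10).
#' @param n_traits Number of trait labels cycled over causal variants
#'   (default 8).
#' @param ld_block_tiles LD block width in tiles (default 25).
#' @param seed Integer seed.
#' @return List with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `maf`, `pip`, `trait`, `is_causal`, `is_common`) and `ld_blocks`
#'   (tibble: `chrom`, `start`, `end`, `name`).
#' @export
simulate_variants <- function(sim, n_common = 400L, n_causal = 40L,
                              enrichment_factor = 10, n_traits = 8L,
                              ld_block_tiles = 25L, seed = 1L) {
  stopifnot(inherits(sim, "multiome_sim"))
  withr::with_seed(seed, {
    draw_maf <- function(k) {
      bin <- sample(3, k, replace = TRUE)
      ifelse(bin == 1, runif(k, 1e-4, 0.01),
             ifelse(bin == 2, runif(k, 0.01, 0.1), runif(k, 0.1, 0.5)))
    }
    res <- purrr::map(names(sim$windows), function(gid) {
      w <- sim$windows[[gid]]
      span <- w$window_end - w$window_start

      pos_c <- w$window_start + sample.int(span, n_common, replace = TRUE) - 1L
      tile_weight <- rep(1, w$n_tiles)
      tile_weight[sim$truth[[gid]]$active_tiles] <- enrichment_factor
      tiles_k <- sample(w$n_tiles, n_causal, replace = TRUE,
                        prob = tile_weight)
      pos_k <- w$window_start + (tiles_k - 1L) * w$tile_size +
        sample.int(w$tile_size, n_causal, replace = TRUE) - 1L

      variants <- dplyr::bind_rows(
        tibble::tibble(
          variant_id = sprintf("%s_common%04d", gid, seq_len(n_common)),
          chrom = w$chrom, pos = pos_c, maf = draw_maf(n_common),
          pip = 0, trait = NA_character_,
          is_causal = FALSE, is_common = TRUE),
        tibble::tibble(
          variant_id = sprintf("%s_causal%04d", gid, seq_len(n_causal)),
          chrom = w$chrom, pos = pos_k, maf = draw_maf(n_causal),
          pip = runif(n_causal, 0.5, 1),
          trait = sprintf("trait%02d",
                          1 + (seq_len(n_causal) - 1) %% n_traits),
          is_causal = TRUE, is_common = FALSE)
      )
      block_bp <- ld_block_tiles * w$tile_size
      starts <- seq(w$window_start, w$window_end - 1L, by = block_bp)
      ld <- tibble::tibble(
        chrom = w$chrom, start = starts,
        end = pmin(starts + block_bp, w$window_end),
        name = sprintf("%s_LD%03d", gid, seq_along(starts)))
      list(variants = variants, ld = ld)
    })
    list(variants = purrr::map_dfr(res, "variants"),
         ld_blocks = purrr::map_dfr(res, "ld"))
  })
}

#' Simulate a differentiation trajectory with accessibility leading expression
#'
#' Cells are ordered on a pseudotime in `[0, 1]`. Each driver gene
#' switches along a sigmoid at time `t0` -- half the genes activate, half
#' deactivate, as in real differentiation where early-state markers turn
#' off, which keeps expression profiles informative at both trajectory
#' ends. Chromatin (and therefore the model-predicted expression) follows
#' the sigmoid at `t0`, while the observed expression follows the same
#' sigmoid delayed by `delta`. The 2D layout is a noisy curve
#' parameterized by pseudotime, and the true differentiation direction is
#' the curve tangent.
#'
#' @param n_cells Number of cells (default 800).
#' @param n_genes Driver genes (default 40).
#' @param delta Pseudotime lag of expression behind accessibility
#'   (default 0.15; 0 plants no lead).
#' @param frac_down Fraction of deactivating genes (default 0.5).
#' @param steepness Sigmoid steepness (default 12).
#' @param expr_scale Mean expression at full activation (default 20).
#' @param noise_sd Layout jitter (default 0.15).
#' @param seed Integer seed.
#' @return List with `pred` (accessibility-timed expected expression,
#'   cells x genes), `obs` (Poisson counts at the delayed timing),
#'   `atac` (Poisson accessibility counts at the leading timing),
#'   `layout` (cells x 2), `pseudotime`, `true_direction` (unit
#'   tangents), `cell_types` (pseudotime tertile labels).
#' @export
simulate_trajectory <- function(n_cells = 800L, n_genes = 40L,
                                delta = 0.15, frac_down = 0.5,
                                steepness = 12, expr_scale = 20,
                                noise_sd = 0.15, seed = 1L) {
  if (delta < 0) abort("`delta` must be non-negative")
  withr::with_seed(seed, {
    t <- sort(runif(n_cells))
    t0 <- runif(n_genes, 0.1, 0.7)
    down <- seq_len(n_genes) <= round(frac_down * n_genes)
    sig <- function(tt, t0) 1 / (1 + exp(-steepness * (tt - t0)))
    shape <- function(tt, t0) {
      f <- outer(tt, t0, sig)
      f[, down] <- 1 - f[, down]
      f
    }
    acc_frac <- shape(t, t0)
    obs_frac <- shape(t, t0 + delta)

    pred <- expr_scale * acc_frac
    obs <- matrix(rpois(n_cells * n_genes, expr_scale * obs_frac),
                  n_cells, n_genes)
    atac <- matrix(rpois(n_cells * n_genes, 5 * acc_frac),
                   n_cells, n_genes)
    dimnames(pred) <- dimnames(obs) <- dimnames(atac) <-
      list(sprintf("cell%04d", seq_len(n_cells)),
           sprintf("driver%03d", seq_len(n_genes)))

    x <- 10 * t + rnorm(n_cells, sd = noise_sd)
    y <- 3 * sin(pi * t) + rnorm(n_cells, sd = noise_sd)
    tangent <- cbind(rep(10, n_cells), 3 * pi * cos(pi * t))
    tangent <- tangent / sqrt(rowSums(tangent^2))

    list(pred = pred, obs = obs, atac = atac,
         layout = cbind(x = x, y = y), pseudotime = t,
         true_direction = tangent,
         cell_types = paste0("stage",
                             as.integer(cut(t, 3, labels = FALSE))))
  })
}
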
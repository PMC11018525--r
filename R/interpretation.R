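#' Cell-type-specific approximate Shapley scores for tiles
#'
#' For a linear predictor the Shapley value of tile `t` on a profile `x`
#' reduces to `w_t * (x_t - mean(X[, t]))`, where the background mean is
#' taken over all training cells. Scores are computed per cell type by
#' repeatedly sampling `pseudobulk_size` training cells of the type
#' (without replacement within an iteration), averaging their scaled
#' accessibility into a pseudobulk profile, scoring it, and averaging over
#' `n_iter` iterations; the per-tile means are then z-scored across tiles
#' within the (gene, cell type) pair. Cell types with fewer than
#' `min_cells` training cells are skipped.
#'
#' @param model A `gene_model`.
#' @param x Cell-by-tile accessibility matrix for the training cells
#'   (depth-normalized; scaled internally unless `scaled = TRUE`).
#' @param cell_types Character vector of cell-type labels, one per row of
#'   `x`.
#' @param seed Integer seed for pseudobulk sampling.
#' @param n_iter Pseudobulk iterations per cell type (default 500).
#' @param pseudobulk_size Cells per pseudobulk sample (default 50).
#' @param min_cells Minimum cells for a type to be scored (default 100).
#' @param scaled Whether `x` is already min-max scaled.
#' @return A `shapley_table` tibble: `gene_id`, `cell_type`, `tile`,
#'   `shapley` (mean over iterations), `z`, `n_cells`.
#' @export
shapley_scores <- function(model, x, cell_types, seed = 1L, n_iter = 500L,
                           pseudobulk_size = 50L, min_cells = 100L,
                           scaled = FALSE) {
  stopifnot(inherits(model, "gene_model"), nrow(x) == length(cell_types))
  xs <- as.matrix(x)
  if (!scaled) xs <- apply_scaler(model$scaler, xs)
  bg_mean <- colMeans(xs)
  w <- model$w

  types <- sort(unique(cell_types))
  out <- purrr::map_dfr(types, function(ct) {
    idx <- which(cell_types == ct)
    if (length(idx) < min_cells) {
      inform(sprintf("skipping cell type '%s': %d cells < %d required",
                     ct, length(idx), min_cells))
      return(NULL)
    }
    size <- min(pseudobulk_size, length(idx))
    shap_sum <- numeric(length(w))
    withr::with_seed(seed + match(ct, types), {
      for (it in seq_len(n_iter)) {
        pb <- colMeans(xs[sample(idx, size), , drop = FALSE])
        shap_sum <- shap_sum + w * (pb - bg_mean)
      }
    })
    shap <- shap_sum / n_iter
    s <- sd(shap)
    z <- if (s > 0) (shap - mean(shap)) / s else rep(0, length(shap))
    tibble::tibble(
      gene_id = model$gene_id, cell_type = ct, tile = seq_along(w),
      shapley = shap, z = z, n_cells = length(idx)
    )
  })
  structure(out, class = c("shapley_table", class(out)),
            n_iter = n_iter, pseudobulk_size = pseudobulk_size)
}

#' Leave-one-tile-out significance of tiles on held-out cells
#'
#' For each tile with a positive coefficient, predictions "without the
#' tile" are formed by zeroing its coefficient (intercept and scaler
#' untouched), and a one-sided paired Wilcoxon signed-rank test compares
#' the absolute prediction errors with versus without the tile per cell
#' type (H1: errors are smaller with the tile). Tiles with a zero
#' coefficient yield identical predictions and get `p = 1` by convention.
#'
#' @param model A `gene_model`.
#' @param x_test Accessibility matrix for held-out cells (depth-normalized;
#'   scaled internally unless `scaled = TRUE`).
#' @param y_test Observed normalized expression for those cells.
#' @param cell_types Cell-type labels for the held-out cells.
#' @param scaled Whether `x_test` is already scaled.
#' @return Tibble: `gene_id`, `cell_type`, `tile`, `p_value` (one row per
#'   tile and cell type). Apply [bh_fdr()] across the full run (all genes)
#'   to obtain q-values.
#' @export
tile_significance <- function(model, x_test, y_test, cell_types,
                              scaled = FALSE) {
  stopifnot(inherits(model, "gene_model"),
            nrow(x_test) == length(y_test),
            length(cell_types) == length(y_test))
  xs <- as.matrix(x_test)
  if (!scaled) xs <- apply_scaler(model$scaler, xs)
  eta <- as.numeric(xs %*% model$w + model$epsilon)
  err_with <- abs(exp(eta) - y_test)
  types <- sort(unique(cell_types))

  purrr::map_dfr(seq_along(model$w), function(t) {
    if (model$w[t] == 0) {
      return(tibble::tibble(gene_id = model$gene_id, cell_type = types,
                            tile = t, p_value = 1))
    }
    eta_wo <- eta - xs[, t] * model$w[t]
    err_wo <- abs(exp(eta_wo) - y_test)
    p <- vapply(types, function(ct) {
      sel <- cell_types == ct
      paired_signed_rank(err_with[sel], err_wo[sel], alternative = "less")
    }, numeric(1))
    tibble::tibble(gene_id = model$gene_id, cell_type = types,
                   tile = t, p_value = p)
  })
}

#' Filter gene-linked tiles
#'
#' The enhancer-candidate filter: keep tiles from genes whose held-out
#' Spearman correlation exceeds `rho_min`, with Shapley z-score above
#' `z_min` and BH-adjusted leave-one-tile-out significance below `q_max`.
#' Tiles are ranked by p-value for enrichment-recall analysis.
#'
#' @param shapley A `shapley_table` (possibly covering several genes).
#' @param sig Tile-significance table with `p_value`, and `q_value` if
#'   already adjusted (otherwise BH is applied across the rows of `sig`).
#' @param model_results Per-gene results tibble with `gene_id` and
#'   `test_spearman` (e.g. from [fit_gene_models()]).
#' @param rho_min Minimum model test correlation (default 0.1).
#' @param z_min Minimum Shapley z-score (default 0.5).
#' @param q_max Maximum FDR (default 0.001).
#' @return Tibble of linked tiles: `gene_id`, `cell_type`, `tile`, `z`,
#'   `p_value`, `q_value`, `test_spearman`, `rank` (1 = most significant).
#' @export
linked_tiles <- function(shapley, sig, model_results, rho_min = 0.1,
                         z_min = 0.5, q_max = 0.001) {
  if (!"q_value" %in% names(sig))
    sig <- dplyr::mutate(sig, q_value = bh_fdr(.data$p_value))
  out <- dplyr::inner_join(
    tibble::as_tibble(shapley)[c("gene_id", "cell_type", "tile", "z")],
    sig[c("gene_id", "cell_type", "tile", "p_value", "q_value")],
    by = c("gene_id", "cell_type", "tile")
  )
  out <- dplyr::inner_join(out, model_results[c("gene_id", "test_spearman")],
                           by = "gene_id")
  out <- dplyr::filter(out, .data$test_spearman > rho_min,
                       .data$z > z_min, .data$q_value < q_max)
  out <- dplyr::arrange(out, .data$p_value, dplyr::desc(.data$z))
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Dependent-correlation test for comparing two predictors of one outcome
#'
#' Tests whether correlation `rho12` (method 1 vs shared outcome) exceeds
#' `rho13` (method 2 vs the same outcome), accounting for their dependence
#' through `rho23` (method 1 vs method 2):
#' \deqn{t = (\rho_{12}-\rho_{13}) \sqrt{\frac{(n-1)(1+\rho_{23})}
#'   {2\frac{n-1}{n-3}|S| + \frac{(\rho_{12}+\rho_{13})^2}{4}(1-\rho_{23})^3}}
#'   \sim T(n-3)}
#' with \eqn{|S| = 1 - (\rho_{12}^2+\rho_{13}^2+\rho_{23}^2) +
#' 2\rho_{12}\rho_{13}\rho_{23}}. One-sided p from the Student t
#' distribution with `n - 3` degrees of freedom (H1:
#' \eqn{\rho_{12} > \rho_{13}}).
#'
#' @param rho12,rho13,rho23 Correlations in (-1, 1) (vectorized).
#' @param n Number of observations (> 3).
#' @return Tibble with `t_stat` and `p_value`.
#' @export
dependent_correlation_test <- function(rho12, rho13, rho23, n) {
  if (any(n <= 3)) abort("dependent_correlation_test requires n > 3")
  det_s <- 1 - (rho12^2 + rho13^2 + rho23^2) + 2 * rho12 * rho13 * rho23
  denom <- 2 * ((n - 1) / (n - 3)) * det_s +
    ((rho12 + rho13)^2 / 4) * (1 - rho23)^3
  t_stat <- ifelse(
    rho12 == rho13, 0,
    ifelse(denom > 0,
           (rho12 - rho13) * sqrt((n - 1) * (1 + rho23) / denom),
           sign(rho12 - rho13) * Inf)
  )
  tibble::tibble(t_stat = t_stat,
                 p_value = pt(t_stat, df = n - 3, lower.tail = FALSE))
}

#' Compare two prediction vectors against a shared observed outcome
#'
#' Computes the Spearman correlations of each prediction with the outcome
#' and between the predictions, then applies
#' [dependent_correlation_test()].
#'
#' @param pred_a,pred_b Prediction vectors (method 1 and method 2).
#' @param obs Observed outcome vector.
#' @return One-row tibble: `rho12`, `rho13`, `rho23`, `n`, `t_stat`,
#'   `p_value`.
#' @export
compare_predictions <- function(pred_a, pred_b, obs) {
  stopifnot(length(pred_a) == length(obs), length(pred_b) == length(obs))
  rho12 <- cor(pred_a, obs, method = "spearman")
  rho13 <- cor(pred_b, obs, method = "spearman")
  rho23 <- cor(pred_a, pred_b, method = "spearman")
  res <- dependent_correlation_test(rho12, rho13, rho23, length(obs))
  tibble::tibble(rho12 = rho12, rho13 = rho13, rho23 = rho23,
                 n = length(obs), t_stat = res$t_stat,
                 p_value = res$p_value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties receive average ranks; the exact
#' null distribution is used for up to 25 informative pairs and the normal
#' approximation with continuity correction beyond that. When every pair
#' is tied the test is uninformative and `p = 1` by convention.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`
#'   (directions refer to `a` relative to `b`).
#' @return The p-value.
#' @export
paired_signed_rank <- function(a, b,
                               alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  suppressWarnings(
    wilcox.test(d, mu = 0, alternative = alternative,
                exact = length(d) <= 25, correct = TRUE)$p.value
  )
}

#' Compare Shapley scores of interacting versus non-interacting tiles
#'
#' Benchmarks tile scores against externally supplied promoter-interaction
#' calls (e.g. promoter capture Hi-C). Interactions spanning several tiles
#' are represented by their maximum score. Both the interacting and the
#' background (non-interacting tiles of the same genes) sets are
#' restricted to tiles whose accessibility exceeds the 10th percentile of
#' `reference_accessibility`, then subsampled within accessibility
#' quantile bins so the two accessibility distributions match, and finally
#' compared per cell type with a one-sided Mann-Whitney U test
#' (H1: interacting tiles score higher).
#'
#' @param shapley A `shapley_table` covering the genes of interest.
#' @param interactions Tibble mapping interactions to tiles:
#'   `gene_id`, `interaction_id`, `tile`.
#' @param accessibility Tibble of per-tile mean accessibility:
#'   `gene_id`, `tile`, `accessibility`.
#' @param reference_accessibility Numeric vector defining the
#'   accessibility floor (default: the accessibility values supplied).
#' @param score_col Which score column of `shapley` to compare
#'   (default `"z"`).
#' @param n_bins Number of accessibility quantile bins for matching.
#' @param seed Integer seed for the matching subsample.
#' @return Tibble per cell type: `cell_type`, `n_interacting`,
#'   `n_background`, `p_value`. Cell types with an empty matched set are
#'   skipped.
#' @export
interaction_score_comparison <- function(shapley, interactions, accessibility,
                                         reference_accessibility =
                                           accessibility$accessibility,
                                         score_col = "z", n_bins = 10L,
                                         seed = 1L) {
  floor_acc <- quantile(reference_accessibility, 0.1, names = FALSE)
  shap <- dplyr::inner_join(tibble::as_tibble(shapley), accessibility,
                            by = c("gene_id", "tile"))
  shap$score <- shap[[score_col]]
  int_tiles <- dplyr::distinct(interactions[c("gene_id", "tile", "interaction_id")])

  purrr::map_dfr(sort(unique(shap$cell_type)), function(ct) {
    s_ct <- shap[shap$cell_type == ct, ]
    # per-interaction representative: max score over spanned tiles
    int_ct <- dplyr::inner_join(int_tiles, s_ct, by = c("gene_id", "tile"))
    int_rep <- dplyr::summarise(
      dplyr::group_by(int_ct, .data$gene_id, .data$interaction_id),
      score = max(.data$score),
      accessibility = max(.data$accessibility), .groups = "drop")
    bg <- dplyr::anti_join(s_ct, int_tiles, by = c("gene_id", "tile"))
    bg <- bg[bg$gene_id %in% int_rep$gene_id, ]

    int_rep <- int_rep[int_rep$accessibility > floor_acc, ]
    bg <- bg[bg$accessibility > floor_acc, ]
    if (nrow(int_rep) == 0 || nrow(bg) == 0) {
      inform(sprintf("skipping cell type '%s': empty matched set", ct))
      return(NULL)
    }

    breaks <- unique(quantile(c(int_rep$accessibility, bg$accessibility),
                              probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(breaks) < 2) {
      # accessibility is (near-)constant: a single matching bin
      bin_int <- factor(rep("all", nrow(int_rep)))
      bin_bg <- factor(rep("all", nrow(bg)))
    } else {
      bin_int <- cut(int_rep$accessibility, breaks, include.lowest = TRUE)
      bin_bg <- cut(bg$accessibility, breaks, include.lowest = TRUE)
    }
    keep <- withr::with_seed(seed, {
      lapply(levels(bin_int), function(b) {
        ii <- which(bin_int == b); jj <- which(bin_bg == b)
        m <- min(length(ii), length(jj))
        list(int = if (m > 0) sample(ii, m) else integer(0),
             bg = if (m > 0) sample(jj, m) else integer(0))
      })
    })
    int_keep <- unlist(lapply(keep, `[[`, "int"))
    bg_keep <- unlist(lapply(keep, `[[`, "bg"))
    if (length(int_keep) == 0 || length(bg_keep) == 0) {
      inform(sprintf("skipping cell type '%s': empty matched set", ct))
      return(NULL)
    }
    p <- suppressWarnings(
      wilcox.test(int_rep$score[int_keep], bg$score[bg_keep],
                  alternative = "greater")$p.value)
    tibble::tibble(cell_type = ct, n_interacting = length(int_keep),
                   n_background = length(bg_keep), p_value = p)
  })
}
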
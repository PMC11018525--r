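#' Poisson regression loss for a gene model
#'
#' The per-cell average Poisson negative log-likelihood kernel plus an L2
#' penalty on the coefficients:
#' \deqn{\frac{1}{N}\sum_i \left(e^{X_i w + \epsilon} - y_i (X_i w + \epsilon)\right) + \alpha \|w\|_2^2}
#'
#' @param X Scaled cell-by-tile matrix.
#' @param y Normalized expression vector (need not be integer).
#' @param w Coefficient vector (length `ncol(X)`).
#' @param epsilon Intercept.
#' @param alpha L2 regularization weight.
#' @return The scalar loss.
#' @export
poisson_loss <- function(X, y, w, epsilon, alpha) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)) || !all(is.finite(w)) ||
      !is.finite(epsilon) || !is.finite(alpha))
    abort("poisson_loss requires finite inputs")
  stopifnot(length(y) == nrow(X), length(w) == ncol(X))
  cpp_poisson_loss(X, as.numeric(y), as.numeric(w), epsilon, alpha)
}

#' Fit the (non-negative) regularized Poisson regression
#'
#' Full-batch adaptive-moment (Adam) gradient descent on `(w, epsilon)`
#' with projection of `w` onto the non-negative orthant after every step,
#' stopping when the relative loss change falls below `tol` or at
#' `max_iter`. An active-set projected Newton polish (enabled by default)
#' then drives the KKT residual to `polish_tol`, so exact zeros and
#' first-order optimality are both attained. The intercept is
#' unconstrained but floored at `log(1e-8)` so all-zero targets degrade
#' gracefully.
#'
#' @param X Scaled cell-by-tile matrix (training cells).
#' @param y Normalized expression vector for the same cells.
#' @param alpha L2 regularization weight (non-negative).
#' @param nonneg Constrain coefficients to be non-negative (default TRUE).
#' @param lr Adam learning rate (default 0.01).
#' @param max_iter Maximum Adam iterations (default 5,000).
#' @param tol Relative loss-change convergence tolerance (default 1e-6).
#' @param polish Run the Newton refinement (default TRUE).
#' @param polish_tol KKT residual target for the polish (default 1e-9).
#' @param polish_max_iter Maximum Newton steps (default 100).
#' @return List with `w`, `epsilon`, `loss`, `n_iter`, `converged`, `kkt`.
#' @export
fit_poisson <- function(X, y, alpha, nonneg = TRUE, lr = 0.01,
                        max_iter = 5000L, tol = 1e-6, polish = TRUE,
                        polish_tol = 1e-9, polish_max_iter = 100L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), alpha >= 0)
  eps_init <- log(mean(y) + 1e-8)
  fit <- cpp_fit_poisson(X, as.numeric(y), alpha, lr, as.integer(max_iter),
                         tol, nonneg, eps_init, log(1e-8), polish,
                         as.integer(polish_max_iter), polish_tol)
  fit$w <- as.numeric(fit$w)
  fit
}

#' Select the regularization weight by k-fold cross-validation
#'
#' For each candidate `alpha`, fits on each fold's complement and scores
#' the held-out fold by the unpenalized Poisson deviance term
#' `mean(exp(eta) - y * eta)`; returns the candidate with the lowest mean
#' held-out score. Ties resolve to the larger (more regularized) value.
#'
#' @param X Scaled cell-by-tile matrix covering at least the training cells
#'   (rows indexed by the split's fold indices).
#' @param y Normalized expression vector aligned to `X`.
#' @param split A `cell_split` from [split_cells()].
#' @param grid Candidate alphas (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param ... Passed to [fit_poisson()].
#' @return List with `alpha` (the selection) and `cv` (a tibble of
#'   per-alpha mean held-out deviance).
#' @export
select_alpha <- function(X, y, split, grid = c(0.01, 0.1, 1, 10, 100), ...) {
  stopifnot(inherits(split, "cell_split"), length(grid) >= 1)
  X <- as.matrix(X)
  scores <- vapply(grid, function(a) {
    fold_dev <- vapply(split$folds, function(hold) {
      tr <- setdiff(split$train_idx, hold)
      fit <- fit_poisson(X[tr, , drop = FALSE], y[tr], alpha = a, ...)
      eta <- X[hold, , drop = FALSE] %*% fit$w + fit$epsilon
      mean(exp(eta) - y[hold] * eta)
    }, numeric(1))
    mean(fold_dev)
  }, numeric(1))
  finite <- is.finite(scores)
  if (!any(finite)) abort("all cross-validation fits diverged")
  best <- max(grid[finite & scores == min(scores[finite])])  # tie -> larger alpha
  list(alpha = best,
       cv = tibble::tibble(alpha = grid, mean_heldout_deviance = scores))
}

#' Fit a complete per-gene model: split, scale, cross-validate, evaluate
#'
#' The end-to-end per-gene workflow: hold out a quarter of the cells,
#' min-max scale each tile on the training cells only, select the L2
#' weight by fourfold cross-validation (unless `alpha` is given), fit the
#' non-negative Poisson regression on all training cells, and score the
#' fit by Spearman correlation between predicted and observed expression
#' on the held-out cells.
#'
#' @param x Cell-by-tile accessibility matrix, already depth-normalized
#'   (see [normalize_accessibility()]).
#' @param y Depth-normalized expression vector for the same cells (see
#'   [normalize_expression()]).
#' @param gene_id Gene identifier stored on the model.
#' @param split Optional `cell_split`; by default a fresh split seeded by
#'   `seed`.
#' @param seed Seed used when `split` is NULL.
#' @param alpha Optional fixed L2 weight; skips cross-validation.
#' @param alpha_grid Candidate alphas for cross-validation.
#' @param ... Passed to [fit_poisson()].
#' @return A `gene_model` object.
#' @export
fit_gene_model <- function(x, y, gene_id = "gene", split = NULL, seed = 1L,
                           alpha = NULL, alpha_grid = c(0.01, 0.1, 1, 10, 100),
                           ...) {
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x))
  if (is.null(split)) split <- split_cells(nrow(x), seed = seed)
  scaler <- fit_scaler(x[split$train_idx, , drop = FALSE])
  xs <- apply_scaler(scaler, x)

  cv <- NULL
  if (is.null(alpha)) {
    sel <- select_alpha(xs, y, split, grid = alpha_grid, ...)
    alpha <- sel$alpha
    cv <- sel$cv
  }
  fit <- fit_poisson(xs[split$train_idx, , drop = FALSE], y[split$train_idx],
                     alpha = alpha, ...)

  eta_test <- xs[split$test_idx, , drop = FALSE] %*% fit$w + fit$epsilon
  ev <- spearman_safe(exp(as.numeric(eta_test)), y[split$test_idx])

  structure(
    list(gene_id = gene_id, w = fit$w, epsilon = fit$epsilon, alpha = alpha,
         scaler = scaler, split = split, test_spearman = ev$rho,
         test_degenerate = ev$degenerate, converged = fit$converged,
         n_iter = fit$n_iter, loss = fit$loss, kkt = fit$kkt, cv = cv,
         n_tiles = ncol(x)),
    class = "gene_model"
  )
}

# Spearman correlation with the degenerate-input convention: a constant
# vector has no rank ordering, so rho is reported as 0 with a flag.
spearman_safe <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0)
    return(list(rho = 0, degenerate = TRUE))
  list(rho = suppressWarnings(cor(a, b, method = "spearman")),
       degenerate = FALSE)
}

#' Predict expression from a fitted gene model
#'
#' @param object A `gene_model`.
#' @param newdata Cell-by-tile matrix of depth-normalized accessibility
#'   (scaled internally with the model's stored scaler), or an
#'   already-scaled matrix when `scaled = TRUE`.
#' @param scaled Whether `newdata` is already min-max scaled.
#' @param ... Unused.
#' @return Non-negative numeric vector `exp(X w + epsilon)`.
#' @export
predict.gene_model <- function(object, newdata, scaled = FALSE, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$w))
    abort(sprintf("newdata has %d tiles; model expects %d",
                  ncol(x), length(object$w)))
  if (!scaled) x <- apply_scaler(object$scaler, x)
  exp(as.numeric(x %*% object$w + object$epsilon))
}

#' Evaluate a gene model on held-out cells
#'
#' @param model A `gene_model`.
#' @param x_test Accessibility matrix for the evaluation cells
#'   (depth-normalized; scaled internally).
#' @param y_test Observed normalized expression for those cells.
#' @param scaled Whether `x_test` is already scaled.
#' @return List with `rho` (Spearman, average-rank ties) and `degenerate`
#'   (TRUE when either vector is constant, in which case `rho` is 0).
#' @export
evaluate_model <- function(model, x_test, y_test, scaled = FALSE) {
  y_hat <- predict(model, x_test, scaled = scaled)
  spearman_safe(y_hat, y_test)
}

#' @export
#' @method print gene_model
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s | %d tiles | alpha = %g | test Spearman rho = %.3f%s\n",
    x$gene_id, x$n_tiles, x$alpha, x$test_spearman,
    if (x$test_degenerate) " (degenerate)" else ""))
  cat(sprintf("  %d active tiles (w > 0), intercept %.4f, KKT residual %.2e\n",
              sum(x$w > 0), x$epsilon, x$kkt))
  invisible(x)
}

#' Tidy a fitted gene model into a per-tile coefficient table
#'
#' @param x A `gene_model`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `tile`, `estimate`, `active`.
#' @export
tidy.gene_model <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id,
    tile = seq_along(x$w),
    estimate = x$w,
    active = x$w > 0
  )
}

#' One-row model summary
#'
#' @param x A `gene_model`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `alpha`, `test_spearman`, `n_tiles`,
#'   `n_active`, `converged`, `n_iter`, `loss`.
#' @export
glance.gene_model <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, alpha = x$alpha, test_spearman = x$test_spearman,
    n_tiles = x$n_tiles, n_active = sum(x$w > 0), converged = x$converged,
    n_iter = x$n_iter, loss = x$loss
  )
}

#' Fit models for many genes and summarize them
#'
#' Convenience wrapper fitting one model per gene over a shared cell
#' split, returning the models and a per-gene results table.
#'
#' @param tile_matrices Named list of cell-by-tile accessibility matrices
#'   (depth-normalized), one per gene.
#' @param expression Cell-by-gene matrix of depth-normalized expression
#'   with column names covering the gene ids.
#' @param split Optional shared `cell_split`.
#' @param seed Seed for the split when not supplied.
#' @param ... Passed to [fit_gene_model()].
#' @return List with `models` (named list of `gene_model`) and `results`
#'   (tibble, one row per gene from [glance.gene_model()]).
#' @export
fit_gene_models <- function(tile_matrices, expression, split = NULL,
                            seed = 1L, ...) {
  stopifnot(!is.null(names(tile_matrices)),
            all(names(tile_matrices) %in% colnames(expression)))
  n <- nrow(expression)
  if (is.null(split)) split <- split_cells(n, seed = seed)
  models <- purrr::imap(tile_matrices, function(x, gid) {
    fit_gene_model(x, as.numeric(expression[, gid]), gene_id = gid,
                   split = split, ...)
  })
  list(models = models,
       results = purrr::map_dfr(models, glance))
}
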
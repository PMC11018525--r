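test_that("Shapley scores follow the linear attribution formula", {
  # w_t (pseudobulk_t - background mean_t): controlled check with one cell type
  m <- manual_model(w = c(2, 0, 1))
  x <- rbind(c(0.8, 0.2, 0.1),
             c(0.8, 0.9, 0.1),
             c(0.8, 0.4, 0.1))  # constant tiles 1 and 3 -> pseudobulk = mean
  sh <- suppressMessages(
    shapley_scores(m, x, rep("T", 3), seed = 1, n_iter = 5,
                   pseudobulk_size = 3, min_cells = 1, scaled = TRUE))
  expect_equal(sh$shapley, rep(0, 3))  # pseudobulk equals background mean

  # two cell types with different accessibility in tile 1
  x2 <- rbind(matrix(c(0.8, 0, 0.1), 4, 3, byrow = TRUE),
              matrix(c(0.3, 0, 0.1), 4, 3, byrow = TRUE))
  ct <- rep(c("hi", "lo"), each = 4)
  sh2 <- shapley_scores(m, x2, ct, seed = 1, n_iter = 10,
                        pseudobulk_size = 4, min_cells = 4, scaled = TRUE)
  hi1 <- sh2$shapley[sh2$cell_type == "hi" & sh2$tile == 1]
  expect_equal(hi1, 2 * (0.8 - 0.55))  # w = 2, pseudobulk 0.8, mean 0.55
  # zero-coefficient tiles always score zero
  expect_equal(sh2$shapley[sh2$tile == 2], rep(0, 2))
})

test_that("Shapley local accuracy and z-standardization hold exactly", {
  fitx <- small_fit()
  m <- fitx$m
  tr <- m$split$train_idx
  xs <- apply_scaler(m$scaler, fitx$x)[tr, ]
  ct <- fitx$sim$cells$cell_type[tr]
  sh <- shapley_scores(m, xs, ct, seed = 5, n_iter = 50, scaled = TRUE)

  for (type in unique(sh$cell_type)) {
    d <- sh[sh$cell_type == type, ]
    # z-scores standardized across tiles to numerical precision
    expect_lt(abs(mean(d$z)), 1e-10)
    expect_lt(abs(sd(d$z) - 1), 1e-10)
  }

  # local accuracy: with the pseudobulk forced to the full cell-type mean
  # (sample size = all cells of the type, without replacement), the score
  # total equals the linear-predictor gap between pseudobulk and background
  bg <- colMeans(xs)
  type_a <- which(ct == "A")
  sh_a <- suppressMessages(
    shapley_scores(m, xs, ct, seed = 2, n_iter = 3,
                   pseudobulk_size = length(type_a),
                   min_cells = length(type_a), scaled = TRUE))
  sh_a <- sh_a[sh_a$cell_type == "A", ]
  pb <- colMeans(xs[type_a, , drop = FALSE])
  expect_equal(sum(sh_a$shapley),
               sum(pb * m$w) - sum(bg * m$w), tolerance = 1e-10)

  # cell types under the threshold are skipped with a message
  expect_message(
    sh_skip <- shapley_scores(m, xs, ct, seed = 1, n_iter = 5,
                              min_cells = 1e5),
    "skipping")
  expect_equal(nrow(sh_skip), 0)
})

test_that("leave-one-tile-out significance flags planted tiles per cell type", {
  fitx <- small_fit()
  m <- fitx$m; sim <- fitx$sim
  te <- m$split$test_idx
  sig <- tile_significance(m, fitx$x[te, ], fitx$y[te],
                           sim$cells$cell_type[te])
  # w = 0 tiles get p = 1 by convention, for every cell type
  zero_tiles <- which(m$w == 0)
  expect_true(all(sig$p_value[sig$tile %in% zero_tiles] == 1))
  expect_equal(nrow(sig), m$n_tiles * 3)

  sig$q_value <- bh_fdr(sig$p_value)
  truth <- sim$truth$gene01$active_tiles
  expressing <- sim$truth$gene01$expressing_type
  p_expr <- sig$p_value[sig$tile %in% truth & sig$cell_type == expressing]
  q_other <- sig$q_value[sig$tile %in% truth & sig$cell_type != expressing]
  # planted tiles carry signal where the enhancer is active (the fixture
  # is small; the full-scale q < 0.001 behaviour is checked at the
  # 2,000-cell study conditions in the acceptance suite) ...
  expect_lt(median(p_expr), 0.01)
  # ... and none where it is closed
  expect_gt(min(q_other), 0.05)
})

test_that("gene-linked tile filtering applies all three thresholds", {
  sh <- tibble::tibble(gene_id = "g", cell_type = "T", tile = 1:4,
                       shapley = c(1, 1, 0.1, 1),
                       z = c(2, 0.4, 2, 2), n_cells = 100)
  sig <- tibble::tibble(gene_id = "g", cell_type = "T", tile = 1:4,
                        p_value = c(1e-9, 1e-9, 1e-9, 0.5),
                        q_value = c(1e-6, 1e-6, 1e-6, 0.6))
  res_ok <- tibble::tibble(gene_id = "g", test_spearman = 0.4)

  lt <- linked_tiles(sh, sig, res_ok)
  expect_setequal(lt$tile, c(1, 3))  # tile 2 fails z, tile 4 fails q
  expect_equal(lt$rank, seq_len(nrow(lt)))

  # a weakly predicted gene contributes nothing regardless of z
  res_low <- tibble::tibble(gene_id = "g", test_spearman = 0.05)
  expect_equal(nrow(linked_tiles(sh, sig, res_low)), 0)
})

test_that("dependent-correlation test matches an independent oracle", {
  # second, independently coded evaluation of the statistic
  oracle <- function(r12, r13, r23, n) {
    S <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
    tt <- (r12 - r13) * sqrt(
      ((n - 1) * (1 + r23)) /
        (2 * ((n - 1) / (n - 3)) * S + (r12 + r13)^2 / 4 * (1 - r23)^3))
    list(t = tt, p = 1 - pt(tt, n - 3))
  }
  res <- dependent_correlation_test(0.6, 0.4, 0.5, 100)
  orc <- oracle(0.6, 0.4, 0.5, 100)
  expect_equal(res$t_stat, orc$t)
  expect_equal(res$p_value, orc$p)
  expect_lt(res$p_value, 0.05)

  # equal correlations: t = 0, p = 0.5
  eq <- dependent_correlation_test(0.5, 0.5, 0.3, 50)
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_value, 0.5)

  # minimal n = 5: finite statistic, interior p
  tiny <- dependent_correlation_test(0.4, 0.1, 0.2, 5)
  orc5 <- oracle(0.4, 0.1, 0.2, 5)
  expect_equal(tiny$t_stat, orc5$t)
  expect_true(is.finite(tiny$t_stat))
  expect_true(tiny$p_value > 0 && tiny$p_value < 1)

  # antisymmetry in the two method-outcome correlations
  a <- dependent_correlation_test(0.7, 0.2, 0.4, 80)
  b <- dependent_correlation_test(0.2, 0.7, 0.4, 80)
  expect_equal(a$t_stat, -b$t_stat)

  # degenerate rho23 = 1 with unequal correlations
  dg <- dependent_correlation_test(0.6, 0.4, 1, 30)
  expect_equal(dg$p_value, 0)
  expect_error(dependent_correlation_test(0.5, 0.4, 0.3, 3), "n > 3")
})

test_that("compare_predictions wires the correlations into the test", {
  set.seed(21)
  obs <- rnorm(200)
  good <- obs + rnorm(200, sd = 0.4)
  bad <- obs + rnorm(200, sd = 3)
  cmp <- compare_predictions(good, bad, obs)
  expect_gt(cmp$rho12, cmp$rho13)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$n, 200)
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # monotone non-decreasing in sorted p order
  set.seed(22)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("paired signed-rank test matches exhaustive enumeration at n = 5", {
  a <- c(3.1, 2.0, 4.5, 1.2, 5.0)
  b <- c(2.5, 2.7, 3.0, 1.1, 4.2)  # distinct |differences|: exact branch
  d <- a - b
  # brute force: distribution of W+ over all 2^5 sign assignments
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  wall <- signs %*% r
  p_two <- mean(wall >= wobs) + mean(wall <= sum(r) - wobs)
  expect_equal(paired_signed_rank(a, b), min(1, p_two))
  p_greater <- mean(wall >= wobs)
  expect_equal(paired_signed_rank(a, b, "greater"), p_greater)

  expect_equal(paired_signed_rank(1:4, 1:4), 1)  # all ties dropped

  # large-sample branch against the normal approximation formula
  set.seed(23)
  x <- rnorm(40) + 0.8
  y <- rnorm(40)
  d2 <- x - y
  r2 <- rank(abs(d2))
  w <- sum(r2[d2 > 0])
  n <- length(d2)
  mu <- n * (n + 1) / 4
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  p_ref <- pnorm((w - mu - 0.5) / sig, lower.tail = FALSE)
  expect_equal(paired_signed_rank(x, y, "greater"), p_ref, tolerance = 1e-6)
})

test_that("interaction-score comparison matches accessibility and uses the max rule", {
  set.seed(24)
  n <- 60
  base <- tibble::tibble(
    gene_id = "g", cell_type = "T", tile = 1:n,
    shapley = rnorm(n), z = rnorm(n), n_cells = 200)
  acc <- tibble::tibble(gene_id = "g", tile = 1:n,
                        accessibility = runif(n, 1, 2))

  # identical score distributions: no signal
  int_null <- tibble::tibble(gene_id = "g", interaction_id = paste0("i", 1:20),
                             tile = 1:20)
  p_null <- interaction_score_comparison(base, int_null, acc, seed = 1)$p_value
  expect_gt(p_null, 0.05)

  # interacting tiles shifted upward: strong signal
  shifted <- base
  shifted$z[1:20] <- shifted$z[1:20] + 3
  p_shift <- interaction_score_comparison(shifted, int_null, acc,
                                          seed = 1)$p_value
  expect_lt(p_shift, 0.01)

  # multi-tile interaction is represented by its maximum score
  two_tile <- base
  two_tile$z <- rep(0.5, n)
  two_tile$z[1] <- 0.2; two_tile$z[2] <- 0.9
  acc_flat <- tibble::tibble(gene_id = "g", tile = 1:n, accessibility = 1.5)
  int_span <- tibble::tibble(gene_id = "g", interaction_id = "i1",
                             tile = c(1, 2))
  res <- interaction_score_comparison(two_tile, int_span, acc_flat,
                                      reference_accessibility = rep(1, 10),
                                      seed = 2)
  # one interaction with representative score 0.9 against background 0.5s:
  # the one-sided Mann-Whitney p-value for a single larger observation
  m_bg <- res$n_background
  expect_equal(res$p_value,
               suppressWarnings(
                 wilcox.test(0.9, rep(0.5, m_bg),
                             alternative = "greater")$p.value))
})
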
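test_that("LSI embedding is deterministic and separates populations", {
  set.seed(41)
  lam1 <- rep(c(8, 0.1), each = 5)   # population 1 open on features 1-5
  lam2 <- rep(c(0.1, 8), each = 5)   # population 2 open on features 6-10
  counts <- rbind(
    t(replicate(20, rpois(10, lam1))),
    t(replicate(20, rpois(10, lam2))))
  counts <- counts[, colSums(counts) > 0]
  emb <- lsi_embedding(counts, n_dims = 3)
  expect_identical(emb, lsi_embedding(counts, n_dims = 3))
  # the two planted populations separate along the leading components
  grp <- rep(c(1, 2), each = 20)
  gap <- abs(mean(emb[grp == 1, 1]) - mean(emb[grp == 2, 1])) +
    abs(mean(emb[grp == 1, 2]) - mean(emb[grp == 2, 2]))
  spread <- sd(emb[grp == 1, 1]) + sd(emb[grp == 2, 1]) + 1e-9
  expect_gt(gap / spread, 2)

  # identical cells map to identical rows
  same <- matrix(rep(c(3, 1, 0, 2), 5), 5, 4, byrow = TRUE)
  emb_same <- suppressWarnings(lsi_embedding(same, n_dims = 2))
  expect_lt(max(abs(sweep(emb_same, 2, emb_same[1, ]))), 1e-10)
  expect_warning(lsi_embedding(counts, n_dims = 100), "reduced")
  expect_error(lsi_embedding(-counts, 2), "non-negative")
})

test_that("kNN smoothing averages neighbourhoods with self inclusion", {
  set.seed(42)
  expr <- matrix(rnorm(100), 20, 5)
  emb <- matrix(rnorm(40), 20, 2)
  expect_equal(knn_smooth(expr, emb, k = 1), expr)        # self only
  allk <- knn_smooth(expr, emb, k = 20)
  expect_equal(allk, matrix(colMeans(expr), 20, 5, byrow = TRUE))
  expect_warning(knn_smooth(expr, emb, k = 50), "clamped")
  # smoothing cannot inflate per-gene variance
  sm <- knn_smooth(expr, emb, k = 5)
  expect_true(all(apply(sm, 2, var) <= apply(expr, 2, var) + 1e-12))
  # coincident cells all smooth to the global mean
  emb0 <- matrix(0, 20, 2)
  expect_equal(knn_smooth(expr, emb0, k = 20),
               matrix(colMeans(expr), 20, 5, byrow = TRUE))
})

test_that("gene filtering keeps strictly positive predicted/observed correlation", {
  set.seed(43)
  obs <- matrix(rnorm(300), 100, 3,
                dimnames = list(NULL, c("pos", "neg", "flat")))
  pred <- obs
  pred[, "neg"] <- -obs[, "neg"] + rnorm(100, sd = 0.1)
  pred[, "flat"] <- 0
  keep <- filter_genes_by_correlation(pred, obs)
  expect_equal(keep, "pos")  # negative dropped; exactly-zero rho dropped
})

test_that("potential arrows point at correlation-matched target cells", {
  set.seed(44)
  n <- 30
  prof <- matrix(rnorm(n * 8), n, 8)  # distinct profiles
  layout <- cbind(runif(n), runif(n))
  # pred == obs with k = 1: every cell matches itself, arrows vanish
  f1 <- potential_vectors(prof, prof, layout, k_target = 1)
  expect_equal(f1$dx, rep(0, n))
  expect_equal(f1$dy, rep(0, n))
  # k = n: every arrow points at the global centroid
  fn <- potential_vectors(prof, prof, layout, k_target = n)
  expect_equal(fn$dx, rep(mean(layout[, 1]), n) - layout[, 1])
  expect_equal(fn$dy, rep(mean(layout[, 2]), n) - layout[, 2])
  # permutation equivariance
  perm <- sample(n)
  fp <- potential_vectors(prof[perm, ], prof[perm, ], layout[perm, ],
                          k_target = 5)
  f5 <- potential_vectors(prof, prof, layout, k_target = 5)
  expect_equal(fp$dx, f5$dx[perm])
  expect_equal(fp$dy, f5$dy[perm])
  # degenerate (constant) predicted vector: zero arrow, flagged
  prof0 <- prof; prof0[3, ] <- 0
  # constant after scaling happens when the raw row is constant
  f0 <- potential_vectors(matrix(1, n, 8), prof, layout, k_target = 3,
                          scaled = TRUE)
  expect_true(all(f0$degenerate))
  expect_equal(f0$dx, rep(0, n))
})

test_that("grid smoothing equals the per-bin average", {
  field <- structure(
    tibble::tibble(cell = as.character(1:4),
                   x = c(0.1, 0.9, 0.1, 0.9), y = c(0.1, 0.1, 0.9, 0.9),
                   dx = c(1, 2, 3, -3), dy = c(0, 1, 1, -1),
                   degenerate = FALSE),
    class = c("potential_field", class(tibble::tibble())))
  g <- grid_smooth(field, grid_size = 2)
  expect_equal(nrow(g), 4)        # one occupied cell each
  expect_equal(sort(g$dx), sort(field$dx))

  # opposite arrows in a shared cell cancel
  field2 <- field
  field2$x <- c(0.1, 0.15, 0.9, 0.9); field2$dx <- c(1, -1, 2, 2)
  field2$dy <- c(0.5, -0.5, 0, 0)
  g2 <- grid_smooth(field2, grid_size = 2)
  cell_low <- g2[g2$grid_x < 0.5 & g2$grid_y < 0.5, ]
  expect_equal(cell_low$dx, 0)
  expect_equal(cell_low$dy, 0)
  expect_equal(cell_low$n_cells, 2L)

  # brute-force bin-average oracle on random fields
  set.seed(45)
  fr <- structure(
    tibble::tibble(cell = as.character(1:200), x = runif(200), y = runif(200),
                   dx = rnorm(200), dy = rnorm(200), degenerate = FALSE),
    class = c("potential_field", class(tibble::tibble())))
  gs <- 5
  g3 <- grid_smooth(fr, grid_size = gs)
  bx <- pmin(1L + as.integer((fr$x - min(fr$x)) / diff(range(fr$x)) * gs), gs)
  by <- pmin(1L + as.integer((fr$y - min(fr$y)) / diff(range(fr$y)) * gs), gs)
  orc <- tapply(fr$dx, list(bx, by), mean)
  for (i in seq_len(nrow(g3))) {
    obx <- 1L + as.integer((g3$grid_x[i] - min(fr$x)) / diff(range(fr$x)) * gs - 0.5)
    oby <- 1L + as.integer((g3$grid_y[i] - min(fr$y)) / diff(range(fr$y)) * gs - 0.5)
    expect_equal(g3$dx[i], orc[as.character(obx), as.character(oby)])
  }
})

test_that("cosine comparison handles aligned, opposed and zero arrows", {
  f <- structure(
    tibble::tibble(cell = as.character(1:3), x = 0, y = 0,
                   dx = c(1, 0, 0), dy = c(0, 2, 0), degenerate = FALSE,
                   cell_type = c("a", "a", "b")),
    class = c("potential_field", class(tibble::tibble())))
  same <- cosine_compare(f, f)
  expect_equal(same$cells$cosine[1:2], c(1, 1))
  expect_true(same$cells$undefined[3])
  neg <- f; neg$dx <- -neg$dx; neg$dy <- -neg$dy
  expect_equal(cosine_compare(f, neg)$cells$cosine[1:2], c(-1, -1))
  orth <- f; orth$dx <- c(0, 2, 0); orth$dy <- c(1, 0, 0)
  expect_equal(cosine_compare(f, orth)$cells$cosine[1:2], c(0, 0))
  expect_equal(same$by_cell_type$n, c(2L, 1L))
})

test_that("a planted lead-lag trajectory yields forward-pointing arrows", {
  tr <- simulate_trajectory(n_cells = 400, delta = 0.15, seed = 46)
  emb <- lsi_embedding(tr$atac, n_dims = 10)
  f <- chromatin_potential(tr$pred, tr$obs, emb, tr$layout,
                           cell_types = tr$cell_types)
  cosine <- (f$dx * tr$true_direction[, 1] + f$dy * tr$true_direction[, 2]) /
    sqrt(f$dx^2 + f$dy^2)
  expect_gt(mean(cosine, na.rm = TRUE), 0.5)
  expect_gt(length(attr(f, "genes_used")), 30)

  # no planted lead: arrows carry no forward signal
  tr0 <- simulate_trajectory(n_cells = 400, delta = 0, seed = 46)
  f0 <- chromatin_potential(tr0$pred, tr0$obs, emb, tr0$layout)
  cos0 <- (f0$dx * tr0$true_direction[, 1] + f0$dy * tr0$true_direction[, 2]) /
    sqrt(f0$dx^2 + f0$dy^2)
  expect_lt(abs(mean(cos0, na.rm = TRUE)), 0.25)
})
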
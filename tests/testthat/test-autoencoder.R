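small_stack <- function(n = 60, p_block = 20, seed = 1, effect = 1.5) {
  ds <- generate_dataset(synth_config(
    n_samples = n,
    omics_blocks = default_omics_blocks(n_features = p_block,
                                        n_informative = 4,
                                        effect_size = effect),
    seed = seed))
  list(stack = preprocess_blocks(ds$omics), ds = ds)
}

test_that("initialization chains layer dimensions and is seeded", {
  cfg <- ae_config(bottleneck = 150)
  m <- init_autoencoder(1000, cfg)
  expect_equal(vapply(m$W, dim, integer(2)),
               matrix(c(1000, 500, 500, 150, 150, 500, 500, 1000), nrow = 2))
  expect_equal(lengths(m$b), c(500, 150, 500, 1000))
  expect_length(m$history, 0)

  m2 <- init_autoencoder(1000, cfg)
  expect_identical(m$W, m2$W)
  expect_error(init_autoencoder(0, cfg), "positive integer")
  expect_warning(init_autoencoder(3, ae_config(bottleneck = 5,
                                               hidden_sizes = c(4, 5, 4))),
                 "over-complete")
})

test_that("the penalized objective matches an independent transcription", {
  set.seed(42)
  m <- tiny_ae()
  X <- matrix(runif(3 * 5), 3, 5,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:5)))
  pen_cases <- list(c(0, 0, 0), c(0.001, 0, 1e-4), c(0.01, 0.02, 1e-3))
  for (p in pen_cases) {
    cfg <- ae_config(bottleneck = 2, hidden_sizes = c(4, 2, 4),
                     l1_override = p[1], l2_override = p[2], alpha_a = p[3])
    m$config <- cfg
    expect_equal(ae_loss(m, X),
                 oracle_ae_loss(m$W, m$b, X, p[1], p[2], p[3]),
                 tolerance = 1e-10)
  }
  expect_error(ae_loss(m, X - 2), "must lie in \\[0, 1\\]")
})

test_that("a saturating reconstruction of binary input drives the loss to ~0", {
  # sigmoid output can only approach 0/1; with alpha_w = alpha_a = 0 the
  # clipped cross-entropy of a near-perfect reconstruction is ~1e-6
  X <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("f1", "f2")))
  cfg <- ae_config(bottleneck = 2, hidden_sizes = c(2, 2, 2),
                   alpha_w = 0, alpha_a = 0, l1_override = 0, l2_override = 0)
  m <- suppressWarnings(init_autoencoder(2, cfg))  # deliberately over-complete
  for (i in 1:4) { m$W[[i]][] <- 0; m$b[[i]][] <- 0 }
  # route each input through a dedicated saturated unit
  m$W[[1]] <- diag(50, 2); m$W[[2]] <- diag(50, 2)
  m$W[[3]] <- diag(50, 2); m$W[[4]] <- diag(80, 2); m$b[[4]][] <- -40
  expect_equal(reconstruct(m, X), X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(ae_loss(m, X), 1e-4)
})

test_that("backpropagation matches finite differences of the objective", {
  set.seed(7)
  cfg <- ae_config(bottleneck = 2, hidden_sizes = c(4, 2, 4),
                   l1_override = 0.01, l2_override = 0.005, alpha_a = 1e-3)
  m <- init_autoencoder(5, cfg)
  X <- matrix(runif(15), 3, 5,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:5)))
  gr <- aesubtype:::cpp_ae_grad(m$W, m$b, X, 0.01, 0.005, 1e-3)
  h <- 1e-6
  for (i in 1:4) {
    for (idx in list(c(1, 1), c(2, 2))) {
      mp <- m; mp$W[[i]][idx[1], idx[2]] <- mp$W[[i]][idx[1], idx[2]] + h
      mm <- m; mm$W[[i]][idx[1], idx[2]] <- mm$W[[i]][idx[1], idx[2]] - h
      num <- (ae_loss(mp, X) - ae_loss(mm, X)) / (2 * h)
      expect_equal(gr$dW[[i]][idx[1], idx[2]], num, tolerance = 1e-4,
                   label = sprintf("dW[[%d]][%d,%d]", i, idx[1], idx[2]))
    }
    mp <- m; mp$b[[i]][1] <- mp$b[[i]][1] + h
    mm <- m; mm$b[[i]][1] <- mm$b[[i]][1] - h
    num <- (ae_loss(mp, X) - ae_loss(mm, X)) / (2 * h)
    expect_equal(gr$db[[i]][1], num, tolerance = 1e-4,
                 label = sprintf("db[[%d]]", i))
  }
})

test_that("training is a seeded no-op at 0 epochs and reduces the loss otherwise", {
  ss <- small_stack()
  cfg0 <- ae_config(bottleneck = 10, hidden_sizes = c(40, 10, 40), epochs = 0,
                    seed = 3)
  m0 <- init_autoencoder(100, cfg0)
  expect_identical(train_autoencoder(m0, ss$stack), m0)

  cfg <- ae_config(bottleneck = 10, hidden_sizes = c(40, 10, 40), epochs = 10,
                   batch_size = 16, seed = 3)
  m <- train_autoencoder(init_autoencoder(100, cfg), ss$stack)
  expect_length(m$history, 10)
  expect_lt(m$history[10], m$history[1])
  expect_lt(ae_loss(m, ss$stack),
            ae_loss(init_autoencoder(100, cfg), ss$stack))

  m2 <- train_autoencoder(init_autoencoder(100, cfg), ss$stack)
  expect_identical(m$W, m2$W)
  expect_identical(m$b, m2$b)
})

test_that("encode yields the bottleneck and reconstruct the input shape", {
  ss <- small_stack()
  cfg <- ae_config(bottleneck = 10, hidden_sizes = c(40, 10, 40), epochs = 2,
                   batch_size = 16, seed = 4)
  m <- train_autoencoder(init_autoencoder(100, cfg), ss$stack)
  F <- encode(m, ss$stack)
  expect_equal(dim(F), c(60, 10))
  expect_identical(rownames(F), rownames(ss$stack$values))
  expect_true(all(abs(F) <= 1))
  expect_identical(F, encode(m, ss$stack))
  expect_equal(dim(reconstruct(m, ss$stack)), dim(ss$stack$values))

  mz <- init_autoencoder(100, cfg)
  for (i in 1:4) { mz$W[[i]][] <- 0; mz$b[[i]][] <- 0 }
  expect_true(all(encode(mz, ss$stack) == 0))
})

test_that("rmse is the root mean squared residual, zero for a fixed point", {
  X <- matrix(0.5, 4, 3, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  cfg <- ae_config(bottleneck = 2, hidden_sizes = c(3, 2, 3))
  mz <- init_autoencoder(3, cfg)
  for (i in 1:4) { mz$W[[i]][] <- 0; mz$b[[i]][] <- 0 }
  expect_equal(reconstruction_rmse(mz, X), 0)

  set.seed(9)
  m <- tiny_ae(3, c(3, 2, 3), seed = 9)
  Xr <- matrix(runif(12), 4, 3,
               dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  rec <- reconstruct(m, Xr)
  direct <- 0
  for (i in 1:4) for (j in 1:3) direct <- direct + (Xr[i, j] - rec[i, j])^2
  expect_equal(reconstruction_rmse(m, Xr), sqrt(direct / 12), tolerance = 1e-12)
})

test_that("the canonical grid carries the eight bottlenecks and overrides", {
  grid <- default_ae_grid()
  expect_length(grid, 8)
  expect_equal(vapply(grid, function(g) g$hidden_sizes[2], integer(1)),
               stats::setNames(c(50L, 100L, 150L, 200L, 250L, 300L, 400L, 500L),
                               sprintf("model_%d", 1:8)))
  expect_equal(grid$model_3$l1_override, 0.001)
  expect_equal(grid$model_3$l2_override, 0)
  expect_true(all(vapply(grid, function(g) g$epochs, integer(1)) == 10L))
})

test_that("run_model_grid trains per config and reports the grid schema", {
  ss <- small_stack()
  grid <- list(
    a = ae_config(bottleneck = 5, hidden_sizes = c(30, 5, 30), epochs = 2,
                  batch_size = 16, seed = 5),
    b = ae_config(bottleneck = 8, hidden_sizes = c(30, 8, 30), epochs = 2,
                  batch_size = 16, l1_override = 0.001, l2_override = 0,
                  seed = 6))
  gr <- run_model_grid(ss$stack, grid)
  expect_named(gr$models, c("a", "b"))
  expect_equal(ncol(gr$features$a), 5)
  expect_equal(nrow(gr$report), 2)
  expect_identical(names(gr$report),
                   c("ae_models", "hidden", "epochs", "activation",
                     "hidden_dropout_ratios", "l1", "l2", "model_ids",
                     "rmse", "deep_features", "mean c-index/SD"))
  expect_equal(gr$report$l1[2], 0.001)
  expect_equal(gr$report$l2[2], 0)
  expect_true(all(gr$report$rmse > 0))

  one <- run_model_grid(ss$stack, grid[1])
  expect_equal(nrow(one$report), 1)
  expect_error(run_model_grid(ss$stack, list()), "empty model grid")
})

test_that("training beats a column-permuted baseline in reconstruction", {
  ss <- small_stack(seed = 8)
  cfg <- ae_config(bottleneck = 10, hidden_sizes = c(40, 10, 40), epochs = 10,
                   batch_size = 16, seed = 8)
  m <- train_autoencoder(init_autoencoder(100, cfg), ss$stack)
  V <- ss$stack$values
  Vperm <- withr::with_seed(8, apply(V, 2, sample))
  dimnames(Vperm) <- dimnames(V)
  expect_lt(reconstruction_rmse(m, V), reconstruction_rmse(m, Vperm))
})
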
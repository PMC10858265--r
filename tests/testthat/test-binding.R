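test_that("k-mer feature blocks follow the printed column-count formulas", {
  set.seed(111)
  recs <- data.frame(
    seq = vapply(1:12, function(i)
      paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = ""), ""),
    affinity = runif(12, 0.1, 1))
  X1 <- encode_feature_matrix(recs, binding_feature_config(kmer_orders = 1L))
  expect_equal(ncol(X1), 4L * 16L)
  X2 <- encode_feature_matrix(recs, binding_feature_config(kmer_orders = 2L))
  expect_equal(ncol(X2), 16L * 15L)
  X3 <- encode_feature_matrix(recs, binding_feature_config(kmer_orders = 3L))
  expect_equal(ncol(X3), 64L * 14L)
  # indicator structure: one 1 per record per position block
  expect_true(all(rowSums(X1) == 16L))
  expect_true(all(X1 %in% c(0, 1)))
  expect_identical(unname(X1[1L, paste0("1mer_p1_", substr(recs$seq[1L], 1, 1))]), 1)

  pred <- truth_pred_13()
  X <- encode_feature_matrix(recs,
                             binding_feature_config(kmer_orders = 1L,
                                                    shape_preset = "13shape"),
                             pred)
  expect_equal(ncol(X), 64L + 7L * 16L + 6L * 15L)   # 1mers + bp + step blocks
  shape_cols <- X[, -(1:64), drop = FALSE]
  expect_gte(min(shape_cols), 0)
  expect_lte(max(shape_cols), 1)

  expect_error(encode_feature_matrix(recs,
                                     binding_feature_config(shape_preset = "13shape")),
               "no predictor")
  expect_error(binding_feature_config(kmer_orders = integer(0)),
               "at least one")
  expect_error(binding_feature_config(kmer_orders = 4L), "within 1..3")
})

test_that("ridge at vanishing lambda matches ordinary least squares", {
  set.seed(121)
  X <- matrix(rnorm(50 * 5), 50, 5)
  beta <- c(2, -1, 0.5, 0, 3)
  y <- drop(X %*% beta) + 1.5
  fit <- deepshape:::ridge_solve(X, y, 1e-10)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(fit$intercept, unname(ols[1L]), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(ols[-1L]), tolerance = 1e-6)
})

test_that("nested CV recovers noiseless linear signal and rejects permuted labels", {
  set.seed(131)
  X <- matrix(rnorm(120 * 8), 120, 8)
  y <- drop(X %*% rnorm(8)) + 0.3
  fit <- bind_ridge(X, y, seed = 1L)
  expect_gte(fit$r2, 0.999)
  # out-of-fold coverage is a partition
  expect_length(fit$fold, 120L)
  expect_setequal(unique(fit$fold), 1:10)
  expect_true(all(table(fit$fold) >= 1L))
  expect_true(all(is.finite(fit$oof)))
  expect_identical(bind_ridge(X, y, seed = 1L)$oof, fit$oof)

  yperm <- sample(y)
  expect_lte(bind_ridge(X, yperm, seed = 2L)$r2, 0.05)

  expect_error(bind_ridge(X[1:10, ], y[1:10]), "at least 20")
  expect_error(bind_ridge(X, replace(y, 1L, NA)), "non-finite")
  expect_error(bind_ridge(matrix(1, 30, 2), rnorm(30)), "rank 0")
})

test_that("shape features add information beyond 1-mers when affinity reads shape", {
  pred <- truth_pred_13()
  bind <- simulate_binding_data(pred, c("Roll", "HelT", "MGW"), n = 150L,
                                len = 12L, seed = 7L)
  y <- log(bind$affinity)
  cfg1 <- binding_feature_config(kmer_orders = 1L)
  cfgS <- binding_feature_config(kmer_orders = 1L, shape_preset = "13shape")
  X1 <- encode_feature_matrix(bind, cfg1)
  XS <- encode_feature_matrix(bind, cfgS, pred)
  r1 <- bind_ridge(X1, y, seed = 3L)$r2
  rS <- bind_ridge(XS, y, seed = 3L)$r2
  expect_gt(rS, r1)
})

test_that("binding tables read, validate, and round-trip", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\taffinity", "ACGTACGT\t0.9", "TTGCACGA\t0.25"), path)
  b <- read_binding_table(path)
  expect_equal(nrow(b), 2L)
  expect_equal(b$affinity, c(0.9, 0.25))
  writeLines(c("ACGT\t1.0", "ACGTA\t0.5"), path)
  expect_error(read_binding_table(path), "aligned length")
  writeLines(c("ACGT\t1.0", "ACGA\t-0.5"), path)
  expect_error(read_binding_table(path), "positive")
})

test_that("profile aggregation keeps the top fraction sorted by affinity", {
  pred <- truth_pred_13()
  set.seed(141)
  recs <- data.frame(
    seq = vapply(1:100, function(i)
      paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""), ""),
    affinity = runif(100, 0.01, 1))
  m <- aggregate_profiles(recs, pred, "MGW")
  expect_equal(nrow(m), 25L)
  expect_equal(ncol(m), 10L)
  aff <- attr(m, "affinity")
  expect_equal(aff[1L], max(recs$affinity))
  expect_true(all(diff(aff) <= 0))
  expect_equal(nrow(aggregate_profiles(recs, pred, "MGW", top_fraction = 1)),
               100L)
  mb <- aggregate_profiles(recs, pred, "Roll", n_bins = 5L)
  expect_equal(dim(attr(mb, "bin_means")), c(5L, 9L))
  expect_error(aggregate_profiles(recs[0, ], pred, "MGW"), "aligned|empty")
})

test_that("cap scans enumerate small cores and mirror under rc-closed ensembles", {
  net <- make_small_net("MGW", layers = 2L, filter = 8L, seed = 25L)
  pred <- shapenet_set(list(MGW = net), depth = 2L, symmetrize = TRUE)
  sc <- cap_scan("AAA", "TTT", 3L, pred, "MGW")
  expect_equal(attr(sc, "n_sequences"), 64L)
  expect_equal(nrow(sc), 9L)
  # the ensemble is closed under reverse complement and MGW is rc-invariant,
  # so summary statistics at mirrored positions coincide
  for (p in 1:4) {
    expect_equal(sc$median[p], sc$median[10L - p], tolerance = 1e-9)
    expect_equal(sc$q1[p], sc$q1[10L - p], tolerance = 1e-9)
    expect_equal(sc$q3[p], sc$q3[10L - p], tolerance = 1e-9)
  }
  expect_true(all(sc$whisker_lo <= sc$q1 & sc$q3 <= sc$whisker_hi))

  # seeded sampling path is reproducible
  tp <- truth_pred_13()
  s1 <- cap_scan("AAAA", "AAAA", 9L, tp, "MGW", sample_size = 40L, seed = 5L)
  s2 <- cap_scan("AAAA", "AAAA", 9L, tp, "MGW", sample_size = 40L, seed = 5L)
  expect_identical(s1, s2)
  expect_error(cap_scan("AA", "AA", 0L, tp, "MGW"), "core_length")
})

test_that("binding simulations are seed-stable with controllable noise", {
  pred <- truth_pred_13()
  b1 <- simulate_binding_data(pred, "MGW", n = 30L, len = 10L, seed = 9L)
  b2 <- simulate_binding_data(pred, "MGW", n = 30L, len = 10L, seed = 9L)
  expect_identical(b1, b2)
  expect_true(all(b1$affinity > 0))
  expect_equal(log(b1$affinity), attr(b1, "log_affinity"), tolerance = 1e-12)
})
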
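test_that("table construction matches a brute-force dictionary oracle exactly", {
  for (seed in 1:5) {
    ds <- random_dataset(seed)
    for (k in c(3L, 5L)) {
      tab <- kmer_table(ds, k = k)
      ora <- oracle_kmer_table(ds, k)
      expect_identical(tab$kmers, ora$kmers)
      expect_identical(tab$counts, ora$counts)
      expect_equal(tab$means, ora$means, tolerance = 1e-15)
    }
  }
})

test_that("table means, coverage holes and min_count behave as documented", {
  recs <- list(list(id = "a", seq = "AAAAA", values = c(1, 1, 3.0, 1, 1)),
               list(id = "b", seq = "AAAAA", values = c(1, 1, 3.0, 1, 1)),
               list(id = "c", seq = "AAAAA", values = c(1, 1, 5.0, 1, 1)))
  ds <- deepshape:::new_shape_dataset(recs)
  tab <- kmer_table(ds, k = 5L)
  expect_identical(tab$kmers, "AAAAA")
  expect_equal(tab$means, 11 / 3)
  expect_identical(tab$counts, 3L)

  big <- random_dataset(99, n_seqs = 30L, lens = 10:16, mask_p = 0)
  t7 <- kmer_table(big, k = 7L)
  expect_lt(length(t7$kmers), 4L^7L)        # heptamers cannot be covered

  t3 <- kmer_table(big, k = 3L)
  t3min <- kmer_table(big, k = 3L, min_count = 5L)
  expect_true(all(t3min$counts >= 5L))
  expect_lt(length(t3min$kmers), length(t3$kmers))

  expect_error(kmer_table(ds, k = 4L), "odd")
  expect_error(kmer_table(ds, k = 7L), "exceeds")
})

test_that("sliding prediction defines exactly the admissible centres", {
  ds <- random_dataset(7, mask_p = 0)
  tab <- kmer_table(ds, k = 5L)
  s10 <- "ACGTACGTAC"
  p <- predict(tab, s10)
  expect_length(p, 10L)
  expect_true(all(is.na(p[c(1, 2, 9, 10)])))

  # a sequence containing one table key: value equals the direct lookup
  km <- tab$kmers[1L]
  p2 <- predict(tab, km)
  expect_equal(p2[3L], tab$means[1L])
  # absent window stays NA
  empty_tab <- kmer_table(ds, k = 5L, min_count = 10000L)
  expect_true(all(is.na(predict(empty_tab, s10))))
  expect_error(predict(tab, "ACG"), "shorter")
})

test_that("per-step tables centre on the documented step and round-trip on files", {
  set.seed(3)
  recs <- lapply(1:8, function(i) {
    len <- sample(8:12, 1L)
    list(id = paste0("s", i),
         seq = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""),
         values = rnorm(len - 1L))
  })
  ds <- deepshape:::new_shape_dataset(recs)
  expect_equal(ds$node_kind, "step")
  tab <- kmer_table(ds, k = 5L, feature = "Roll")
  ora <- oracle_kmer_table(ds, 5L)
  expect_identical(tab$kmers, ora$kmers)
  expect_equal(tab$means, ora$means, tolerance = 1e-15)

  path <- tempfile(fileext = ".tsv")
  write_kmer_table(tab, path)
  back <- read_kmer_table(path)
  expect_identical(back$kmers, tab$kmers)
  expect_identical(back$means, tab$means)    # bit-exact decimal round trip
  expect_identical(back$counts, tab$counts)
  expect_identical(back$node_kind, "step")
  expect_identical(back$feature, "Roll")
  expect_identical(back$k, 5L)
})

test_that("a pentamer table is exact when the truth is pentamer-local", {
  gtm <- make_ground_truth(seed = 81L, R = 2L, node_kind = "bp",
                           terminal_mask_margin = 0L)
  corpus <- sample_corpus(gtm, n_seqs = 400L, length_range = c(12L, 16L),
                          seed = 82L, noiseless = TRUE)
  tab <- kmer_table(corpus_dataset(corpus), k = 5L)
  ev <- sample_corpus(gtm, n_seqs = 30L, length_range = c(12L, 16L),
                      seed = 83L, noiseless = TRUE)
  err <- 0; npos <- 0L
  for (r in ev$records) {
    p <- predict(tab, r$seq)
    ok <- is.finite(p) & is.finite(r$true_values)
    err <- err + sum(abs(p[ok] - r$true_values[ok]))
    npos <- npos + sum(ok)
  }
  expect_gt(npos, 100L)
  expect_lt(err / npos, 1e-12)
})

test_that("flank bias scores range from 0 (uniform contexts) to 15/16 (point mass)", {
  gtm <- make_ground_truth(seed = 91L, R = 1L, node_kind = "bp")
  uni <- sample_corpus(gtm, n_seqs = 1500L, length_range = c(15L, 20L),
                       seed = 92L)
  rep_uni <- flank_bias_report(corpus_dataset(uni), k = 3L)
  common <- rep_uni[rep_uni$n_contexts >= 250L, ]
  expect_gt(nrow(common), 10L)
  expect_true(all(common$bias_score < 0.2))

  forced <- sample_corpus(gtm, n_seqs = 120L, length_range = c(15L, 20L),
                          seed = 93L,
                          context = list(kmer = "ACGTA", context = "CACGTAG"))
  rep_f <- flank_bias_report(corpus_dataset(forced), k = 5L)
  row <- rep_f[rep_f$kmer == "ACGTA", ]
  expect_equal(row$bias_score, 15 / 16)
  ctx <- attr(rep_f, "context_counts")[["ACGTA"]]
  expect_equal(sum(ctx > 0), 1L)
  expect_gt(ctx[["CG"]], 0L)

  # windows at sequence ends contribute no context
  tiny <- deepshape:::new_shape_dataset(list(
    list(id = "t", seq = "ACGTA", values = rnorm(5))))
  expect_equal(nrow(flank_bias_report(tiny, k = 5L)), 0L)
})

test_that("method comparison restricts to jointly defined positions", {
  res <- recovery_experiment(recovery_seeds[1L])
  gtm <- res$gtm
  ev <- sample_corpus(gtm, n_seqs = 40L, length_range = c(15L, 20L),
                      seed = 7L)
  cm <- compare_methods(corpus_truth_dataset(ev), res$fit, res$table,
                        depth = 4L)
  expect_named(cm, c("net", "table"))
  expect_gt(attr(cm, "n_positions"), 0L)
  expect_true(all(is.finite(cm)))
})

test_that("reverse-complement merging pools strand-equivalent windows", {
  recs <- list(list(id = "a", seq = "AAAAA", values = c(9, 9, 1, 9, 9)),
               list(id = "b", seq = "TTTTT", values = c(9, 9, 3, 9, 9)))
  ds <- deepshape:::new_shape_dataset(recs)
  plain <- kmer_table(ds, k = 5L)
  expect_setequal(plain$kmers, c("AAAAA", "TTTTT"))

  inv <- kmer_table(ds, k = 5L, feature = "MGW", merge_rc = TRUE)
  expect_identical(inv$kmers, "AAAAA")
  expect_equal(inv$means, 2)              # invariant: (1 + 3) / 2
  expect_identical(inv$counts, 2L)

  flip <- kmer_table(ds, k = 5L, feature = "Shear", merge_rc = TRUE)
  expect_equal(flip$means, -1)            # sign-flip: (1 - 3) / 2
  # lookups from either strand resolve to the merged entry
  expect_equal(predict(inv, "TTTTT")[3L], 2)
})
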
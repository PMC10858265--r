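test_that("ground-truth tables obey the decay law and are seed-reproducible", {
  g0 <- make_ground_truth(seed = 1L, R = 3L, gamma = 0)
  expect_true(all(g0$contribution_table[2:3, , ] == 0))
  expect_false(all(g0$contribution_table[1L, , ] == 0))

  g1 <- make_ground_truth(seed = 5L, R = 4L, gamma = 0.6)
  g2 <- make_ground_truth(seed = 5L, R = 4L, gamma = 0.6)
  expect_identical(g1, g2)
  g3 <- make_ground_truth(seed = 6L, R = 4L, gamma = 0.6)
  expect_false(identical(g1$center_table, g3$center_table))

  # contributions shrink geometrically by construction
  gg <- make_ground_truth(seed = 9L, R = 4L, gamma = 0.3, contrib_sd = 1)
  mx <- apply(abs(gg$contribution_table), 1L, max)
  for (d in 2:4) expect_lte(mx[d], max(mx) * 0.3^(d - 1) / 0.3^0 + 1e-12)

  expect_error(make_ground_truth(R = 9L), "R must be")
  expect_error(make_ground_truth(gamma = 1), "gamma")
})

test_that("noiseless profiles are additive, local, and match exhaustive enumeration", {
  gtm <- make_ground_truth(seed = 11L, R = 2L, node_kind = "bp",
                           terminal_mask_margin = 0L)
  # poly-A interior values are constant (translation invariance)
  v <- true_shape(strrep("A", 20L), gtm)
  expect_true(all(abs(v[3:18] - v[3L]) < 1e-14))

  # an edit beyond the radius leaves a position unchanged
  s1 <- "ACGTACGTACGTACG"
  s2 <- paste0(substr(s1, 1, 10), "T", substr(s1, 12, 15))  # edit position 11
  v1 <- true_shape(s1, gtm)
  v2 <- true_shape(s2, gtm)
  expect_identical(v1[1:8], v2[1:8])        # distance >= 3 from the edit
  expect_false(identical(v1[9:13], v2[9:13]))

  # exhaustive oracle over all 4^5 windows at R = 2
  bases <- c("A", "C", "G", "T")
  win <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                     b5 = bases, stringsAsFactors = FALSE)
  ct <- gtm$center_table
  gt <- gtm$contribution_table
  for (i in seq_len(nrow(win))) {
    w <- unlist(win[i, ])
    manual <- ct[[w[3L]]] +
      gt[2L, 1L, w[1L]] + gt[1L, 1L, w[2L]] +
      gt[1L, 2L, w[4L]] + gt[2L, 2L, w[5L]]
    got <- true_shape(paste(w, collapse = ""), gtm)[3L]
    expect_equal(got, unname(manual), tolerance = 1e-14)
  }
})

test_that("step-node truths index flanks from both step bases", {
  gtm <- make_ground_truth(seed = 21L, R = 1L, node_kind = "step")
  s <- "ACGTA"
  v <- true_shape(s, gtm)
  expect_length(v, 4L)
  # node 2 is step CG; 5' flank base A (distance 1 from C), 3' flank T
  manual <- gtm$center_table[["CG"]] +
    gtm$contribution_table[1L, 1L, "A"] +
    gtm$contribution_table[1L, 2L, "T"]
  expect_equal(v[2L], unname(manual), tolerance = 1e-14)
})

test_that("fluctuation surfaces are strictly positive and sequence-dependent", {
  gtm <- make_ground_truth(seed = 31L, R = 2L, node_kind = "bp",
                           terminal_mask_margin = 0L)
  f1 <- true_shape("ACGTACGTACGT", gtm, what = "fluctuation")
  f2 <- true_shape("TTTTTTTTTTTT", gtm, what = "fluctuation")
  expect_true(all(f1 > 0))
  expect_false(isTRUE(all.equal(f1, f2)))
})

test_that("corpus sampling mirrors the reference conditions and is reproducible", {
  gtm <- make_ground_truth(seed = 41L, R = 4L)
  corpus <- sample_corpus(gtm, n_seqs = 2121L, length_range = c(15L, 25L),
                          seed = 42L)
  expect_length(corpus$records, 2121L)
  lens <- nchar(vapply(corpus$records, `[[`, "", "seq"))
  expect_true(all(lens >= 15L & lens <= 25L))
  expect_setequal(unique(lens), 15:25)

  again <- sample_corpus(gtm, n_seqs = 2121L, length_range = c(15L, 25L),
                         seed = 42L)
  expect_identical(corpus$records, again$records)

  # terminal mask: MGW-like margin of 2 at both ends
  r1 <- corpus$records[[1L]]
  expect_true(all(is.na(r1$values[c(1, 2, lens[1L] - 1L, lens[1L])])))
  expect_true(all(is.finite(r1$values[3:(lens[1L] - 2L)])))

  # noiseless mode reproduces the truth exactly
  nl <- sample_corpus(gtm, n_seqs = 10L, length_range = c(15L, 18L),
                      seed = 43L, noiseless = TRUE)
  for (r in nl$records)
    expect_identical(r$values, r$true_values)

  # noisy values differ from truth with the calibrated spread
  noisy <- sample_corpus(gtm, n_seqs = 50L, length_range = c(15L, 18L),
                         seed = 44L)
  resid <- unlist(lapply(noisy$records, function(r) r$values - r$true_values))
  resid <- resid[is.finite(resid)]
  expect_gt(stats::sd(resid), 0.7 * gtm$noise_sd)
  expect_lt(stats::sd(resid), 1.3 * gtm$noise_sd)

  expect_error(sample_corpus(gtm, length_range = c(10L, 3L)), "degenerate")
})

test_that("constrained-context mode plants the k-mer only inside its context", {
  gtm <- make_ground_truth(seed = 51L, R = 1L)
  corpus <- sample_corpus(gtm, n_seqs = 80L, length_range = c(15L, 22L),
                          seed = 52L,
                          context = list(kmer = "ACGTA", context = "CACGTAG"))
  for (r in corpus$records) {
    hits <- gregexpr("ACGTA", r$seq, fixed = TRUE)[[1L]]
    expect_length(hits, 1L)
    # every occurrence sits inside CACGTAG
    expect_identical(substr(r$seq, hits - 1L, hits + 5L), "CACGTAG")
  }
})

test_that("noiseless empirical tables converge to the truth's window values", {
  gtm <- make_ground_truth(seed = 61L, R = 2L, node_kind = "bp",
                           terminal_mask_margin = 0L)
  corpus <- sample_corpus(gtm, n_seqs = 850L, length_range = c(15L, 20L),
                          seed = 62L, noiseless = TRUE)
  tab <- kmer_table(corpus_dataset(corpus), k = 5L)
  expect_gt(sum(tab$counts), 1e4)           # enough windows to cover
  # every table mean equals the noiseless window value exactly
  for (i in seq_along(tab$kmers)) {
    expect_equal(tab$means[i], true_shape(tab$kmers[i], gtm)[3L],
                 tolerance = 1e-12)
  }
})

test_that("generator manifests serialize every parameter", {
  gtm <- make_ground_truth(seed = 71L, R = 3L)
  path <- tempfile(fileext = ".json")
  write_gtm_manifest(gtm, path)
  m <- jsonlite::fromJSON(readLines(path))
  expect_equal(m$R, 3L)
  expect_equal(m$gamma, 0.6)
  expect_equal(unlist(m$center_table), gtm$center_table, tolerance = 1e-15)
  expect_equal(m$noise_sd, gtm$noise_sd, tolerance = 1e-15)
})
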
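# Shared fixtures. Everything is generated in code; nothing is read from
# disk except files the tests themselves write to tempdir().

# A quickly trained small model (enough structure for locality/symmetry
# checks; accuracy is irrelevant for those).
make_small_net <- function(feature = "MGW", layers = 3L, filter = 8L,
                           seed = 1L, epochs = 2L, n_seqs = 15L,
                           dropout = 0, R = 2L) {
  kind <- shape_feature(feature)$node_kind
  gtm <- make_ground_truth(seed = seed, R = R, node_kind = kind)
  corpus <- sample_corpus(gtm, n_seqs = n_seqs, length_range = c(10L, 14L),
                          seed = seed)
  cfg <- shapenet_config(n_shape_layers = layers, filter_size = filter,
                         dropout_ratio = dropout, learning_rate = 0.02,
                         epochs = epochs, batch_size = 8L, seed = seed)
  shapenet(corpus_dataset(corpus), feature, cfg)
}

# Brute-force k-mer table oracle: dictionary of per-kmer value lists.
oracle_kmer_table <- function(ds, k, min_count = 1L) {
  center_off <- if (ds$node_kind == "bp") (k - 1L) %/% 2L else k %/% 2L - 1L
  dict <- list()
  for (r in ds$records) {
    n <- nchar(r$seq)
    if (n < k) next
    for (s in seq_len(n - k + 1L)) {
      km <- substr(r$seq, s, s + k - 1L)
      v <- r$values[s + center_off]
      if (is.finite(v) && !grepl("N", km, fixed = TRUE))
        dict[[km]] <- c(dict[[km]], v)
    }
  }
  dict <- dict[order(names(dict))]
  dict <- dict[lengths(dict) >= min_count]
  list(kmers = names(dict),
       means = unname(vapply(dict, mean, 0)),
       counts = unname(lengths(dict)))
}

# The parameter-recovery experiment (radius-4 truth, 2000 noisy training
# sequences, pentamer-table baseline), memoised so several test files can
# assert on the same fits without recomputing them.
.recovery_cache <- new.env(parent = emptyenv())
recovery_experiment <- function(seed) {
  key <- paste0("s", seed)
  got <- .recovery_cache[[key]]
  if (!is.null(got)) return(got)
  gtm <- make_ground_truth(seed = seed, R = 4L, gamma = 0.6,
                           noise_frac = 0.05, node_kind = "bp")
  corpus <- sample_corpus(gtm, n_seqs = 2000L, length_range = c(15L, 25L),
                          seed = seed + 1L)
  ds <- corpus_dataset(corpus)
  cfg <- shapenet_config(n_shape_layers = 7L, filter_size = 32L,
                         dropout_ratio = 0.1, learning_rate = 0.05,
                         epochs = 40L, batch_size = 32L, seed = seed + 2L)
  fit <- shapenet(ds, "MGW", cfg)
  heldout <- sample_corpus(gtm, n_seqs = 200L, length_range = c(15L, 25L),
                           seed = seed + 3L)
  truth <- corpus_truth_dataset(heldout)
  tab <- kmer_table(ds, k = 5L)
  res <- list(gtm = gtm, fit = fit, table = tab,
              mae = compare_methods(truth, fit, tab, depth = 4L),
              layer_mae = shapenet_eval(fit, truth))
  .recovery_cache[[key]] <- res
  res
}
recovery_seeds <- c(101L, 202L, 303L)

random_dataset <- function(seed, n_seqs = 12L, lens = 8:14, mask_p = 0.1) {
  set.seed(seed)
  recs <- lapply(seq_len(n_seqs), function(i) {
    len <- sample(lens, 1L)
    v <- rnorm(len)
    v[runif(len) < mask_p] <- NA
    list(id = paste0("r", i),
         seq = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""),
         values = v)
  })
  deepshape:::new_shape_dataset(recs)
}

truth_pred_13 <- function(seed = 201L) {
  feats <- shape_features("13shape")
  gtms <- lapply(seq_len(nrow(feats)), function(i)
    make_ground_truth(seed = seed + i, R = 2L, node_kind = feats$node_kind[i],
                      terminal_mask_margin = 0L))
  names(gtms) <- feats$name
  truth_predictor(gtms)
}
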
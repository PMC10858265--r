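#' Synthetic flank-decay ground truth
#'
#' A generative stand-in for the Monte-Carlo shape corpus, built around the
#' same structural assumption the prediction model encodes: the shape value
#' at a position is determined mainly by its own base (or base-pair step)
#' plus contributions from flanking bases whose influence decays with
#' distance. Concretely, the noiseless value at node i is
#' \deqn{v_i = c(u_i) + \sum_{d=1}^{R} g(d, 5', b_{i-d}) + g(d, 3', b_{i+d})}
#' where `c` is a per-central-unit table (4 entries for nucleotide nodes,
#' 16 for dinucleotide nodes), and the flank contribution tables `g` are
#' drawn with standard deviation `contrib_sd * gamma^(d-1)`, so influence
#' shrinks geometrically with distance; terms beyond the sequence end are
#' simply absent. Because the truth is known exactly, trained models can be
#' scored against noiseless profiles and a radius-R truth with R <= 2 is
#' exactly representable by a pentamer table -- the property the
#' query-table comparisons exploit.
#'
#' A companion fluctuation surface (for `-FL` features) is generated as a
#' strictly positive smooth function of the same local windows:
#' `fluct_base * exp(additive flank terms)`.
#'
#' The noise level is expressed as a fraction of the feature's value range;
#' the absolute `noise_sd` is calibrated once at construction by evaluating
#' the noiseless model on seeded random sequences and taking the 1st-99th
#' percentile span.
#'
#' @param seed Integer seed; tables are fully determined by it.
#' @param R Influence radius in bp (`<= 7`).
#' @param gamma Geometric decay of flank influence per bp, in `[0, 1)`.
#' @param noise_frac Gaussian noise standard deviation as a fraction of the
#'   feature's (p99 - p1) range.
#' @param node_kind `"bp"` or `"step"`.
#' @param center_sd,contrib_sd Standard deviations of the central-unit
#'   table and of the distance-1 flank contributions.
#' @param terminal_mask_margin Positions masked `NA` at each sequence end
#'   (mimics undefined groove values at termini).
#' @return An object of class `"ground_truth"`.
#' @export
make_ground_truth <- function(seed = 1L, R = 4L, gamma = 0.6,
                              noise_frac = 0.05, node_kind = "bp",
                              center_sd = 1.0, contrib_sd = 0.5,
                              terminal_mask_margin = if (node_kind == "bp") 2L else 0L) {
  R <- as.integer(R)
  if (R < 0L || R > 7L) stop("R must be in 0..7", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)", call. = FALSE)
  if (!node_kind %in% c("bp", "step")) stop("bad node_kind", call. = FALSE)
  gtm <- with_seed(seed, {
    units <- if (node_kind == "bp") BASES else DINUCS
    center <- stats::setNames(stats::rnorm(length(units), sd = center_sd),
                              units)
    contrib <- array(0, dim = c(max(R, 1L), 2L, 4L),
                     dimnames = list(NULL, c("5prime", "3prime"), BASES))
    fluct_mod <- contrib
    if (R >= 1L) for (d in seq_len(R)) {
      # random direction, rescaled so the largest |contribution| at distance
      # d is exactly contrib_sd * gamma^(d-1): the decay bound holds by
      # construction, not just in expectation
      r <- stats::rnorm(8L)
      contrib[d, , ] <- r / max(abs(r)) * contrib_sd * gamma^(d - 1)
      rf <- stats::rnorm(8L)
      fluct_mod[d, , ] <- rf / max(abs(rf)) * 0.3 * gamma^(d - 1)
    }
    fluct_center <- stats::setNames(stats::rnorm(length(units), sd = 0.3),
                                    units)
    list(node_kind = node_kind, R = R, gamma = gamma,
         center_table = center, contribution_table = contrib,
         fluct_base = 0.5, fluct_center = fluct_center,
         fluct_modifiers = fluct_mod,
         terminal_mask_margin = as.integer(terminal_mask_margin),
         noise_frac = noise_frac, seed = as.integer(seed))
  })
  class(gtm) <- "ground_truth"
  # calibrate absolute noise sd against the realized value range
  cal <- with_seed(seed + 1013L, {
    vals <- unlist(lapply(seq_len(200L), function(i) {
      s <- paste(sample(BASES, 21L, replace = TRUE), collapse = "")
      true_shape(s, gtm, mask = FALSE)
    }))
    stats::quantile(vals, c(0.01, 0.99), names = FALSE, type = 7)
  })
  gtm$value_range <- cal[2L] - cal[1L]
  gtm$noise_sd <- noise_frac * gtm$value_range
  gtm
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("ground_truth: %s nodes, radius %d bp, decay %.2f, ",
                     "noise sd %.4g (%.0f%% of range %.4g)\n"),
              x$node_kind, x$R, x$gamma, x$noise_sd, 100 * x$noise_frac,
              x$value_range))
  invisible(x)
}

#' Noiseless profile under a synthetic ground truth
#'
#' @param seq Sequence string over `A/C/G/T`.
#' @param gtm A `"ground_truth"`.
#' @param what `"shape"` or `"fluctuation"`.
#' @param mask Apply the terminal mask (`NA` at the outermost
#'   `terminal_mask_margin` nodes)?
#' @return Numeric profile: n values for per-bp truth, n-1 for step truth.
#' @export
true_shape <- function(seq, gtm, what = c("shape", "fluctuation"),
                       mask = TRUE) {
  what <- match.arg(what)
  stopifnot(inherits(gtm, "ground_truth"))
  chars <- split_seq(seq)
  if (any(chars == "N"))
    stop("ground truth is defined over A/C/G/T only", call. = FALSE)
  n <- length(chars)
  per_bp <- gtm$node_kind == "bp"
  n_nodes <- if (per_bp) n else n - 1L
  if (n_nodes < 1L) stop("sequence too short for node kind", call. = FALSE)

  units <- if (per_bp) chars else paste0(chars[-n], chars[-1L])
  if (what == "shape") {
    ctab <- gtm$center_table
    gtab <- gtm$contribution_table
  } else {
    ctab <- gtm$fluct_center
    gtab <- gtm$fluct_modifiers
  }
  base_idx <- match(chars, BASES)
  out <- unname(ctab[units])
  if (gtm$R >= 1L) for (i in seq_len(n_nodes)) {
    p5 <- i            # bp index of the node's 5'-most base
    p3 <- if (per_bp) i else i + 1L
    for (d in seq_len(gtm$R)) {
      if (p5 - d >= 1L) out[i] <- out[i] + gtab[d, 1L, base_idx[p5 - d]]
      if (p3 + d <= n)  out[i] <- out[i] + gtab[d, 2L, base_idx[p3 + d]]
    }
  }
  if (what == "fluctuation") out <- gtm$fluct_base * exp(out)
  if (mask && gtm$terminal_mask_margin > 0L) {
    m <- gtm$terminal_mask_margin
    if (2L * m >= n_nodes) out[] <- NA_real_
    else out[c(seq_len(m), n_nodes - m + seq_len(m))] <- NA_real_
  }
  out
}

#' Sample a synthetic training corpus
#'
#' Draws random sequences, evaluates the ground truth at every position,
#' adds position-wise Gaussian noise (the generator's calibrated
#' `noise_sd`), applies the terminal mask, and returns a corpus that can be
#' written as a standard training file. Regenerating with the same seed is
#' bit-identical.
#'
#' Composition can be biased (`base_probs`), or a constrained-context mode
#' can plant a chosen k-mer so that it only ever occurs inside one fixed
#' longer context -- the situation that biases query tables (see
#' [flank_bias_report()]).
#'
#' @param gtm A `"ground_truth"`.
#' @param n_seqs Number of sequences (the reference corpus size used
#'   throughout the package experiments is 2121).
#' @param length_range Inclusive integer range of sequence lengths.
#' @param base_probs Sampling probabilities for A, C, G, T.
#' @param seed Seed for sequences and noise.
#' @param context Optional list `list(kmer =, context =)`: each sequence is
#'   guaranteed to contain `kmer` only inside `context` (which must contain
#'   `kmer`), planted at a random admissible position.
#' @param noiseless Skip the Gaussian noise (training values equal truth).
#' @param what Generate `"shape"` or `"fluctuation"` targets.
#' @return A `"shape_corpus"`: list with `records` (id, seq, `true_values`,
#'   `values` (noisy, masked), all per node), `gtm`, `seed`. Convert for
#'   training with [corpus_dataset()] or write with [write_training_file()].
#' @export
sample_corpus <- function(gtm, n_seqs = 2121L, length_range = c(15L, 25L),
                          base_probs = rep(0.25, 4), seed = 1L,
                          context = NULL, noiseless = FALSE,
                          what = "shape") {
  stopifnot(inherits(gtm, "ground_truth"), n_seqs >= 1L)
  lo <- as.integer(length_range[1L]); hi <- as.integer(length_range[2L])
  if (lo > hi || lo < max(3L, 2L * gtm$terminal_mask_margin + 1L))
    stop("degenerate length range", call. = FALSE)
  if (!is.null(context)) {
    if (!grepl(context$kmer, context$context, fixed = TRUE))
      stop("context must contain the k-mer", call. = FALSE)
    if (nchar(context$context) > lo)
      stop("context longer than the shortest sequence", call. = FALSE)
  }
  base_probs <- base_probs / sum(base_probs)

  records <- with_seed(seed, {
    lapply(seq_len(n_seqs), function(i) {
      len <- if (lo == hi) lo else sample(lo:hi, 1L)
      repeat {
        s <- paste(sample(BASES, len, replace = TRUE, prob = base_probs),
                   collapse = "")
        if (is.null(context)) break
        # strip stray occurrences, then plant the fixed context
        if (grepl(context$kmer, s, fixed = TRUE)) next
        w <- nchar(context$context)
        at <- sample.int(len - w + 1L, 1L)
        s <- paste0(substring(s, 1L, at - 1L), context$context,
                    substring(s, at + w, len))
        # planting may have created a stray copy across the junctions
        if (length(gregexpr(context$kmer, s, fixed = TRUE)[[1L]]) == 1L)
          break
      }
      tv <- true_shape(s, gtm, what = what, mask = FALSE)
      masked <- true_shape(s, gtm, what = what, mask = TRUE)
      noisy <- if (noiseless) tv else tv + stats::rnorm(length(tv),
                                                        sd = gtm$noise_sd)
      noisy[is.na(masked)] <- NA_real_
      list(id = sprintf("syn%05d", i), seq = s,
           true_values = masked, values = noisy)
    })
  })
  structure(list(records = records, gtm = gtm, seed = as.integer(seed),
                 what = what),
            class = "shape_corpus")
}

#' Views of a synthetic corpus as training / evaluation datasets
#'
#' `corpus_dataset()` exposes the noisy (training) values;
#' `corpus_truth_dataset()` exposes the noiseless true profiles, for
#' scoring predictors against the ground truth.
#'
#' @param corpus A `"shape_corpus"`.
#' @return A `"shape_dataset"`.
#' @export
corpus_dataset <- function(corpus) {
  stopifnot(inherits(corpus, "shape_corpus"))
  new_shape_dataset(lapply(corpus$records, function(r)
    list(id = r$id, seq = r$seq, values = r$values)))
}

#' @rdname corpus_dataset
#' @export
corpus_truth_dataset <- function(corpus) {
  stopifnot(inherits(corpus, "shape_corpus"))
  new_shape_dataset(lapply(corpus$records, function(r)
    list(id = r$id, seq = r$seq, values = r$true_values)))
}

#' @export
print.shape_corpus <- function(x, ...) {
  nlen <- nchar(vapply(x$records, `[[`, "", "seq"))
  cat(sprintf("shape_corpus: %d sequences (lengths %d-%d), %s targets\n",
              length(x$records), min(nlen), max(nlen), x$what))
  print(x$gtm)
  invisible(x)
}

#' Write a generator manifest
#'
#' JSON record of every generator parameter (and the tables themselves) so
#' later runs can verify corpora against the exact ground truth.
#'
#' @param gtm A `"ground_truth"`.
#' @param path Output path.
#' @export
write_gtm_manifest <- function(gtm, path) {
  stopifnot(inherits(gtm, "ground_truth"))
  obj <- unclass(gtm)
  obj$center_table <- as.list(gtm$center_table)
  obj$fluct_center <- as.list(gtm$fluct_center)
  obj$contribution_table <- as.vector(gtm$contribution_table)
  obj$fluct_modifiers <- as.vector(gtm$fluct_modifiers)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}
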
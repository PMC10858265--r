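#' Shape predictors as interchangeable profile sources
#'
#' Downstream analyses (feature encoding, profile aggregation, cap scans)
#' only need "a per-position shape profile for a sequence and feature".
#' `shape_profile()` is that interface. Two providers are shipped:
#' `shapenet_set()` bundles fitted [shapenet()] models (one per feature)
#' with a readout depth; `truth_predictor()` serves noiseless profiles from
#' synthetic [make_ground_truth()] models, which is how regression
#' experiments with an exactly known sequence-shape relationship are built.
#' A feature name ending in `-FL` served by a `truth_predictor` returns the
#' ground truth's fluctuation surface.
#'
#' @param predictor A predictor object.
#' @param seq Sequence string.
#' @param feature Feature name.
#' @return Numeric profile (n or n-1 values).
#' @export
shape_profile <- function(predictor, seq, feature) {
  UseMethod("shape_profile")
}

#' @rdname shape_profile
#' @param models Named list of `"shapenet"` objects (names = feature
#'   names).
#' @param depth Readout layer used for every model.
#' @param symmetrize Passed to [predict.shapenet()].
#' @export
shapenet_set <- function(models, depth = NULL, symmetrize = FALSE) {
  stopifnot(length(models) >= 1L, !is.null(names(models)),
            all(vapply(models, inherits, TRUE, "shapenet")))
  structure(list(models = models, depth = depth, symmetrize = symmetrize),
            class = "shapenet_set")
}

#' @export
shape_profile.shapenet_set <- function(predictor, seq, feature) {
  m <- predictor$models[[feature]]
  if (is.null(m)) stop("no trained model for feature '", feature, "'",
                       call. = FALSE)
  depth <- if (is.null(predictor$depth)) m$config$n_shape_layers
           else predictor$depth
  predict(m, seq, depth = depth, symmetrize = predictor$symmetrize)
}

#' @export
shape_profile.shapenet <- function(predictor, seq, feature) {
  if (!identical(predictor$feature$name, feature))
    stop("model is for ", predictor$feature$name, ", not ", feature,
         call. = FALSE)
  predict(predictor, seq)
}

#' @rdname shape_profile
#' @param gtms Named list of `"ground_truth"` objects keyed by feature
#'   name.
#' @export
truth_predictor <- function(gtms) {
  stopifnot(!is.null(names(gtms)),
            all(vapply(gtms, inherits, TRUE, "ground_truth")))
  structure(list(gtms = gtms), class = "truth_predictor")
}

#' @export
shape_profile.truth_predictor <- function(predictor, seq, feature) {
  g <- predictor$gtms[[feature]]
  if (!is.null(g)) return(true_shape(seq, g, mask = FALSE))
  parent <- sub("-FL$", "", feature)
  g <- predictor$gtms[[parent]]
  if (grepl("-FL$", feature) && !is.null(g))
    return(true_shape(seq, g, what = "fluctuation", mask = FALSE))
  stop("no ground truth for feature '", feature, "'", call. = FALSE)
}

#' Binding tables
#'
#' TSV with two fields, `sequence<TAB>affinity`: pre-aligned fixed-length
#' binding-site sequences and their relative binding affinity (positive;
#' dataset-normalized units). A header line is permitted and detected.
#'
#' @param path File path.
#' @return Data frame with columns `seq`, `affinity`.
#' @export
read_binding_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts[[1L]]) != 2L)
    stop("binding table must have 2 tab-separated fields", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(parts[[1L]][2L]))))
    parts <- parts[-1L]                       # header
  df <- data.frame(seq = toupper(vapply(parts, `[[`, "", 1L)),
                   affinity = as.numeric(vapply(parts, `[[`, "", 2L)),
                   stringsAsFactors = FALSE)
  check_binding_records(df)
  df
}

check_binding_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("seq", "affinity") %in% names(records)))
  n <- unique(nchar(records$seq))
  if (length(n) != 1L)
    stop("binding records must share one aligned length; found lengths ",
         paste(n, collapse = ", "), call. = FALSE)
  if (any(!is.finite(records$affinity)) || any(records$affinity <= 0))
    stop("affinities must be positive finite numbers", call. = FALSE)
  invisible(records)
}

#' Feature configuration for binding regression
#'
#' @param kmer_orders Subset of `c(1, 2, 3)`: which k-mer indicator
#'   families to include. A length-n sequence contributes `4n` 1-mer,
#'   `16(n-1)` 2-mer and `64(n-2)` 3-mer columns.
#' @param shape_preset `NULL` or a preset for [shape_features()]
#'   (`"4shape"`, `"13shape"`, `"13shape+FL"`); each per-bp or groove
#'   feature contributes n columns, each step feature n-1.
#' @param shape_norm `"minmax"` (column-wise to `[0, 1]`, the default) or
#'   `"zscore"`; how shape columns are normalized across the dataset.
#' @return A list of class `"binding_feature_config"`.
#' @export
binding_feature_config <- function(kmer_orders = 1L, shape_preset = NULL,
                                   shape_norm = c("minmax", "zscore")) {
  kmer_orders <- sort(unique(as.integer(kmer_orders)))
  if (length(kmer_orders) && !all(kmer_orders %in% 1:3))
    stop("kmer_orders must be within 1..3", call. = FALSE)
  if (!length(kmer_orders) && is.null(shape_preset))
    stop("at least one feature family must be enabled", call. = FALSE)
  structure(list(kmer_orders = kmer_orders, shape_preset = shape_preset,
                 shape_norm = match.arg(shape_norm)),
            class = "binding_feature_config")
}

#' Encode binding records as a regression design matrix
#'
#' k-mer blocks are position-specific indicators (4^k columns per window
#' position); shape blocks are per-position profiles from `predictor`,
#' normalized column-wise across the dataset.
#'
#' @param records Data frame with `seq` (aligned, one length) and
#'   optionally `affinity`.
#' @param config A [binding_feature_config()].
#' @param predictor Needed when `config$shape_preset` is set; see
#'   [shape_profile()].
#' @return Numeric matrix with informative column labels.
#' @export
encode_feature_matrix <- function(records, config, predictor = NULL) {
  stopifnot(inherits(config, "binding_feature_config"))
  seqs <- toupper(records$seq)
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("sequences must share one aligned length", call. = FALSE)
  blocks <- list()

  for (k in config$kmer_orders) {
    kmers <- DINUCS
    if (k == 1L) kmers <- BASES
    if (k == 3L) kmers <- as.vector(t(outer(DINUCS, BASES, paste0)))
    npos <- n - k + 1L
    B <- matrix(0, length(seqs), npos * 4L^k)
    labs <- character(npos * 4L^k)
    for (p in seq_len(npos)) {
      wins <- substring(seqs, p, p + k - 1L)
      ix <- match(wins, kmers)
      if (anyNA(ix))
        stop("ambiguous base in k-mer encoding at position ", p, call. = FALSE)
      cols <- (p - 1L) * 4L^k + ix
      B[cbind(seq_along(seqs), cols)] <- 1
      labs[(p - 1L) * 4L^k + seq_len(4L^k)] <- sprintf("%dmer_p%d_%s", k, p, kmers)
    }
    colnames(B) <- labs
    blocks[[length(blocks) + 1L]] <- B
  }

  if (!is.null(config$shape_preset)) {
    if (is.null(predictor))
      stop("shape features requested but no predictor given", call. = FALSE)
    feats <- shape_features(config$shape_preset)
    for (i in seq_len(nrow(feats))) {
      fname <- feats$name[i]
      profs <- t(vapply(seqs, function(s) shape_profile(predictor, s, fname),
                        numeric(if (feats$node_kind[i] == "step") n - 1L else n)))
      colnames(profs) <- sprintf("%s_p%d", fname, seq_len(ncol(profs)))
      # column-wise normalization over the dataset
      profs <- apply(profs, 2L, function(col) {
        if (config$shape_norm == "minmax") {
          span <- max(col) - min(col)
          if (span == 0) rep(0, length(col)) else (col - min(col)) / span
        } else {
          s <- stats::sd(col)
          if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
        }
      })
      rownames(profs) <- NULL
      blocks[[length(blocks) + 1L]] <- profs
    }
  }
  do.call(cbind, blocks)
}

# closed-form ridge with unpenalized intercept (columns centred on the
# training set)
ridge_solve <- function(X, y, lambda) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- cadd(X, -xbar)
  yc <- y - ybar
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  beta <- tryCatch(solve(A, crossprod(Xc, yc)),
                   error = function(e)
                     stop("design is rank-deficient beyond the ridge floor: ",
                          conditionMessage(e), call. = FALSE))
  list(beta = drop(beta), intercept = ybar - sum(xbar * drop(beta)))
}

ridge_predict <- function(fit, X) drop(X %*% fit$beta) + fit$intercept

#' L2-regularized regression of binding specificity with nested CV
#'
#' The standard evaluation protocol for sequence/shape feature sets:
#' records are split into 10 outer folds; within each outer training set an
#' inner 10-fold cross-validation selects the ridge penalty lambda (lowest
#' validation mean squared error across a log-spaced grid), the model is
#' refit on the full outer training set with the selected lambda, and the
#' held-out fold is predicted. The pooled out-of-fold predictions -- each
#' record predicted exactly once -- yield the reported \eqn{R^2}, computed
#' as the coefficient of determination \eqn{1 - SSE/SST} (not squared
#' Pearson).
#'
#' @param x Design matrix from [encode_feature_matrix()].
#' @param y Response (relative affinity, or its log).
#' @param seed Seed for both fold assignments.
#' @param lambda_grid Ridge penalties to search (default: 13 values
#'   log-spaced from 1e-6 to 1e6).
#' @param n_folds Outer and inner fold count.
#' @return Object of class `"bind_ridge"`: `r2`, `oof` (pooled out-of-fold
#'   predictions), `fold` (outer assignment), `lambda_per_fold`, `y`,
#'   `final` (full-data refit at the median selected lambda), `seed`.
#' @export
bind_ridge <- function(x, y, seed = 1L, lambda_grid = 10^seq(-6, 6, by = 1),
                       n_folds = 10L) {
  x <- as.matrix(x)
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  nr <- nrow(x)
  if (nr < 20L) stop("need at least 20 records", call. = FALSE)
  if (all(apply(x, 2L, function(c) stats::sd(c) == 0)))
    stop("design has rank 0 (all columns constant)", call. = FALSE)

  with_seed(seed, {
    fold <- sample(rep_len(seq_len(n_folds), nr))
    oof <- numeric(nr)
    lam_sel <- numeric(n_folds)
    for (fo in seq_len(n_folds)) {
      tr <- which(fold != fo)
      te <- which(fold == fo)
      inner <- sample(rep_len(seq_len(n_folds), length(tr)))
      mse <- sapply(lambda_grid, function(lam) {
        errs <- vapply(seq_len(n_folds), function(fi) {
          itr <- tr[inner != fi]
          iva <- tr[inner == fi]
          fit <- ridge_solve(x[itr, , drop = FALSE], y[itr], lam)
          mean((ridge_predict(fit, x[iva, , drop = FALSE]) - y[iva])^2)
        }, 0)
        mean(errs)
      })
      lam_sel[fo] <- lambda_grid[which.min(mse)]
      fit <- ridge_solve(x[tr, , drop = FALSE], y[tr], lam_sel[fo])
      oof[te] <- ridge_predict(fit, x[te, , drop = FALSE])
    }
    r2 <- 1 - sum((y - oof)^2) / sum((y - mean(y))^2)
    final <- ridge_solve(x, y, stats::median(lam_sel))
    structure(list(r2 = r2, oof = oof, fold = fold,
                   lambda_per_fold = lam_sel, y = y, final = final,
                   lambda_grid = lambda_grid, seed = as.integer(seed),
                   n_folds = as.integer(n_folds)),
              class = "bind_ridge")
  })
}

#' @export
print.bind_ridge <- function(x, ...) {
  cat(sprintf("bind_ridge: %d records, %d-fold nested CV, pooled R2 = %.4f\n",
              length(x$y), x$n_folds, x$r2))
  cat("  selected lambda per fold:",
      paste(signif(x$lambda_per_fold, 3), collapse = " "), "\n")
  invisible(x)
}

#' @method coef bind_ridge
#' @export
coef.bind_ridge <- function(object, ...) {
  c("(Intercept)" = object$final$intercept, object$final$beta)
}

#' @export
predict.bind_ridge <- function(object, newx, ...) {
  ridge_predict(object$final, as.matrix(newx))
}

#' @method residuals bind_ridge
#' @export
residuals.bind_ridge <- function(object, ...) object$y - object$oof

#' @method plot bind_ridge
#' @export
plot.bind_ridge <- function(x, ...) {
  graphics::plot(x$y, x$oof, xlab = "observed", ylab = "out-of-fold predicted",
                 main = sprintf("bind_ridge (R2 = %.3f)", x$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Affinity-sorted shape-profile matrix
#'
#' Predicts a shape profile for every aligned binding record, keeps the
#' top fraction by relative affinity (default the top 25%), and returns the
#' profiles as a matrix ordered by descending affinity -- the raw material
#' for binding-site shape heatmaps. Optionally also returns mean profiles
#' per affinity bin.
#'
#' @param records Binding data frame (`seq`, `affinity`).
#' @param predictor A [shape_profile()] provider.
#' @param feature Feature name.
#' @param top_fraction Fraction of highest-affinity records kept
#'   (`ceiling(top_fraction * N)` rows).
#' @param n_bins If not `NULL`, attach `attr(, "bin_means")`: mean profile
#'   within each of `n_bins` equal-count affinity bins of the kept rows.
#' @return Matrix (records x positions) with `attr(, "affinity")`.
#' @export
aggregate_profiles <- function(records, predictor, feature,
                               top_fraction = 0.25, n_bins = NULL) {
  check_binding_records(records)
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  ord <- order(records$affinity, decreasing = TRUE)
  keep <- ord[seq_len(ceiling(top_fraction * nrow(records)))]
  seqs <- records$seq[keep]
  profs <- t(vapply(seqs, function(s) shape_profile(predictor, s, feature),
                    numeric(length(shape_profile(predictor, seqs[1L], feature)))))
  rownames(profs) <- NULL
  attr(profs, "affinity") <- records$affinity[keep]
  if (!is.null(n_bins)) {
    bins <- cut(seq_len(nrow(profs)), breaks = n_bins, labels = FALSE)
    attr(profs, "bin_means") <- t(vapply(seq_len(n_bins), function(b)
      colMeans(profs[bins == b, , drop = FALSE]), numeric(ncol(profs))))
  }
  profs
}

#' Cap scan: shape distributions of random cores between fixed flanks
#'
#' Holds the 5' and 3' caps fixed (e.g. `AAAA` A-tracts or `GCGC` ends),
#' enumerates all `4^core_length` intervening cores when that is at most
#' 65536 and otherwise draws `sample_size` seeded random cores, predicts
#' the feature profile of every `cap5 + core + cap3` sequence, and
#' summarizes each position with the median, quartiles and 1.5 x IQR
#' whisker bounds (the usual boxplot definition), exposing how fixed
#' flanks shift and constrain the shape of everything between them.
#'
#' @param cap5,cap3 Fixed flanking strings (either may be empty).
#' @param core_length Length of the randomized core, `>= 1`.
#' @param predictor A [shape_profile()] provider.
#' @param feature Feature name.
#' @param sample_size Number of sampled cores when enumeration is too
#'   large.
#' @param seed Seed for core sampling.
#' @return Data frame: `position`, `mean`, `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi`; attribute `"n_sequences"`.
#' @export
cap_scan <- function(cap5, cap3, core_length, predictor, feature,
                     sample_size = 4096L, seed = 1L) {
  core_length <- as.integer(core_length)
  if (core_length < 1L) stop("core_length must be >= 1", call. = FALSE)
  cores <- if (4^core_length <= 65536) {
    apply(do.call(expand.grid, rep(list(BASES), core_length))[
      , rev(seq_len(core_length)), drop = FALSE], 1L, paste, collapse = "")
  } else {
    with_seed(seed, vapply(seq_len(sample_size), function(i)
      paste(sample(BASES, core_length, replace = TRUE), collapse = ""), ""))
  }
  seqs <- paste0(toupper(cap5), cores, toupper(cap3))
  profs <- t(vapply(seqs, function(s) shape_profile(predictor, s, feature),
                    numeric(length(shape_profile(predictor, seqs[1L], feature)))))
  qs <- apply(profs, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE, type = 7)
  iqr <- qs[3L, ] - qs[1L, ]
  out <- data.frame(position = seq_len(ncol(profs)),
                    mean = colMeans(profs),
                    q1 = qs[1L, ], median = qs[2L, ], q3 = qs[3L, ],
                    whisker_lo = qs[1L, ] - 1.5 * iqr,
                    whisker_hi = qs[3L, ] + 1.5 * iqr)
  attr(out, "n_sequences") <- nrow(profs)
  out
}

#' Simulate a synthetic TF-binding dataset with known shape readout
#'
#' Generates aligned random sequences whose log relative affinity is a
#' linear function of their (noiseless) shape profiles under a set of
#' synthetic ground truths: per-feature, per-position weights are drawn
#' once from a seeded normal, then
#' `log a = sum_f sum_p w[f,p] * profile_f[p] (+ noise)` and the stored
#' affinity is `exp(log a)`. Because step-feature truths depend on
#' dinucleotide identities, the affinity is not a linear function of
#' single-base indicators -- shape features genuinely add information over
#' 1-mer encodings.
#'
#' @param predictor A [shape_profile()] provider (typically
#'   [truth_predictor()]).
#' @param features Feature names to wire into the affinity.
#' @param n Number of records.
#' @param len Aligned sequence length.
#' @param seed Seed.
#' @param noise_sd Gaussian noise added to the log affinity.
#' @param weight_sd Standard deviation of the readout weights.
#' @return Data frame `seq`, `affinity`; attribute `"log_affinity"`.
#' @export
simulate_binding_data <- function(predictor, features, n = 200L, len = 16L,
                                  seed = 1L, noise_sd = 0, weight_sd = 0.3) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(BASES, len, replace = TRUE), collapse = ""), "")
    w <- lapply(features, function(f) {
      np <- length(shape_profile(predictor, seqs[1L], f))
      stats::rnorm(np, sd = weight_sd)
    })
    names(w) <- features
    loga <- vapply(seqs, function(s)
      sum(vapply(features, function(f)
        sum(w[[f]] * shape_profile(predictor, s, f)), 0)), 0)
    loga <- loga + if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    loga <- loga - mean(loga)
    df <- data.frame(seq = seqs, affinity = exp(loga),
                     stringsAsFactors = FALSE)
    attr(df, "log_affinity") <- unname(loga)
    rownames(df) <- NULL
    df
  })
}
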
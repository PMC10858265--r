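#' Build a k-mer query table
#'
#' The predecessor of the layered network: every length-k window observed
#' in the training data contributes its central position's value to that
#' k-mer's running mean. Prediction then slides a window along a query
#' sequence and looks the centre value up. A table of width k can, by
#' construction, never see more than `(k-1)/2` bp of flanking sequence, and
#' k-mers absent from (or rare in) the training data leave holes -- the two
#' limitations the shape-layer network removes.
#'
#' For per-bp features the central position of a window starting at `s` is
#' `s + (k-1)/2`; for step features the central step is the one whose 5'
#' base sits at `s + floor(k/2) - 1` (window length counts nucleotides).
#' Undefined (masked) central values are skipped.
#'
#' @param data A `"shape_dataset"` (raw feature units).
#' @param k Odd window width in nucleotides, `>= 3` (5 reproduces the
#'   classic pentamer table).
#' @param min_count Entries observed fewer than `min_count` times are
#'   dropped from the table.
#' @param feature Optional feature name recorded in the table (defaults to
#'   the dataset's node kind only).
#' @param merge_rc Merge each k-mer with its reverse complement (values
#'   sign-flipped first for `"sign-flip"` features); only meaningful for
#'   per-bp features where the centre maps onto itself.
#' @return An object of class `"kmer_table"`: list with `k`, `node_kind`,
#'   `kmers`, `means`, `counts`.
#' @export
kmer_table <- function(data, k = 5L, min_count = 1L, feature = NULL,
                       merge_rc = FALSE) {
  ds <- as_shape_dataset(data)
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be odd and >= 3", call. = FALSE)
  spec <- if (!is.null(feature)) shape_feature(feature)
  center_off <- if (ds$node_kind == "bp") (k - 1L) %/% 2L else k %/% 2L - 1L

  sums <- new.env(parent = emptyenv())
  cnts <- new.env(parent = emptyenv())
  any_window <- FALSE
  for (r in ds$records) {
    n <- nchar(r$seq)
    if (n < k) next
    any_window <- TRUE
    starts <- seq_len(n - k + 1L)
    kmers <- substring(r$seq, starts, starts + k - 1L)
    vals <- r$values[starts + center_off]
    ok <- is.finite(vals) & !grepl("N", kmers, fixed = TRUE)
    for (j in which(ok)) {
      km <- kmers[j]
      if (merge_rc) {
        rc <- revcomp(km)
        if (rc < km) {
          km <- rc
          if (!is.null(spec) && identical(spec$rc_class, "sign-flip"))
            vals[j] <- -vals[j]
        }
      }
      sums[[km]] <- (if (is.null(sums[[km]])) 0 else sums[[km]]) + vals[j]
      cnts[[km]] <- (if (is.null(cnts[[km]])) 0L else cnts[[km]]) + 1L
    }
  }
  if (!any_window)
    stop("k = ", k, " exceeds every sequence length", call. = FALSE)
  kms <- sort(ls(sums))
  counts <- vapply(kms, function(x) cnts[[x]], 0L)
  means <- vapply(kms, function(x) sums[[x]], 0) / counts
  keep <- counts >= min_count
  structure(list(k = k, node_kind = ds$node_kind,
                 feature = if (is.null(spec)) NULL else spec$name,
                 merge_rc = merge_rc,
                 kmers = kms[keep], means = unname(means[keep]),
                 counts = unname(counts[keep])),
            class = "kmer_table")
}

#' Sliding-window prediction from a query table
#'
#' Slides the table's window along `seq`; each admissible centre gets the
#' table value of its window, positions whose window runs off the sequence
#' and windows missing from the table stay `NA` (no imputation by default).
#' With `fallback = TRUE` a missing window drops to the centred `(k-2)`-mer
#' recursively -- off by default because interpolating a query table is
#' exactly the bias the layered model was built to avoid.
#'
#' @param object A `"kmer_table"`.
#' @param seq Sequence string, length `>= k`.
#' @param fallback Optional `"kmer_table"` of width `k - 2` built from the
#'   same data, consulted for windows missing from the main table.
#' @param ... Unused.
#' @return Numeric profile (length n for per-bp, n-1 for step features)
#'   with `NA` at undefined positions.
#' @export
predict.kmer_table <- function(object, seq, fallback = NULL, ...) {
  seq <- toupper(seq)
  n <- nchar(seq)
  k <- object$k
  if (n < k) stop("sequence shorter than window (", k, ")", call. = FALSE)
  n_nodes <- if (object$node_kind == "bp") n else n - 1L
  center_off <- if (object$node_kind == "bp") (k - 1L) %/% 2L else k %/% 2L - 1L
  out <- rep(NA_real_, n_nodes)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  lookup <- function(km) {
    if (object$merge_rc) {
      rc <- revcomp(km)
      if (rc < km) km <- rc
    }
    i <- match(km, object$kmers)
    if (is.na(i)) NA_real_ else object$means[i]
  }
  if (!is.null(fallback)) {
    stopifnot(inherits(fallback, "kmer_table"),
              fallback$k == k - 2L,
              identical(fallback$node_kind, object$node_kind))
  }
  for (j in seq_along(starts)) {
    v <- lookup(kmers[j])
    if (is.na(v) && !is.null(fallback)) {
      i <- match(substring(kmers[j], 2L, k - 1L), fallback$kmers)
      if (!is.na(i)) v <- fallback$means[i]
    }
    out[starts[j] + center_off] <- v
  }
  out
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d (%s nodes%s), %d / %d k-mers present\n",
              x$k, x$node_kind,
              if (!is.null(x$feature)) paste0(", ", x$feature) else "",
              length(x$kmers), 4L^x$k))
  invisible(x)
}

#' Table file I/O
#'
#' Lexicographically sorted TSV `kmer<TAB>mean<TAB>count`, means with 17
#' significant digits (bit-exact round trip).
#'
#' @param object A `"kmer_table"`.
#' @param path File path.
#' @param node_kind,k Metadata needed to reconstruct the table on read
#'   (read from the header line written by `write_kmer_table()`).
#' @export
write_kmer_table <- function(object, path) {
  stopifnot(inherits(object, "kmer_table"))
  hdr <- sprintf("#deepshape-kmer-table k=%d node_kind=%s feature=%s merge_rc=%d",
                 object$k, object$node_kind,
                 if (is.null(object$feature)) "-" else object$feature,
                 as.integer(object$merge_rc))
  lines <- sprintf("%s\t%.17g\t%d", object$kmers, object$means, object$counts)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1L]
  if (!startsWith(hdr, "#deepshape-kmer-table"))
    stop("not a kmer table file: ", path, call. = FALSE)
  gethdr <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  feat <- gethdr("feature")
  structure(list(k = as.integer(gethdr("k")),
                 node_kind = gethdr("node_kind"),
                 feature = if (feat == "-") NULL else feat,
                 merge_rc = gethdr("merge_rc") == "1",
                 kmers = vapply(body, `[[`, "", 1L),
                 means = as.numeric(vapply(body, `[[`, "", 2L)),
                 counts = as.integer(vapply(body, `[[`, "", 3L))),
            class = "kmer_table")
}

#' Flanking-sequence bias of a training corpus
#'
#' A query table implicitly averages over whatever flanking sequences its
#' k-mers happened to have in the training data. If a k-mer only ever
#' occurs inside one longer context, the table entry is biased towards that
#' context's flanks (e.g. a pentamer seen only inside one heptamer). This
#' diagnostic tallies, for every k-mer, the empirical distribution of the
#' (5' base, 3' base) pair immediately outside the window, and scores the
#' bias as the total-variation distance from the uniform distribution over
#' the 16 flanking pairs: 0 for perfectly even context coverage, up to
#' 15/16 for a point mass on a single context. Windows at sequence ends
#' (no outer base on one side) are excluded from the tally.
#'
#' @param data A `"shape_dataset"` (or list of records; values unused).
#' @param k Window width.
#' @return A data frame with columns `kmer`, `n_contexts` (total tallied
#'   occurrences), `bias_score`, and attribute `"context_counts"` (named
#'   list of 16-long count vectors).
#' @export
flank_bias_report <- function(data, k = 5L) {
  ds <- as_shape_dataset(data)
  k <- as.integer(k)
  pairs <- as.vector(t(outer(BASES, BASES, paste0)))
  tab <- new.env(parent = emptyenv())
  for (r in ds$records) {
    n <- nchar(r$seq)
    if (n < k + 2L) next
    starts <- 2L:(n - k)      # need one base on each side
    kmers <- substring(r$seq, starts, starts + k - 1L)
    ctx <- paste0(substring(r$seq, starts - 1L, starts - 1L),
                  substring(r$seq, starts + k, starts + k))
    ok <- !grepl("N", paste0(kmers, ctx), fixed = TRUE)
    for (j in which(ok)) {
      km <- kmers[j]
      if (is.null(tab[[km]]))
        tab[[km]] <- stats::setNames(integer(16L), pairs)
      tab[[km]][ctx[j]] <- tab[[km]][ctx[j]] + 1L
    }
  }
  kms <- sort(ls(tab))
  counts <- lapply(kms, function(x) tab[[x]])
  names(counts) <- kms
  ntot <- vapply(counts, sum, 0L)
  bias <- vapply(counts, function(ct) sum(abs(ct / sum(ct) - 1 / 16)) / 2, 0)
  out <- data.frame(kmer = kms, n_contexts = ntot, bias_score = unname(bias),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "context_counts") <- counts
  out
}

#' Compare network and query-table predictions against known truth
#'
#' Computes each method's MAE on an evaluation set, restricted to positions
#' where the network prediction, the table prediction *and* the reference
#' value are all defined, so both methods are scored on identical ground.
#' On synthetic data the reference values are the generator's noiseless
#' profiles, so the MAEs measure method error, not simulation noise.
#'
#' @param eval_data A `"shape_dataset"` whose `values` are the reference
#'   profiles (typically noiseless synthetic truth).
#' @param net A `"shapenet"`.
#' @param table A `"kmer_table"`.
#' @param depth Readout layer for the network.
#' @return Named numeric vector `c(net = , table = )` plus attribute
#'   `"n_positions"`.
#' @export
compare_methods <- function(eval_data, net, table, depth) {
  ds <- as_shape_dataset(eval_data)
  err_net <- err_tab <- 0
  npos <- 0L
  for (r in ds$records) {
    truth <- r$values
    pn <- predict(net, r$seq, depth = depth)
    pt <- predict(table, r$seq)
    ok <- is.finite(truth) & is.finite(pn) & is.finite(pt)
    if (!any(ok)) next
    err_net <- err_net + sum(abs(pn[ok] - truth[ok]))
    err_tab <- err_tab + sum(abs(pt[ok] - truth[ok]))
    npos <- npos + sum(ok)
  }
  if (npos == 0L)
    stop("no positions where both methods and the reference are defined",
         call. = FALSE)
  structure(c(net = err_net / npos, table = err_tab / npos),
            n_positions = npos)
}
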
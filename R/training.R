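#' Shape training files
#'
#' One file per feature, TSV with three fields per record:
#' `seq_id<TAB>sequence<TAB>v1,v2,...` where the comma-separated values are
#' the per-position shape values 5' to 3' (`n` values for per-bp features,
#' `n-1` for step features) and `NA` marks undefined positions (e.g. groove
#' width at terminal base pairs). Sequences of different lengths may share
#' one file. Values are written with 17 significant digits so a
#' write-then-load round trip preserves them exactly.
#'
#' `load_training_file()` computes percentile normalization stats from all
#' defined values in the file and returns a `"shape_dataset"`; raw values
#' are kept (normalization happens inside [shapenet()]).
#'
#' @param records List of records `list(id=, seq=, values=)`.
#' @param path File path.
#' @return `load_training_file()`: a `"shape_dataset"` with `records`,
#'   `stats` ([compute_norm_stats()]) and `node_kind`.
#' @export
write_training_file <- function(records, path) {
  lines <- vapply(records, function(r) {
    v <- ifelse(is.na(r$values), "NA", sprintf("%.17g", r$values))
    paste(r$id, toupper(r$seq), paste(v, collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_training_file
#' @export
load_training_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty training file: ", path, call. = FALSE)
  records <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("line ", i, ": expected 3 tab-separated fields, got ",
           length(parts), call. = FALSE)
    toks <- strsplit(parts[3L], ",", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    bad <- which(is.na(vals) & toks != "NA")
    if (length(bad))
      stop("line ", i, ": non-numeric value token '", toks[bad[1L]], "'",
           call. = FALSE)
    list(id = parts[1L], seq = toupper(parts[2L]), values = vals)
  })
  new_shape_dataset(records, path = path)
}

new_shape_dataset <- function(records, stats = NULL, path = NULL) {
  nlen <- nchar(vapply(records, `[[`, "", "seq"))
  vlen <- lengths(lapply(records, `[[`, "values"))
  node_kind <- if (all(vlen == nlen)) "bp"
  else if (all(vlen == nlen - 1L)) "step"
  else stop("ragged records: value counts match neither n nor n-1",
            if (!is.null(path)) paste0(" in ", path) else "", call. = FALSE)
  if (is.null(stats)) {
    allv <- unlist(lapply(records, `[[`, "values"))
    stats <- compute_norm_stats(allv[is.finite(allv)])
  }
  structure(list(records = records, stats = stats, node_kind = node_kind),
            class = "shape_dataset")
}

as_shape_dataset <- function(x) {
  if (inherits(x, "shape_dataset")) return(x)
  if (is.list(x) && !is.null(x$records))
    return(new_shape_dataset(x$records, stats = x$stats))
  if (is.list(x) && length(x) && is.list(x[[1L]]) && !is.null(x[[1L]]$seq))
    return(new_shape_dataset(x))
  stop("cannot interpret object as a shape_dataset", call. = FALSE)
}

#' @export
print.shape_dataset <- function(x, ...) {
  nlen <- nchar(vapply(x$records, `[[`, "", "seq"))
  cat(sprintf("shape_dataset: %d sequences (lengths %d-%d), %s nodes\n",
              length(x$records), min(nlen), max(nlen), x$node_kind))
  print(x$stats)
  invisible(x)
}

#' Subset a shape dataset
#'
#' @param x A `"shape_dataset"`.
#' @param i Record indices.
#' @param recompute_stats Recompute normalization stats from the subset
#'   (default keeps the parent stats so train/validation splits share one
#'   normalization).
#' @export
subset_dataset <- function(x, i, recompute_stats = FALSE) {
  x <- as_shape_dataset(x)
  new_shape_dataset(x$records[i],
                    stats = if (recompute_stats) NULL else x$stats)
}

#' Hyperparameter grid search
#'
#' Trains one model per candidate configuration on a single fixed
#' train/validation split and reports the per-layer validation MAE
#' (normalized scale). The best configuration is the one with the lowest
#' validation MAE at its deepest layer.
#'
#' @param data A `"shape_dataset"`.
#' @param feature Feature name.
#' @param grid List of [shapenet_config()] objects.
#' @param split_seed Seed for the train/validation split.
#' @param val_fraction Fraction of records held out for validation
#'   (default 0.1).
#' @param verbose Report progress.
#' @return List with `best_config`, `best_index`, and `results`: a data
#'   frame with one row per configuration (columns `val_mae_layer<k>` and
#'   `val_mae_deepest`).
#' @export
grid_search <- function(data, feature, grid, split_seed = 1L,
                        val_fraction = 0.1, verbose = FALSE) {
  if (!length(grid)) stop("empty configuration grid", call. = FALSE)
  ds <- as_shape_dataset(data)
  n <- length(ds$records)
  n_val <- max(1L, round(val_fraction * n))
  if (n_val >= n) stop("validation split leaves no training data", call. = FALSE)
  idx_val <- with_seed(split_seed, sample.int(n, n_val))
  train <- subset_dataset(ds, setdiff(seq_len(n), idx_val),
                          recompute_stats = TRUE)
  val <- subset_dataset(ds, idx_val)

  rows <- lapply(seq_along(grid), function(i) {
    cfg <- grid[[i]]
    fit <- shapenet(train, feature, cfg)
    mae <- shapenet_eval(fit, val)
    if (verbose)
      message(sprintf("config %d/%d: deepest-layer val MAE %.5f",
                      i, length(grid), mae[length(mae)]))
    stats::setNames(c(mae, mae[length(mae)]),
                    c(paste0("val_mae_layer", seq_along(mae)),
                      "val_mae_deepest"))
  })
  # configs may differ in depth; align on union of columns
  cols <- unique(unlist(lapply(rows, names)))
  results <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    r[match(cols, names(r))])))
  names(results) <- cols
  best <- which.min(results$val_mae_deepest)
  list(best_config = grid[[best]], best_index = best, results = results)
}
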
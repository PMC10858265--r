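#' DNA shape feature registry
#'
#' Shape features describe the local geometry of the B-DNA double helix,
#' position by position. Three families are distinguished by where a value
#' lives on the molecule:
#'
#' * *inter-bp (step) features* -- `Shift`, `Slide`, `Rise` (translations,
#'   Angstrom) and `Tilt`, `Roll`, `HelT` (rotations, degrees) -- are defined
#'   between adjacent base pairs, so an n-mer carries n-1 values;
#' * *intra-bp features* -- `Shear`, `Stretch`, `Stagger` (Angstrom) and
#'   `Buckle`, `ProT`, `Opening` (degrees) -- are defined within one base
#'   pair (n values);
#' * *minor groove features* -- `MGW` (Angstrom) and `EP` (kT/e) -- describe
#'   groove geometry and electrostatics at the groove centre (n values, but
#'   undefined at the outermost base pairs).
#'
#' Every feature has a fluctuation companion written `<name>-FL`, the
#' variability of the feature across a conformational ensemble and a proxy
#' for local flexibility; an FL feature shares its parent's node kind and
#' units.
#'
#' `shape_features()` resolves a preset to its feature table;
#' `shape_feature()` looks up a single feature (case-sensitively).
#'
#' @param preset One of `"4shape"` (`MGW`, `ProT`, `Roll`, `HelT`),
#'   `"13shape"` (MGW plus the six inter-bp and six intra-bp features) or
#'   `"13shape+FL"` (those thirteen and their fluctuations).
#' @return A data frame with one row per feature and columns `name`,
#'   `node_kind` (`"bp"` or `"step"`), `units`, `rc_class` (`"invariant"` or
#'   `"sign-flip"`: behaviour under reverse complementation),
#'   `terminal_mask_margin` (count of undefined positions at each sequence
#'   end in training data) and `is_fluctuation`.
#' @examples
#' shape_features("4shape")$name
#' shape_feature("Roll")$node_kind
#' @export
shape_features <- function(preset = "13shape") {
  reg <- feature_registry()
  names13 <- c("MGW",
               "Shift", "Slide", "Rise", "Tilt", "Roll", "HelT",
               "Shear", "Stretch", "Stagger", "Buckle", "ProT", "Opening")
  sel <- switch(preset,
    "4shape"      = c("MGW", "ProT", "Roll", "HelT"),
    "13shape"     = names13,
    "13shape+FL"  = c(names13, paste0(names13, "-FL")),
    stop("unknown feature preset: '", preset, "'", call. = FALSE))
  reg[match(sel, reg$name), , drop = FALSE]
}

#' @rdname shape_features
#' @param name Feature name, e.g. `"MGW"` or `"Roll-FL"` (case-sensitive).
#' @export
shape_feature <- function(name) {
  reg <- feature_registry()
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown shape feature: '", name, "'", call. = FALSE)
  reg[i, , drop = FALSE]
}

# Full registry, built once. rc_class follows the standard helical-parameter
# convention: parameters defined with a 5'->3' handedness (Shift, Tilt among
# steps; Shear, Buckle within a pair) change sign when the strands are
# swapped, all others are invariant. Fluctuations are variances and hence
# always invariant. The table can be overridden feature-by-feature via
# options(deepshape.rc_class = c(Shift = "invariant", ...)).
feature_registry <- function() {
  step6  <- c("Shift", "Slide", "Rise", "Tilt", "Roll", "HelT")
  intra6 <- c("Shear", "Stretch", "Stagger", "Buckle", "ProT", "Opening")
  name   <- c("MGW", "EP", step6, intra6)
  units  <- c("Angstrom", "kT/e",
              "Angstrom", "Angstrom", "Angstrom", "degrees", "degrees", "degrees",
              "Angstrom", "Angstrom", "Angstrom", "degrees", "degrees", "degrees")
  node_kind <- c("bp", "bp", rep("step", 6), rep("bp", 6))
  rc_class  <- ifelse(name %in% c("Shift", "Tilt", "Shear", "Buckle"),
                      "sign-flip", "invariant")
  margin <- ifelse(name %in% c("MGW", "EP"), 2L, 0L)

  over <- getOption("deepshape.rc_class", NULL)
  if (!is.null(over)) {
    hit <- intersect(names(over), name)
    rc_class[match(hit, name)] <- unname(over[hit])
  }

  base <- data.frame(name = name, node_kind = node_kind, units = units,
                     rc_class = rc_class, terminal_mask_margin = margin,
                     is_fluctuation = FALSE, stringsAsFactors = FALSE)
  fl <- base
  fl$name <- paste0(base$name, "-FL")
  fl$rc_class <- "invariant"
  fl$is_fluctuation <- TRUE
  rbind(base, fl)
}

#' Normalization statistics for a shape feature
#'
#' Shape features span very different numeric ranges (fractions of an
#' Angstrom up to tens of degrees) and simulation data contain occasional
#' extreme artifacts. Model targets are therefore normalized as
#' \deqn{\hat S = (S - \tilde S) / (S_{99} - S_{1})}
#' where \eqn{\tilde S} is the median and \eqn{S_{1}}, \eqn{S_{99}} the 1st
#' and 99th percentiles of the pooled training values. Note the printed form
#' of this relation elsewhere divides by \eqn{(S_{1} - S_{99})}, which is
#' negative for ascending percentiles; this implementation uses the
#' orientation-preserving denominator \eqn{(S_{99} - S_{1})} so that larger
#' raw values always map to larger normalized values. Normalized values may
#' exceed \[-1, 1\] for extremes; the network's tanh output head is what
#' enforces a strict bound at prediction time.
#'
#' Percentiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`), fixed so that stats files are bit-exactly
#' reproducible.
#'
#' @param values Numeric vector of raw feature values; non-finite entries
#'   are dropped. At least two distinct finite values are required.
#' @return An object of class `"shape_norm_stats"`: list with `median`,
#'   `p1`, `p99`.
#' @examples
#' st <- compute_norm_stats(0:100)
#' st$median; st$p1; st$p99
#' normalize_shape(50, st)
#' @export
compute_norm_stats <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L || length(unique(v)) < 2L)
    stop("degenerate data: need at least 2 distinct finite values", call. = FALSE)
  q <- stats::quantile(v, c(0.01, 0.5, 0.99), names = FALSE, type = 7)
  st <- list(median = q[2L], p1 = q[1L], p99 = q[3L])
  class(st) <- "shape_norm_stats"
  st
}

check_stats <- function(stats) {
  if (!all(c("median", "p1", "p99") %in% names(stats)))
    stop("not a shape_norm_stats object", call. = FALSE)
  if (!isTRUE(stats$p99 - stats$p1 > 0))
    stop("degenerate normalization stats: p99 - p1 must be > 0", call. = FALSE)
  invisible(stats)
}

#' Normalize / denormalize shape values
#'
#' Applies (or inverts) the percentile normalization described in
#' [compute_norm_stats()]. The two functions are exact inverses.
#'
#' @param s Numeric vector of raw (resp. normalized) values; `NA` passes
#'   through, other non-finite values are an error.
#' @param stats A `"shape_norm_stats"` object.
#' @return Numeric vector of the same length.
#' @export
normalize_shape <- function(s, stats) {
  check_stats(stats)
  if (any(!is.finite(s) & !is.na(s)))
    stop("non-finite shape value", call. = FALSE)
  (s - stats$median) / (stats$p99 - stats$p1)
}

#' @rdname normalize_shape
#' @export
denormalize_shape <- function(s, stats) {
  check_stats(stats)
  if (any(!is.finite(s) & !is.na(s)))
    stop("non-finite shape value", call. = FALSE)
  s * (stats$p99 - stats$p1) + stats$median
}

#' @export
print.shape_norm_stats <- function(x, ...) {
  cat(sprintf("shape_norm_stats: median %.6g, p1 %.6g, p99 %.6g (range %.6g)\n",
              x$median, x$p1, x$p99, x$p99 - x$p1))
  invisible(x)
}

#' Reverse-complement transform of a per-position profile
#'
#' When a duplex is read from the opposite strand, a per-position shape
#' profile reverses its order, and features defined with a 5'-to-3'
#' handedness (rc_class `"sign-flip"`) additionally change sign. Applying
#' the transform twice returns the input. Used to symmetrize training data
#' and predictions: e.g. MGW, an invariant feature, must agree between a
#' sequence and its reverse complement after this transform.
#'
#' @param profile Numeric vector (may contain `NA` for masked positions).
#' @param spec A single-row feature table from [shape_feature()], or a
#'   feature name.
#' @param n_nodes Optional expected node count; defaults to
#'   `length(profile)`. Supply it to assert the profile matches a sequence's
#'   node count for the feature's node kind.
#' @return The transformed profile.
#' @export
rc_transform_profile <- function(profile, spec, n_nodes = length(profile)) {
  if (is.character(spec)) spec <- shape_feature(spec)
  if (length(profile) != n_nodes)
    stop("profile length ", length(profile), " does not match node count ",
         n_nodes, call. = FALSE)
  out <- rev(profile)
  if (identical(spec$rc_class, "sign-flip")) out <- -out
  out
}

#' Read and write normalization stats files
#'
#' Plain-text JSON, one record per feature with fields `name`, `median`,
#' `p1`, `p99`, serialized with 17 significant digits so that values
#' round-trip bit-exactly.
#'
#' @param stats_list Named list of `"shape_norm_stats"` objects (names are
#'   feature names).
#' @param path File path.
#' @return `read_norm_stats()` returns the named list; `write_norm_stats()`
#'   returns `path` invisibly.
#' @export
write_norm_stats <- function(stats_list, path) {
  recs <- lapply(names(stats_list), function(nm) {
    st <- check_stats(stats_list[[nm]])
    list(name = nm, median = st$median, p1 = st$p1, p99 = st$p99)
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  recs <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                             simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    st <- list(median = r$median, p1 = r$p1, p99 = r$p99)
    class(st) <- "shape_norm_stats"
    st
  })
  names(out) <- vapply(recs, `[[`, "", "name")
  out
}
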
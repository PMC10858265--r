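BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(t(outer(BASES, BASES, paste0)))  # AA AC AG AT CA ... TT

# Per-base channel probabilities: identity for ACGT, uniform for N.
base_probs <- function(chars, seq_string) {
  bad <- which(!chars %in% c(BASES, "N"))
  if (length(bad))
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         " in sequence '", seq_string, "'", call. = FALSE)
  m <- matrix(0, length(chars), 4L, dimnames = list(NULL, BASES))
  for (b in seq_along(BASES)) m[chars == BASES[b], b] <- 1
  m[chars == "N", ] <- 0.25
  m
}

split_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a single nonempty string", call. = FALSE)
  toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
}

new_encoded_seq <- function(matrix, node_kind, capped, source_length) {
  structure(list(matrix = matrix, node_kind = node_kind,
                 capped = capped, source_length = source_length),
            class = "encoded_seq")
}

#' One-hot sequence encodings over linked nodes
#'
#' A sequence is represented as a chain of nodes, each holding a one-hot
#' feature row. For per-base-pair features each nucleotide is a node with 4
#' channels (`A -> [1,0,0,0]`, `C -> [0,1,0,0]`, `G -> [0,0,1,0]`,
#' `T -> [0,0,0,1]`); for base-pair-step features each adjacent dinucleotide
#' is a node with 16 channels ordered alphabetically `AA, AC, ..., TT`. The
#' ambiguity code `N` encodes as the average over all compatible bases (or
#' dinucleotides), so every row always sums to 1.
#'
#' @param seq A single string over `A/C/G/T/N` (case-insensitive).
#' @return An `"encoded_seq"`: list with `matrix` (nodes x channels),
#'   `node_kind` (`"bp"` or `"step"`), `capped`, `source_length`.
#' @examples
#' encode_mono("ACGTGCG")$matrix
#' encode_di("AC")$matrix        # unit vector at channel "AC"
#' @export
encode_mono <- function(seq) {
  chars <- split_seq(seq)
  new_encoded_seq(base_probs(chars, seq), "bp", FALSE, length(chars))
}

#' @rdname encode_mono
#' @export
encode_di <- function(seq) {
  chars <- split_seq(seq)
  n <- length(chars)
  if (n < 2L)
    stop("dinucleotide encoding needs a sequence of length >= 2", call. = FALSE)
  p <- base_probs(chars, seq)
  # channel (b1, b2) sits at index 4*(b1-1)+b2; an N averages over its
  # compatible pure dinucleotides because the row is the outer product of
  # the two per-base probability vectors.
  m <- matrix(0, n - 1L, 16L, dimnames = list(NULL, DINUCS))
  for (b1 in 1:4) for (b2 in 1:4)
    m[, 4L * (b1 - 1L) + b2] <- p[-n, b1] * p[-1L, b2]
  new_encoded_seq(m, "step", FALSE, n)
}

#' Terminal N caps
#'
#' Terminal nodes of a bare chain have only one neighbour, which would give
#' sequence ends a different degree of freedom than interior positions. To
#' balance this, one uniform-composition "N cap" node is added at each end
#' before the network runs, and removed from the final prediction. A cap's
#' missing outer bond is connected to the cap itself (a self-link), so every
#' node -- caps included -- always has a 5' and a 3' neighbour, and
#' arbitrarily deep layer stacks see a stable boundary. For step encodings
#' the caps are uniform 16-channel "N-step" nodes.
#'
#' @param enc An `"encoded_seq"`.
#' @return The capped (resp. uncapped) `"encoded_seq"`.
#' @export
add_caps <- function(enc) {
  stopifnot(inherits(enc, "encoded_seq"))
  if (enc$capped) stop("sequence is already capped", call. = FALSE)
  nc <- ncol(enc$matrix)
  cap <- matrix(1 / nc, 1L, nc, dimnames = list(NULL, colnames(enc$matrix)))
  enc$matrix <- rbind(cap, enc$matrix, cap)
  enc$capped <- TRUE
  enc
}

#' @rdname add_caps
#' @export
strip_caps <- function(enc) {
  stopifnot(inherits(enc, "encoded_seq"))
  if (!enc$capped) stop("sequence is not capped", call. = FALSE)
  n <- nrow(enc$matrix)
  enc$matrix <- enc$matrix[-c(1L, n), , drop = FALSE]
  enc$capped <- FALSE
  enc
}

# Neighbour index vectors for one chain of n nodes. With caps the outermost
# nodes self-link; without caps the ends also self-link (degenerate chain),
# but the model always runs on capped chains.
neighbor_indices <- function(n) {
  list(prev = c(1L, seq_len(n - 1L)), nxt = c(seq_len(n - 1L) + 1L, n))
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("encoded_seq: %d-nt sequence, %d %s node(s) x %d channels%s\n",
              x$source_length, nrow(x$matrix), x$node_kind, ncol(x$matrix),
              if (x$capped) " (N-capped)" else ""))
  invisible(x)
}

#' Reverse complement of a sequence string
#'
#' @param seq String over `A/C/G/T/N`.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  chars <- split_seq(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bad <- which(!chars %in% names(comp))
  if (length(bad))
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  paste(rev(unname(comp[chars])), collapse = "")
}

#' Read sequences from FASTA
#'
#' Multi-record, wrapped-line FASTA via Biostrings; sequences are
#' upper-cased. `U` (RNA) is rejected; `N` is allowed.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (any(grepl("U", seqs, fixed = TRUE)))
    stop("RNA base 'U' found; DNA input required", call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record '", names(seqs)[which(bad)[1L]],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
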
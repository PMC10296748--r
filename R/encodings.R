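# Per-base lookup tables for the three static schemes. The integer scheme
# assigns the arbitrary values 1/3/2/4 to A/C/G/T; the atomic scheme uses the
# bases' atomic numbers (A 70, C 58, G 78, T 66); EIIP uses the electron-ion
# interaction pseudo-potentials (A 0.1260, C 0.1340, G 0.0806, T 0.1335).
STATIC_SCHEMES <- list(
  integer = c(A = 1, C = 3, G = 2, T = 4),
  atomic  = c(A = 70, C = 58, G = 78, T = 66),
  eiip    = c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
)

ENCODING_SCHEMES <- c("integer", "atomic", "eiip", "bfdna")

#' Theoretical min-max bounds of an encoding scheme
#'
#' The alphabet extremes of each scheme, used as the normalization basis so
#' that scaling is deterministic and identical across training and test data
#' (no per-dataset empirical bounds, hence no information leak across the
#' split).
#'
#' @param scheme One of \code{"integer"}, \code{"atomic"}, \code{"eiip"},
#'   \code{"bfdna"}.
#' @return Numeric vector \code{c(min, max)}.
#' @export
scheme_bounds <- function(scheme) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  switch(scheme,
    integer = c(1, 4),
    atomic  = c(58, 78),
    eiip    = c(0.0806, 0.1340),
    bfdna   = c(0, 1)
  )
}

encoded_sequence <- function(values, scheme, source_id) {
  structure(values, scheme = scheme, source_id = source_id,
            class = "encoded_sequence")
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat(sprintf("<encoded_sequence> scheme=%s source=%s length=%d\n",
              attr(x, "scheme"), attr(x, "source_id"), length(x)))
  print(as.numeric(x))
  invisible(x)
}

# Shared front-end of the static (positionwise) encoders. Ambiguity codes,
# permitted only in lenient mode, encode as 0 under every scheme.
encode_static <- function(seq, scheme, mode) {
  seq <- as_nt_sequence(seq)
  res <- validate_residues(seq, mode)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  map <- STATIC_SCHEMES[[scheme]]
  values <- unname(map[chars])
  values[is.na(values)] <- 0    # ambiguity codes (lenient mode only)
  encoded_sequence(values, scheme, seq$id)
}

#' Integer-number encoding of a DNA sequence
#'
#' Positionwise substitution A -> 1, C -> 3, G -> 2, T -> 4.
#'
#' @param seq An \code{\link{nt_sequence}} or a character scalar.
#' @param mode Residue validation mode; see \code{\link{validate_residues}}.
#'   In lenient mode ambiguity codes encode as 0.
#' @return An \code{encoded_sequence} (numeric vector tagged with the scheme
#'   and source id), same length as the input.
#' @examples
#' encode_integer("ACACCCAGGT")   # 1 3 1 3 3 3 1 2 2 4
#' @export
encode_integer <- function(seq, mode = c("strict", "lenient")) {
  encode_static(seq, "integer", match.arg(mode))
}

#' Atomic-number encoding of a DNA sequence
#'
#' Positionwise substitution by atomic number: A -> 70, C -> 58, G -> 78,
#' T -> 66.
#'
#' @inheritParams encode_integer
#' @return An \code{encoded_sequence}, same length as the input.
#' @examples
#' encode_atomic("ACACCCAGGT")    # 70 58 70 58 58 58 70 78 78 66
#' @export
encode_atomic <- function(seq, mode = c("strict", "lenient")) {
  encode_static(seq, "atomic", match.arg(mode))
}

#' EIIP encoding of a DNA sequence
#'
#' Positionwise substitution by electron-ion interaction pseudo-potential:
#' A -> 0.1260, C -> 0.1340, G -> 0.0806, T -> 0.1335.
#'
#' @inheritParams encode_integer
#' @return An \code{encoded_sequence}, same length as the input.
#' @examples
#' encode_eiip("ACACCCAGGT")
#' @export
encode_eiip <- function(seq, mode = c("strict", "lenient")) {
  encode_static(seq, "eiip", match.arg(mode))
}

#' Base repetition frequencies of a sequence
#'
#' The relative frequency of each of the four bases: count divided by the
#' total sequence length. For pure-A/C/G/T input the four entries sum to 1.
#' In lenient mode, ambiguity codes are excluded from the numerators but kept
#' in the length denominator, so the total sequence length stays literal.
#'
#' @inheritParams encode_integer
#' @return Named numeric vector \code{c(A=, C=, G=, T=)}.
#' @examples
#' base_frequencies("ACACCCAGGT")  # A 0.3, C 0.4, G 0.2, T 0.1
#' @export
base_frequencies <- function(seq, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  seq <- as_nt_sequence(seq)
  res <- validate_residues(seq, mode)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("cannot compute base frequencies of an empty sequence",
                    call. = FALSE)
  counts <- tabulate(factor(chars, levels = BASES), nbins = 4L)
  stats::setNames(counts / n, BASES)
}

#' BFDNA (base-frequency) encoding of a DNA sequence
#'
#' The dynamic encoding scheme: every position takes the relative frequency
#' (count / total length) of its own base within that same sequence. Unlike
#' the static schemes, the value assigned to a base therefore depends on the
#' whole sequence, and all values lie in [0, 1].
#'
#' @inheritParams encode_integer
#' @return An \code{encoded_sequence}, same length as the input. Ambiguous
#'   positions (lenient mode) encode as 0.
#' @examples
#' encode_bfdna("ACACCCAGGT")   # 0.3 0.4 0.3 0.4 0.4 0.4 0.3 0.2 0.2 0.1
#' @export
encode_bfdna <- function(seq, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  seq <- as_nt_sequence(seq)
  freqs <- base_frequencies(seq, mode)
  chars <- strsplit(validate_residues(seq, mode), "", fixed = TRUE)[[1]]
  values <- unname(freqs[chars])
  values[is.na(values)] <- 0    # ambiguity codes
  encoded_sequence(values, "bfdna", seq$id)
}

#' Encode a sequence under a named scheme
#'
#' @inheritParams encode_integer
#' @param scheme One of \code{"integer"}, \code{"atomic"}, \code{"eiip"},
#'   \code{"bfdna"}.
#' @return An \code{encoded_sequence}.
#' @export
encode_sequence <- function(seq, scheme, mode = c("strict", "lenient")) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  mode <- match.arg(mode)
  switch(scheme,
    integer = encode_integer(seq, mode),
    atomic  = encode_atomic(seq, mode),
    eiip    = encode_eiip(seq, mode),
    bfdna   = encode_bfdna(seq, mode)
  )
}

#' Min-max normalize an encoded sequence
#'
#' Maps every value to \code{(v - min) / (max - min)}. By default the bounds
#' are the scheme's theoretical extremes (see \code{\link{scheme_bounds}}).
#'
#' @param encoded An \code{encoded_sequence} or plain numeric vector.
#' @param bounds Numeric \code{c(min, max)} with \code{min < max}; defaults
#'   to the scheme extremes when \code{encoded} carries a scheme tag.
#' @return Normalized vector (an \code{encoded_sequence} if the input was
#'   one).
#' @export
minmax_normalize <- function(encoded, bounds = NULL) {
  if (is.null(bounds)) {
    scheme <- attr(encoded, "scheme")
    if (is.null(scheme))
      stop("bounds must be given for untagged numeric input", call. = FALSE)
    bounds <- scheme_bounds(scheme)
  }
  if (length(bounds) != 2L || !is.finite(bounds[1]) || !is.finite(bounds[2]))
    stop("bounds must be two finite numbers", call. = FALSE)
  if (bounds[1] >= bounds[2])
    stop("degenerate bounds: min must be strictly below max", call. = FALSE)
  values <- (as.numeric(encoded) - bounds[1]) / (bounds[2] - bounds[1])
  if (inherits(encoded, "encoded_sequence")) {
    encoded_sequence(values, attr(encoded, "scheme"),
                     attr(encoded, "source_id"))
  } else values
}

#' Pad or truncate an encoded sequence to a fixed length
#'
#' Truncation keeps the 5' prefix; padding appends \code{pad_value} at the 3'
#' end. The fixed length is required by the flatten-then-dense stage of the
#' classifier.
#'
#' @param encoded Numeric vector or \code{encoded_sequence}.
#' @param target_length Positive integer.
#' @param pad_value Value appended when the input is short (default 0).
#' @return Vector of length \code{target_length}.
#' @export
pad_or_truncate <- function(encoded, target_length, pad_value = 0) {
  stopifnot(length(target_length) == 1L, target_length >= 1)
  values <- as.numeric(encoded)
  out <- if (length(values) >= target_length) {
    values[seq_len(target_length)]
  } else {
    c(values, rep(pad_value, target_length - length(values)))
  }
  if (inherits(encoded, "encoded_sequence")) {
    encoded_sequence(out, attr(encoded, "scheme"), attr(encoded, "source_id"))
  } else out
}

#' Encode a whole dataset into a fixed-width numeric matrix
#'
#' The model-input pipeline: each sequence is encoded at its full length
#' (BFDNA denominators always use the original sequence length), min-max
#' normalized against the scheme extremes, ambiguous positions zeroed, and
#' finally padded/truncated to \code{input_length}.
#'
#' @param dataset A \code{\link{dna_dataset}}.
#' @param scheme Encoding scheme name.
#' @param input_length Fixed model input length (default 1024; sequences in
#'   scope carry at least ~1000 bases).
#' @param normalize Apply min-max normalization (default \code{TRUE}).
#' @param mode Residue validation mode.
#' @param pad_value Pad value applied after normalization (default 0).
#' @return Numeric matrix, one row per sequence (rownames = ids), with
#'   attributes \code{scheme} and \code{labels}.
#' @export
encode_matrix <- function(dataset, scheme, input_length = 1024,
                          normalize = TRUE, mode = c("strict", "lenient"),
                          pad_value = 0) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "dna_dataset"), nrow(dataset) > 0L)
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    enc <- encode_sequence(nt_sequence(dataset$sequence[i], dataset$id[i],
                                       dataset$label[i]), scheme, mode)
    amb <- which(as.numeric(enc) == 0 & scheme != "bfdna")
    v <- if (normalize) minmax_normalize(enc) else enc
    v <- as.numeric(v)
    if (mode == "lenient" && scheme %in% c("integer", "atomic", "eiip")) {
      # ambiguous positions carry the pad value on the normalized scale
      v[amb] <- pad_value
    }
    pad_or_truncate(v, input_length, pad_value)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- dataset$id
  attr(m, "scheme") <- scheme
  attr(m, "labels") <- dataset$label
  m
}
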
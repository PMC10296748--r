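# IUPAC one-letter codes beyond the four unambiguous bases
AMBIGUITY_CODES <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
BASES <- c("A", "C", "G", "T")

#' Create a labeled nucleotide sequence
#'
#' A lightweight container for one DNA sequence: an identifier, the residue
#' string, and an optional class label (e.g. \code{"human_enhancer"}).
#' Residues are upper-cased on construction; validation against the allowed
#' alphabet happens in \code{\link{validate_residues}} (called by every
#' encoder).
#'
#' @param residues Character scalar of nucleotide symbols.
#' @param id Free-text identifier (defaults to \code{"seq1"}).
#' @param label Optional class label, or \code{NA}.
#' @return An object of class \code{nt_sequence}.
#' @examples
#' nt_sequence("ACACCCAGGT", id = "demo")
#' @export
nt_sequence <- function(residues, id = "seq1", label = NA_character_) {
  stopifnot(is.character(residues), length(residues) == 1L)
  structure(
    list(id = as.character(id), residues = toupper(residues),
         label = as.character(label)),
    class = "nt_sequence"
  )
}

#' @export
print.nt_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nt_sequence> %s [%d nt]%s\n  %s\n", x$id, n,
              if (is.na(x$label)) "" else paste0(" label=", x$label), shown))
  invisible(x)
}

#' @export
length.nt_sequence <- function(x) nchar(x$residues)

# Coerce character input to nt_sequence where convenient.
as_nt_sequence <- function(x, id = "seq1") {
  if (inherits(x, "nt_sequence")) return(x)
  nt_sequence(x, id = id)
}

#' Validate the residues of a sequence
#'
#' Case-folds and checks every symbol. In \code{"strict"} mode only A/C/G/T
#' are accepted; in \code{"lenient"} mode IUPAC ambiguity codes (N, R, Y, S,
#' W, K, M, B, D, H, V) are additionally allowed and are handled downstream
#' by the encoders. Symbols outside the IUPAC alphabet are always rejected.
#'
#' @param residues Character scalar (or \code{nt_sequence}).
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return The upper-cased residue string, invisibly usable downstream.
#' @export
validate_residues <- function(residues, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (inherits(residues, "nt_sequence")) residues <- residues$residues
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(residues)
  if (nchar(res) == 0L) stop("sequence is empty", call. = FALSE)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  allowed <- if (mode == "strict") BASES else c(BASES, AMBIGUITY_CODES)
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf("invalid symbol '%s' at position %d (mode = %s)",
                 chars[bad[1]], bad[1], mode), call. = FALSE)
  }
  res
}

#' Assemble a labeled DNA dataset
#'
#' The tabular container used throughout the package: one row per sequence
#' with columns \code{id}, \code{sequence}, \code{label}. Identifiers must be
#' unique and every sequence must carry exactly one label.
#'
#' @param ids Character vector of unique identifiers.
#' @param sequences Character vector of residue strings (case preserved; the
#'   encoders fold case themselves).
#' @param labels Character vector of class labels.
#' @return A \code{data.frame} with class \code{dna_dataset}.
#' @export
dna_dataset <- function(ids, sequences, labels) {
  ids <- as.character(ids); sequences <- as.character(sequences)
  labels <- as.character(labels)
  if (length(ids) != length(sequences) || length(ids) != length(labels))
    stop("ids, sequences and labels must have equal length", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  if (anyNA(labels) || any(labels == ""))
    stop(sprintf("sequence(s) with no resolvable label: %s",
                 paste(ids[is.na(labels) | labels == ""], collapse = ", ")),
         call. = FALSE)
  structure(
    data.frame(id = ids, sequence = sequences, label = labels,
               stringsAsFactors = FALSE),
    class = c("dna_dataset", "data.frame")
  )
}

#' @export
print.dna_dataset <- function(x, ...) {
  cat(sprintf("<dna_dataset> %d sequences, %d class(es): %s\n",
              nrow(x), length(unique(x$label)),
              paste(sort(unique(x$label)), collapse = ", ")))
  NextMethod()
}
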
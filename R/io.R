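#' Read a labeled FASTA file
#'
#' Standard FASTA (wrapped or unwrapped lines) parsed with
#' \pkg{Biostrings}. Labels are resolved from one of two dialects: headers
#' of the form \code{"identifier|label"}, or a two-column tab-separated
#' sidecar file (\code{id \\t label}). Sequence case is preserved at the I/O
#' layer; case folding happens in the encoders.
#'
#' A third, best-effort dialect, \code{"vista"}, maps VISTA Enhancer
#' Browser-style headers (\code{>Human|chr16:86430087-86430726 | element 1 |
#' positive | ...}) to the package's scenario labels: species plus a
#' \code{positive} activity flag become \code{human_enhancer} or
#' \code{mouse_enhancer}, and \code{negative} becomes \code{no_enhancer}.
#' Coordinates are carried as the opaque identifier. Export formats vary;
#' this parser is tolerant rather than authoritative.
#'
#' @param path FASTA file path.
#' @param label_dialect \code{"header"}, \code{"sidecar"}, or \code{"vista"}.
#' @param sidecar_path Label table path; defaults to \code{<path>.labels.tsv}.
#' @return A \code{\link{dna_dataset}} in file order, with a
#'   \code{provenance} attribute recording the source path and dialect.
#' @export
read_fasta <- function(path, label_dialect = c("header", "sidecar", "vista"),
                       sidecar_path = NULL) {
  label_dialect <- match.arg(label_dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) > 0 && !startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA: sequence data before any header at line %d",
                 nonblank[1]), call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  seqs <- as.character(set)
  if (label_dialect == "vista") {
    fields <- lapply(strsplit(headers, "|", fixed = TRUE), trimws)
    species <- tolower(vapply(fields, `[`, character(1), 1))
    coord <- vapply(fields, function(f)
      if (length(f) >= 2) f[2] else f[1], character(1))
    activity <- vapply(fields, function(f) {
      hit <- grep("^(positive|negative)$", tolower(f), value = TRUE)
      if (length(hit) >= 1) hit[1] else NA_character_
    }, character(1))
    labels <- ifelse(activity == "negative", "no_enhancer",
              ifelse(species == "human", "human_enhancer",
              ifelse(species == "mouse", "mouse_enhancer", NA_character_)))
    labels[is.na(activity)] <- NA_character_
    ids <- coord
  } else if (label_dialect == "header") {
    ids <- sub("\\|.*$", "", headers)
    labels <- ifelse(grepl("|", headers, fixed = TRUE),
                     sub("^[^|]*\\|", "", headers), NA_character_)
    labels <- sub("\\|.*$", "", labels)  # first label field only
  } else {
    if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".labels.tsv")
    tab <- read_label_sidecar(sidecar_path)
    ids <- sub("\\s.*$", "", headers)
    labels <- tab$label[match(ids, tab$id)]
  }
  missing <- ids[is.na(labels) | labels == ""]
  if (length(missing) > 0)
    stop(sprintf("sequence(s) with no resolvable label: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ds <- dna_dataset(ids, seqs, labels)
  attr(ds, "provenance") <- list(source = path, dialect = label_dialect)
  ds
}

#' Write a labeled dataset as FASTA
#'
#' Headers carry the label in the \code{"id|label"} dialect; sequence lines
#' are wrapped at \code{line_width}. Output bytes are deterministic for a
#' fixed dataset.
#'
#' @param dataset A \code{\link{dna_dataset}}.
#' @param path Output path.
#' @param line_width Characters per sequence line (default 60).
#' @param sidecar Also write a \code{<path>.labels.tsv} label table.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(dataset, path, line_width = 60, sidecar = FALSE) {
  stopifnot(inherits(dataset, "dna_dataset"), line_width >= 1)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset))) {
    writeLines(sprintf(">%s|%s", dataset$id[i], dataset$label[i]), con)
    s <- dataset$sequence[i]
    starts <- seq(1, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1, nchar(s))),
               con)
  }
  if (sidecar) write_label_sidecar(dataset, paste0(path, ".labels.tsv"))
  invisible(path)
}

#' Read a two-column (id, label) tab-separated label table
#' @param path TSV path (no header row).
#' @return Data frame with columns \code{id}, \code{label}.
#' @export
read_label_sidecar <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such label file: %s", path),
                               call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = "character", quote = "")
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label table", call. = FALSE)
  tab
}

#' Write the (id, label) sidecar table for a dataset
#' @param dataset A \code{\link{dna_dataset}}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_label_sidecar <- function(dataset, path) {
  utils::write.table(dataset[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an encoded matrix as CSV with a companion manifest
#'
#' One row per sequence (row names = ids). The manifest is a small JSON
#' file naming the scheme, dimensions and normalization so downstream tools
#' can interpret the matrix without guessing.
#'
#' @param mat Matrix from \code{\link{encode_matrix}}.
#' @param path Output CSV path; the manifest goes to \code{<path>.manifest.json}.
#' @return Invisibly, \code{path}.
#' @export
write_encoded_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  manifest <- list(scheme = attr(mat, "scheme"), n_sequences = nrow(mat),
                   input_length = ncol(mat),
                   labels = as.list(table(attr(mat, "labels"))))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

CONFIG_DEFAULTS <- list(
  scheme = "bfdna",
  scenario = 1,
  seed = 42,
  mode = "strict",
  scaled_down = TRUE,
  splits = list(train = 0.70, validation = 0.15, test = 0.15),
  training = list(epochs = NULL, batch_size = 32, learning_rate = 1e-3),
  model = list(input_length = NULL, recurrent_units = NULL,
               dropout_rates = NULL, dense_units = NULL),
  data = list(input = NULL, labels = NULL, label_dialect = "header",
              preset = NULL, n_per_class = 300,
              length_range = c(1000, 3000)),
  out = NULL
)

merge_config <- function(defaults, given, prefix = "") {
  for (key in names(given)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: %s", full), call. = FALSE)
    if (is.list(defaults[[key]]) && is.list(given[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], given[[key]], full)
    } else {
      defaults[[key]] <- given[[key]]
    }
  }
  defaults
}

#' Load and validate a run-configuration file
#'
#' YAML configuration with a strict schema: unknown keys are an error, enum
#' fields are checked, and split fractions must sum to 1. Defaults are
#' applied for anything not given, and the full effective configuration is
#' returned (and echoed by the command-line tools for provenance).
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @param overrides Optional named list merged on top of the file.
#' @return The effective configuration list (class \code{bfdna_config}).
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                                 call. = FALSE)
    given <- yaml::read_yaml(path)
    if (!is.null(given)) cfg <- merge_config(cfg, given)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  if (!cfg$scheme %in% ENCODING_SCHEMES)
    stop(sprintf("invalid scheme '%s' (expected one of %s)", cfg$scheme,
                 paste(ENCODING_SCHEMES, collapse = ", ")), call. = FALSE)
  if (!cfg$scenario %in% c(1, 2))
    stop("invalid scenario (expected 1 or 2)", call. = FALSE)
  if (!cfg$mode %in% c("strict", "lenient"))
    stop("invalid mode (expected strict or lenient)", call. = FALSE)
  sp <- unlist(cfg$splits)
  if (abs(sum(sp) - 1) > 1e-9)
    stop(sprintf("split fractions must sum to 1 (got %s = %.3f)",
                 paste(sp, collapse = " + "), sum(sp)), call. = FALSE)
  if (is.null(cfg$training$epochs))
    cfg$training$epochs <- if (isTRUE(cfg$scaled_down)) 15 else 500
  structure(cfg, class = "bfdna_config")
}

config_split <- function(cfg) {
  unname(unlist(cfg$splits)[c("train", "validation", "test")])
}
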
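# Preset per-class base compositions (A, C, G, T). BFDNA maps a position to
# its base's within-sequence frequency, so two compositions that are
# permutations of each other would yield identical BFDNA value
# distributions; the presets below therefore differ in composition *and* in
# their frequency spectra, so every in-scope encoding can see the class
# signal. "none" is the null preset (identical classes) used for
# chance-level guards.
PRESET_COMPOSITIONS <- list(
  strong = list(
    human_enhancer = c(A = 0.40, C = 0.30, G = 0.20, T = 0.10),
    mouse_enhancer = c(A = 0.10, C = 0.15, G = 0.55, T = 0.20),
    no_enhancer    = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  ),
  moderate = list(
    human_enhancer = c(A = 0.30, C = 0.28, G = 0.22, T = 0.20),
    mouse_enhancer = c(A = 0.22, C = 0.24, G = 0.30, T = 0.24),
    no_enhancer    = c(A = 0.25, C = 0.27, G = 0.23, T = 0.25)
  ),
  none = list(
    human_enhancer = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    mouse_enhancer = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    no_enhancer    = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  )
)

#' Configuration for a synthetic labeled-sequence dataset
#'
#' Describes an enhancer-like dataset: per-class nucleotide composition
#' vectors, a uniform length distribution, class sizes, and a seed. The
#' generator draws each position i.i.d. from its class composition — enough
#' structure for every composition- or identity-driven encoding, with no
#' attempt to simulate enhancer motifs or conservation.
#'
#' @param compositions Named list (one entry per class) of length-4
#'   probability vectors over A, C, G, T, each summing to 1.
#' @param length_range Integer \code{c(min, max)}; lengths are uniform on
#'   this range (default 1000-3000, matching enhancer-scale elements).
#' @param n_per_class Sequences per class (default 300).
#' @param seed Integer seed (default 42).
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(compositions, length_range = c(1000, 3000),
                             n_per_class = 300, seed = 42) {
  stopifnot(is.list(compositions), length(compositions) >= 1,
            !is.null(names(compositions)))
  for (nm in names(compositions)) {
    p <- compositions[[nm]]
    if (length(p) != 4 || any(p < 0) || sum(p) == 0)
      stop(sprintf("degenerate composition for class '%s'", nm),
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("composition for class '%s' must sum to 1", nm),
           call. = FALSE)
  }
  stopifnot(length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  if (n_per_class < 1) stop("n_per_class must be positive", call. = FALSE)
  structure(list(compositions = compositions,
                 n_classes = length(compositions),
                 length_range = as.integer(length_range),
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed),
                 class_names = names(compositions)),
            class = "synthetic_config")
}

#' Preset separable dataset configurations
#'
#' \code{"strong"}: class compositions differing by at least 0.15 in two or
#' more bases, with distinct frequency spectra, so classifiers should
#' approach perfect separation. \code{"moderate"}: smaller compositional
#' shifts. \code{"none"}: identical (uniform) compositions — the null
#' dataset for chance-level tests.
#'
#' @param level \code{"strong"}, \code{"moderate"}, or \code{"none"}.
#' @param n_classes 2 (human/mouse enhancer) or 3 (adds no_enhancer).
#' @param ... Passed to \code{\link{synthetic_config}} (e.g.
#'   \code{n_per_class}, \code{length_range}, \code{seed}).
#' @return A \code{synthetic_config}.
#' @export
preset_separable <- function(level = c("strong", "moderate", "none"),
                             n_classes = 2, ...) {
  level <- match.arg(level)
  stopifnot(n_classes %in% c(2, 3))
  comps <- PRESET_COMPOSITIONS[[level]][seq_len(n_classes)]
  synthetic_config(comps, ...)
}

#' Generate a labeled synthetic dataset
#'
#' Each sequence's length is drawn uniformly from the configured range and
#' its residues i.i.d. from the class composition. Output is deterministic
#' under the configured seed.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A \code{\link{dna_dataset}} with ids \code{<class>_<i>}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ids <- character(0); seqs <- character(0); labels <- character(0)
  for (cl in config$class_names) {
    p <- config$compositions[[cl]]
    span <- config$length_range[2] - config$length_range[1] + 1L
    lens <- config$length_range[1] +
      sample.int(span, config$n_per_class, replace = TRUE) - 1L
    s <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    ids <- c(ids, sprintf("%s_%04d", cl, seq_len(config$n_per_class)))
    seqs <- c(seqs, s)
    labels <- c(labels, rep(cl, config$n_per_class))
  }
  dna_dataset(ids, seqs, labels)
}
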
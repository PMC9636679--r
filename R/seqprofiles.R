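# Single-sequence utilities: hydropathy profiles, point-mutation
# application and average molecular weight.

# Kyte-Doolittle hydropathy scale (positive = hydrophobic).
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
               L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
               S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Average (not monoisotopic) residue masses in Da, i.e. amino acid minus
# water; matches SDS-PAGE-style kDa estimates.
.AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

#' Look up a named hydropathy scale
#'
#' @param name Scale identifier; currently `"kd"` (Kyte-Doolittle).
#' @return Named numeric vector mapping residue letters to scale values.
#' @export
hydropathy_scale <- function(name = "kd") {
  switch(name,
         kd = .KD_SCALE,
         stop("unknown hydropathy scale: ", name))
}

#' Parse a point-mutation specification string
#'
#' Accepts tokens of the form `"L91A"` (wild-type residue, 1-based
#' position, replacement residue) separated by '/', ',' or ';', e.g. the
#' leucine-to-alanine set `"L91A/T92A/L94A/L99A/L100A"`.
#'
#' @param text Mutation string.
#' @return An object of class `mutation_spec`: a data.frame with columns
#'   `wt`, `pos`, `mut`, sorted by position.
#' @export
parse_mutations <- function(text) {
  tokens <- strsplit(text, "[/,;]")[[1L]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("bad mutation token: empty specification")
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop("bad mutation token: '", tokens[bad][1L], "'")
  edits <- data.frame(
    wt = toupper(vapply(m, `[[`, character(1L), 2L)),
    pos = as.integer(vapply(m, `[[`, character(1L), 3L)),
    mut = toupper(vapply(m, `[[`, character(1L), 4L)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(edits$pos))
    stop("duplicate edit at position ",
         edits$pos[duplicated(edits$pos)][1L])
  edits <- edits[order(edits$pos), , drop = FALSE]
  rownames(edits) <- NULL
  class(edits) <- c("mutation_spec", "data.frame")
  edits
}

#' Apply point mutations to a residue sequence
#'
#' Each edit's wild-type letter is checked against the sequence before
#' substitution, so a mis-numbered specification fails loudly rather than
#' silently editing the wrong residue.
#'
#' @param seq Residue string (ungapped).
#' @param spec A `mutation_spec` (or a string parseable by
#'   [parse_mutations()]).
#' @return The mutated sequence; differs from the input at exactly the
#'   edit positions.
#' @examples
#' apply_mutations("MAEL", "L4A")
#' @export
apply_mutations <- function(seq, spec) {
  if (is.character(spec)) spec <- parse_mutations(spec)
  stopifnot(inherits(spec, "mutation_spec"))
  letters_s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (any(spec$pos > length(letters_s)))
    stop("edit position ", max(spec$pos), " beyond sequence length ",
         length(letters_s))
  found <- letters_s[spec$pos]
  bad <- which(found != spec$wt)
  if (length(bad)) {
    b <- bad[1L]
    stop("reference residue mismatch at position ", spec$pos[b],
         ": expected ", spec$wt[b], ", found ", found[b])
  }
  letters_s[spec$pos] <- spec$mut
  paste(letters_s, collapse = "")
}

#' Reverse a mutation specification
#'
#' Swaps wild-type and replacement letters so that applying the result
#' undoes the original edits.
#'
#' @param spec A `mutation_spec`.
#' @return The reversed `mutation_spec`.
#' @export
reverse_mutations <- function(spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  out <- data.frame(wt = spec$mut, pos = spec$pos, mut = spec$wt,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_spec", "data.frame")
  out
}

#' Sliding-window hydropathy profile
#'
#' Unweighted mean of per-residue scale values over an odd-length window.
#' Only full windows are scored: the profile covers center positions
#' `ceiling(w/2) .. L - floor(w/2)` and has length `L - w + 1`; no edge
#' padding is invented.
#'
#' @param seq Residue string (ungapped).
#' @param window Odd window length (default 9, the common protein-scale
#'   default).
#' @param scale Named residue-to-value vector, or a scale name accepted by
#'   [hydropathy_scale()].
#' @return An object of class `hydropathy_profile`: a data.frame with
#'   1-based window-center `position` and mean `value`; attributes
#'   `window` and `scale_name`.
#' @examples
#' hydropathy(strrep("A", 20), window = 9)$value[1]  # constant 1.8
#' @export
hydropathy <- function(seq, window = 9L, scale = "kd") {
  scale_name <- if (is.character(scale) && length(scale) == 1L) scale else "custom"
  if (is.character(scale) && length(scale) == 1L) scale <- hydropathy_scale(scale)
  window <- as.integer(window)
  letters_s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(letters_s)
  if (window %% 2L == 0L || window < 1L) stop("window must be odd and >= 1")
  if (window > L) stop("window too large: ", window, " > sequence length ", L)
  unscored <- setdiff(unique(letters_s), names(scale))
  if (length(unscored))
    stop("unscored residue: ", paste(unscored, collapse = ","))
  vals <- unname(scale[letters_s])
  half <- window %/% 2L
  means <- stats::filter(vals, rep(1 / window, window), sides = 2)
  centers <- (half + 1L):(L - half)
  out <- data.frame(position = centers, value = as.numeric(means[centers]))
  structure(out, window = window, scale_name = scale_name,
            class = c("hydropathy_profile", "data.frame"))
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water mass, reported in kDa.
#'
#' @param seq Residue string of standard amino acids.
#' @return Molecular weight in kDa.
#' @examples
#' molecular_weight("G")  # glycine, about 0.075 kDa
#' @export
molecular_weight <- function(seq) {
  letters_s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(letters_s) == 0L) stop("empty sequence")
  unknown <- setdiff(unique(letters_s), names(.AVG_RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue: ", paste(unknown, collapse = ","))
  (sum(.AVG_RESIDUE_MASS[letters_s]) + .WATER_MASS) / 1000
}
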
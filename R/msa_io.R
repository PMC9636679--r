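# Aligned-set container and alignment I/O.
#
# An aligned_set is the parsed protein MSA: rows are orthologue sequences,
# columns are alignment positions. Residues are uppercase; '-' is the only
# gap character ('.' is normalized to '-' at parse time).

.STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

#' Construct an aligned sequence set
#'
#' Builds the package's MSA container from parallel vectors of record
#' identifiers and aligned (gapped) sequence strings. All rows must have
#' equal length; letters are uppercased and '.' gaps normalized to '-'.
#'
#' @param ids Character vector of record identifiers.
#' @param rows Character vector of aligned sequences, same length as `ids`.
#' @param strict Logical; if `TRUE`, nonstandard residue letters
#'   (B, J, O, U, X, Z) are rejected instead of warned about.
#' @return An object of class `aligned_set` with elements `ids`, `rows`,
#'   `n_sp` (number of sequences) and `length` (alignment column count).
#' @examples
#' msa <- aligned_set(c("a", "b"), c("ML-K", "MLQK"))
#' msa$n_sp
#' @export
aligned_set <- function(ids, rows, strict = FALSE) {
  if (length(ids) != length(rows))
    stop("ids and rows must have equal length")
  if (length(rows) < 1L)
    stop("no records")
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: record lengths ", paste(unique(widths), collapse = ", "))
  ok <- c(.STANDARD_AA, if (!strict) .NONSTANDARD_AA, "-")
  for (j in seq_along(rows)) {
    letters_j <- strsplit(rows[[j]], "", fixed = TRUE)[[1L]]
    bad <- which(!(letters_j %in% ok))
    if (length(bad)) {
      stop("invalid symbol '", letters_j[bad[1L]], "' in record '", ids[[j]],
           "' at column ", bad[1L])
    }
    ns <- which(letters_j %in% .NONSTANDARD_AA)
    if (length(ns) && !strict) {
      warning("nonstandard residue letter(s) ",
              paste(unique(letters_j[ns]), collapse = ","),
              " in record '", ids[[j]], "' counted as their own categories")
    }
  }
  structure(
    list(ids = ids, rows = rows, n_sp = length(rows), length = widths[[1L]]),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", x$n_sp, "sequences x", x$length, "columns\n")
  show <- utils::head(x$ids, 5L)
  cat("  ids:", paste(show, collapse = ", "),
      if (x$n_sp > 5L) "..." else "", "\n")
  invisible(x)
}

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' Parses a multi-record FASTA file whose records are already aligned
#' (equal lengths, gaps as '-' or '.'). Record order is preserved and
#' letters are uppercased.
#'
#' @param path Path to an aligned FASTA file.
#' @param strict Logical; reject nonstandard residue letters if `TRUE`.
#' @return An `aligned_set`.
#' @export
read_msa <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in ", path)
  ids <- names(recs)
  # FASTA descriptions: keep the first whitespace-delimited token as the id
  ids <- vapply(strsplit(ids, "[ \t]+"), `[[`, character(1L), 1L)
  aligned_set(ids, as.character(recs), strict = strict)
}

#' Write an aligned set back to FASTA
#'
#' @param msa An `aligned_set`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, width = 60L) {
  stopifnot(inherits(msa, "aligned_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(msa$n_sp)) {
    writeLines(paste0(">", msa$ids[[j]]), con)
    s <- msa$rows[[j]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Census one alignment column
#'
#' Counts residues (gaps excluded) at column `i` and builds the
#' rank-ordered abundance spectrum: distinct residues are ranked by count,
#' descending, ties broken alphabetically; the rank-r residue carries
#' difference d = r (0-based, most abundant residue has d = 0) and
#' abundance N_i(d) equal to its sequence count. Diversity D is the number
#' of distinct residues, so d ranges over 0..D-1.
#'
#' @param msa An `aligned_set`.
#' @param i 1-based alignment column index.
#' @return An object of class `column_census`: list with `column`, `counts`
#'   (named integer vector), `gap_count`, `diversity`, `spectrum` (a
#'   data.frame with columns `d`, `residue`, `count`), `n_effective`
#'   (non-gap count) and `all_gap` flag. An all-gap column yields
#'   diversity 0 and an empty spectrum, flagged rather than an error.
#' @examples
#' msa <- aligned_set(c("a", "b"), c("ML-K", "MLQK"))
#' column_census(msa, 3)$gap_count
#' @export
column_census <- function(msa, i) {
  stopifnot(inherits(msa, "aligned_set"))
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > msa$length)
    stop("column out of range: ", i)
  chars <- substr(msa$rows, i, i)
  gaps <- chars == "-"
  res <- chars[!gaps]
  if (length(res) == 0L) {
    census <- list(column = i, counts = integer(0), gap_count = sum(gaps),
                   diversity = 0L,
                   spectrum = data.frame(d = integer(0),
                                         residue = character(0),
                                         count = integer(0)),
                   n_effective = 0L, all_gap = TRUE)
    class(census) <- "column_census"
    return(census)
  }
  tab <- table(res)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  spectrum <- data.frame(d = seq_along(counts) - 1L,
                         residue = names(counts),
                         count = unname(counts),
                         stringsAsFactors = FALSE)
  census <- list(column = i, counts = counts, gap_count = sum(gaps),
                 diversity = length(counts), spectrum = spectrum,
                 n_effective = length(res), all_gap = FALSE)
  class(census) <- "column_census"
  census
}

#' Map alignment columns to ungapped reference numbering
#'
#' Builds the bijection between alignment columns where the reference row
#' is non-gap and 1-based residue positions of the ungapped reference
#' sequence (matching residue nomenclature such as "L91").
#'
#' @param msa An `aligned_set`.
#' @param reference_id Identifier of the reference record in `msa$ids`.
#' @return An object of class `coordinate_map`: list with `reference_id`,
#'   `col_to_ref` (integer vector over alignment columns, `NA` where the
#'   reference has a gap) and `ref_to_col` (strictly increasing integer
#'   vector over reference positions).
#' @export
build_coordinate_map <- function(msa, reference_id) {
  stopifnot(inherits(msa, "aligned_set"))
  j <- match(reference_id, msa$ids)
  if (is.na(j)) stop("reference not found: ", reference_id)
  letters_ref <- strsplit(msa$rows[[j]], "", fixed = TRUE)[[1L]]
  nongap <- letters_ref != "-"
  col_to_ref <- rep(NA_integer_, msa$length)
  col_to_ref[nongap] <- seq_len(sum(nongap))
  structure(
    list(reference_id = reference_id,
         col_to_ref = col_to_ref,
         ref_to_col = which(nongap)),
    class = "coordinate_map"
  )
}

#' Tabulate an alignment column-by-column
#'
#' Emits one row per alignment column with one cell per sequence — the
#' spreadsheet view of the MSA.
#'
#' @param msa An `aligned_set`.
#' @return A data.frame with `length` rows: first column `column`
#'   (1-based index), then one character column per sequence, named by
#'   record id.
#' @export
to_column_table <- function(msa) {
  stopifnot(inherits(msa, "aligned_set"))
  cells <- lapply(msa$rows, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  out <- data.frame(column = seq_len(msa$length), stringsAsFactors = FALSE)
  for (j in seq_len(msa$n_sp)) out[[msa$ids[[j]]]] <- cells[[j]]
  names(out) <- c("column", msa$ids)
  out
}

#' Write the column table as TSV
#'
#' @param msa An `aligned_set`.
#' @param path Output path.
#' @param comments Optional character vector of '#'-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_column_table <- function(msa, path, comments = character()) {
  tab <- to_column_table(msa)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an external per-residue score track
#'
#' Reads a two-column tab-separated file of (1-based position, score), as
#' exported by external per-residue scoring services. A single header line
#' is tolerated and skipped when its second field is non-numeric.
#'
#' @param path Path to the TSV file.
#' @param label Track name, e.g. "LIST-S2".
#' @return An object of class `score_track`: list with strictly increasing
#'   integer `positions`, numeric `scores`, and `label`.
#' @export
load_score_track <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("no records in ", path)
  first_fields <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  start <- 1L
  if (length(first_fields) >= 2L &&
      is.na(suppressWarnings(as.numeric(first_fields[[2L]])))) {
    start <- 2L  # header line
    if (length(lines) < 2L) stop("no records in ", path)
  }
  n <- length(lines) - start + 1L
  positions <- integer(n)
  scores <- numeric(n)
  for (k in seq_len(n)) {
    ln <- lines[[start + k - 1L]]
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop("parse error at line ", start + k - 1L, ": expected 2 tab-separated fields")
    p <- suppressWarnings(as.integer(fields[[1L]]))
    s <- suppressWarnings(as.numeric(fields[[2L]]))
    if (is.na(p) || is.na(s))
      stop("parse error at line ", start + k - 1L, ": non-numeric field")
    positions[[k]] <- p
    scores[[k]] <- s
  }
  if (n > 1L && any(diff(positions) <= 0L))
    stop("unsorted track: positions must be strictly increasing")
  structure(list(positions = positions, scores = scores, label = label),
            class = "score_track")
}

#' Write a score track as two-column TSV
#'
#' @param track A `score_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  stopifnot(inherits(track, "score_track"))
  utils::write.table(
    data.frame(position = track$positions, score = track$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
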
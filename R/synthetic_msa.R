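# Synthetic orthologue-like alignment generator.
#
# Columns are independent. Background columns draw, once per column, a
# residue-frequency vector from a symmetric Dirichlet over the 20-letter
# alphabet (concentration alpha controls how peaked columns are: small
# alpha -> near-conserved columns, large alpha -> near-uniform diversity),
# then each sequence's residue i.i.d. from those frequencies. Planted
# blocks are fully conserved single-residue intervals and never receive
# gaps, so ground truth for region recovery stays crisp. Rows are i.i.d.
# (no phylogenetic correlation): the conservation statistics exercised
# here are themselves phylogeny-blind.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic alignment
#'
#' @param n_sp Number of sequences (>= 2).
#' @param length Number of alignment columns.
#' @param concentration Symmetric Dirichlet concentration for background
#'   column frequencies (default 1: flat over frequency vectors).
#' @param alphabet Residue alphabet (default the 20 standard letters).
#' @param planted_blocks Data.frame with columns `start`, `end`,
#'   `residue`: fully conserved intervals; must lie within the alignment
#'   and not overlap. `NULL` for none.
#' @param gap_rate Per-cell gap probability outside planted blocks, in
#'   `[0, 1)`.
#' @param seed Integer random seed; identical specs generate identical
#'   alignments.
#' @return An object of class `synthetic_msa_spec`.
#' @export
synthetic_msa_spec <- function(n_sp, length, concentration = 1,
                               alphabet = .STANDARD_AA,
                               planted_blocks = NULL, gap_rate = 0,
                               seed = 1L) {
  n_sp <- as.integer(n_sp)
  length <- as.integer(length)
  if (is.na(n_sp) || n_sp < 2L) stop("n_sp >= 2 required")
  if (length < 1L) stop("length >= 1 required")
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  if (concentration <= 0) stop("concentration must be positive")
  if (!is.null(planted_blocks)) {
    planted_blocks <- as.data.frame(planted_blocks, stringsAsFactors = FALSE)
    stopifnot(all(c("start", "end", "residue") %in% names(planted_blocks)))
    planted_blocks$start <- as.integer(planted_blocks$start)
    planted_blocks$end <- as.integer(planted_blocks$end)
    if (any(planted_blocks$start > planted_blocks$end) ||
        any(planted_blocks$start < 1L) || any(planted_blocks$end > length))
      stop("planted blocks must lie within 1..length with start <= end")
    if (!all(planted_blocks$residue %in% alphabet))
      stop("planted residue not in alphabet")
    cols <- unlist(mapply(seq, planted_blocks$start, planted_blocks$end,
                          SIMPLIFY = FALSE))
    if (anyDuplicated(cols)) stop("block overlap")
  }
  structure(
    list(n_sp = n_sp, length = length, concentration = concentration,
         alphabet = alphabet, planted_blocks = planted_blocks,
         gap_rate = gap_rate, seed = as.integer(seed)),
    class = "synthetic_msa_spec")
}

#' Columns covered by planted blocks
#'
#' @param spec A `synthetic_msa_spec`.
#' @return Sorted integer vector of planted column indices (possibly
#'   empty).
#' @export
planted_columns <- function(spec) {
  stopifnot(inherits(spec, "synthetic_msa_spec"))
  b <- spec$planted_blocks
  if (is.null(b) || nrow(b) == 0L) return(integer(0))
  sort(unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE)))
}

#' Generate a synthetic alignment
#'
#' @param spec A `synthetic_msa_spec`.
#' @return List with `msa` (an `aligned_set` with ids `seq01`, `seq02`,
#'   ...) and `truth`, a data.frame with one row per column: `column`,
#'   `is_planted`, and `frequencies` (the column's true residue
#'   frequencies serialized as `residue:freq` pairs separated by ',').
#' @examples
#' blocks <- data.frame(start = 20, end = 30, residue = "L")
#' out <- generate_msa(synthetic_msa_spec(10, 50, planted_blocks = blocks, seed = 1))
#' out$msa$n_sp
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "synthetic_msa_spec"))
  K <- length(spec$alphabet)
  planted <- planted_columns(spec)
  planted_res <- character(spec$length)
  if (length(planted)) {
    b <- spec$planted_blocks
    for (r in seq_len(nrow(b)))
      planted_res[b$start[r]:b$end[r]] <- b$residue[r]
  }
  with_seed(spec$seed, {
    cells <- matrix("", nrow = spec$n_sp, ncol = spec$length)
    freq_str <- character(spec$length)
    for (i in seq_len(spec$length)) {
      if (i %in% planted) {
        cells[, i] <- planted_res[i]
        freq_str[i] <- paste0(planted_res[i], ":1")
        next
      }
      # symmetric Dirichlet via normalized gammas
      g <- stats::rgamma(K, shape = spec$concentration)
      while (sum(g) == 0) g <- stats::rgamma(K, shape = spec$concentration)
      f <- g / sum(g)
      cells[, i] <- sample(spec$alphabet, spec$n_sp, replace = TRUE, prob = f)
      if (spec$gap_rate > 0) {
        gap <- stats::runif(spec$n_sp) < spec$gap_rate
        cells[gap, i] <- "-"
      }
      freq_str[i] <- paste(paste0(spec$alphabet, ":", signif(f, 6)),
                           collapse = ",")
    }
    ids <- sprintf("seq%02d", seq_len(spec$n_sp))
    rows <- apply(cells, 1L, paste, collapse = "")
    truth <- data.frame(column = seq_len(spec$length),
                        is_planted = seq_len(spec$length) %in% planted,
                        frequencies = freq_str, stringsAsFactors = FALSE)
    list(msa = aligned_set(ids, rows), truth = truth)
  })
}

#' Write the generator's truth table as TSV
#'
#' @param truth The `truth` data.frame from [generate_msa()].
#' @param path Output path.
#' @param comments Optional '#'-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Planted-block recovery experiment
#'
#' Generates an alignment from `spec`, computes the conservation spectrum
#' (reference = first sequence), calls conserved regions with the given
#' selector, and scores the called columns against the planted columns.
#'
#' @param spec A `synthetic_msa_spec` with at least one planted block.
#' @param top_k,quantile,min_run Selector settings passed to
#'   [call_conserved_regions()]. `top_k = 0` is allowed and counts every
#'   planted column as a false negative.
#' @return List with integer counts `tp`, `fp`, `fn`, `tn` (columns), the
#'   called column set `called`, and the planted column set `planted`.
#' @export
recovery_experiment <- function(spec, top_k = NULL, quantile = NULL,
                                min_run = 1L) {
  stopifnot(inherits(spec, "synthetic_msa_spec"))
  planted <- planted_columns(spec)
  if (length(planted) == 0L) stop("spec has no planted block")
  out <- generate_msa(spec)
  sp <- conservation_spectrum(out$msa, reference_id = out$msa$ids[[1L]])
  called <- integer(0)
  if (!(!is.null(top_k) && top_k == 0L)) {
    regions <- call_conserved_regions(sp, top_k = top_k, quantile = quantile,
                                      min_run = min_run)
    called <- sort(unlist(regions$member_columns))
    if (is.null(called)) called <- integer(0)
  }
  all_cols <- seq_len(spec$length)
  list(tp = length(intersect(called, planted)),
       fp = length(setdiff(called, planted)),
       fn = length(setdiff(planted, called)),
       tn = length(setdiff(setdiff(all_cols, called), planted)),
       called = called, planted = planted)
}
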
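# Per-column conservation metrics.
#
# Two families of statistics are computed for every alignment column i:
#
#   Information entropy:  S_i = sum_D P_Di * ln P_Di   (<= 0)
#     with Shannon form H_i = -S_i and the "negative inverse" display form
#     -1/S_i (fully conserved columns, S_i = 0, map to +Inf).
#
#   Phylogenetic kinetic value (PKV):
#     phi_i   = 1 + sum_d d^2 * N_i(d)      over the rank-abundance spectrum
#     E[d^2]  = phi_i / N_sp
#     Phi_i   = phi_i / N_sp^2
#     kappa_i = -ln Phi_i                   (the PKV)
#
# N_i(d) is the abundance of the rank-d residue (most abundant residue has
# d = 0), so phi is an integer >= 1 and kappa attains its global maximum
# 2 ln N_sp exactly at fully conserved, gap-free columns.

#' Entropy forms for one alignment column
#'
#' Computes the raw entropy sum S = sum P ln P over residue emergence
#' probabilities at the column, its Shannon form H = -S, and the
#' negative-inverse display form -1/S used for spectrum plots (S = 0, a
#' fully conserved column, maps to the +Inf sentinel).
#'
#' @param census A `column_census`.
#' @param p_denominator Probability denominator: `"effective"` (non-gap
#'   count at the column; proper probabilities, the default) or `"global"`
#'   (the full sequence count `n_sp`, under which probabilities at gapped
#'   columns sum to less than one).
#' @param n_sp Total sequence count; required when
#'   `p_denominator = "global"`.
#' @return List with `entropy_raw`, `entropy_shannon`, `entropy_display`
#'   and `p_values` (named numeric vector of per-residue probabilities).
#'   All-gap columns yield `NA` metrics.
#' @examples
#' cen <- column_census(aligned_set(letters[1:8], strsplit("LLLLLLLA", "")[[1]]), 1)
#' entropy_forms(cen)$entropy_shannon  # 7/8, 1/8 mixture
#' @export
entropy_forms <- function(census, p_denominator = c("effective", "global"),
                          n_sp = NULL) {
  stopifnot(inherits(census, "column_census"))
  p_denominator <- match.arg(p_denominator)
  if (census$all_gap || census$diversity == 0L) {
    return(list(entropy_raw = NA_real_, entropy_shannon = NA_real_,
                entropy_display = NA_real_, p_values = numeric(0)))
  }
  denom <- if (p_denominator == "effective") census$n_effective else {
    if (is.null(n_sp)) stop("n_sp required for global probability denominator")
    n_sp
  }
  p <- census$counts / denom
  s <- sum(p * log(p))
  list(entropy_raw = s,
       entropy_shannon = -s,
       entropy_display = if (s == 0) Inf else -1 / s,
       p_values = p)
}

#' The per-column existence-augmented second-moment sum phi
#'
#' phi = 1 + sum over the rank-abundance spectrum of d^2 * N(d), where d is
#' the 0-based abundance rank of each distinct residue and N(d) its count.
#' The leading 1 is the existence score of the column itself; phi = 1 if
#' and only if the column is fully conserved.
#'
#' @param census A `column_census`.
#' @return Integer-valued numeric, or `NA` for an all-gap column.
#' @export
phi <- function(census) {
  stopifnot(inherits(census, "column_census"))
  if (census$all_gap || census$diversity == 0L) return(NA_real_)
  1 + sum(census$spectrum$d^2 * census$spectrum$count)
}

#' PKV quantities for one alignment column
#'
#' From phi and the sequence count computes the second moment
#' E[d^2] = phi / n_sp, its normalized form Phi = phi / n_sp^2 and the
#' phylogenetic kinetic value kappa = -ln Phi.
#'
#' @param census A `column_census`.
#' @param n_sp Sequence count used for normalization (the orthologue-set
#'   size; must be >= 1).
#' @return List with `E_d2`, `Phi`, `kappa` (all `NA` for an all-gap
#'   column).
#' @examples
#' cen <- column_census(aligned_set(letters[1:8], rep("K", 8)), 1)
#' pkv(cen, 8)$kappa  # 2 * log(8)
#' @export
pkv <- function(census, n_sp) {
  stopifnot(inherits(census, "column_census"))
  if (is.null(n_sp) || n_sp == 0L) stop("empty alignment")
  ph <- phi(census)
  if (is.na(ph)) return(list(E_d2 = NA_real_, Phi = NA_real_, kappa = NA_real_))
  Phi <- ph / n_sp^2
  list(E_d2 = ph / n_sp, Phi = Phi, kappa = -log(Phi))
}

#' Per-column conservation spectrum of an alignment
#'
#' Runs the column census over every alignment column and combines the
#' entropy forms and the PKV quantities into one record per column. When a
#' reference identifier is given, each record also carries the mapped
#' ungapped reference position and the reference residue.
#'
#' @param msa An `aligned_set`.
#' @param reference_id Optional record identifier used for coordinate
#'   mapping.
#' @param nsp Normalization convention for the PKV: `"global"` uses the
#'   full sequence count at every column (the default), `"local"` uses the
#'   column's non-gap count.
#' @param p_denominator Probability denominator for the entropy forms; see
#'   [entropy_forms()].
#' @return An object of class `conservation_spectrum`: a data.frame with
#'   one row per column and columns `column`, `ref_position`,
#'   `residue_ref`, `n_effective`, `gap_count`, `diversity`,
#'   `entropy_raw`, `entropy_shannon`, `entropy_display`, `phi`, `E_d2`,
#'   `Phi`, `kappa`. Attributes `n_sp`, `reference_id` and `settings`
#'   record the normalization in force. All-gap columns carry `NA`
#'   metrics.
#' @examples
#' msa <- aligned_set(c("a", "b"), c("MLK", "MQK"))
#' conservation_spectrum(msa)$kappa
#' @export
conservation_spectrum <- function(msa, reference_id = NULL,
                                  nsp = c("global", "local"),
                                  p_denominator = c("effective", "global")) {
  stopifnot(inherits(msa, "aligned_set"))
  nsp <- match.arg(nsp)
  p_denominator <- match.arg(p_denominator)
  cmap <- if (!is.null(reference_id)) build_coordinate_map(msa, reference_id)
  ref_row <- if (!is.null(reference_id))
    strsplit(msa$rows[[match(reference_id, msa$ids)]], "", fixed = TRUE)[[1L]]

  n <- msa$length
  rec <- data.frame(
    column = seq_len(n), ref_position = NA_integer_,
    residue_ref = NA_character_, n_effective = NA_integer_,
    gap_count = NA_integer_, diversity = NA_integer_,
    entropy_raw = NA_real_, entropy_shannon = NA_real_,
    entropy_display = NA_real_, phi = NA_real_, E_d2 = NA_real_,
    Phi = NA_real_, kappa = NA_real_, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    cen <- column_census(msa, i)
    rec$n_effective[i] <- cen$n_effective
    rec$gap_count[i] <- cen$gap_count
    rec$diversity[i] <- cen$diversity
    ent <- entropy_forms(cen, p_denominator = p_denominator, n_sp = msa$n_sp)
    rec$entropy_raw[i] <- ent$entropy_raw
    rec$entropy_shannon[i] <- ent$entropy_shannon
    rec$entropy_display[i] <- ent$entropy_display
    if (!cen$all_gap) {
      n_i <- if (nsp == "global") msa$n_sp else cen$n_effective
      kv <- pkv(cen, n_i)
      rec$phi[i] <- phi(cen)
      rec$E_d2[i] <- kv$E_d2
      rec$Phi[i] <- kv$Phi
      rec$kappa[i] <- kv$kappa
    }
    if (!is.null(cmap)) {
      rec$ref_position[i] <- cmap$col_to_ref[i]
      if (!is.na(cmap$col_to_ref[i])) rec$residue_ref[i] <- ref_row[i]
    }
  }
  structure(rec,
            n_sp = msa$n_sp,
            reference_id = reference_id,
            settings = list(nsp = nsp, p_denominator = p_denominator),
            class = c("conservation_spectrum", "data.frame"))
}

#' Call conserved regions from a spectrum
#'
#' Selects high-kappa columns — either the columns holding the `top_k`
#' largest kappa values or those at or above the `quantile` of kappa
#' (ties always included) — and merges them into maximal runs of
#' consecutive reference positions. Columns without a reference position
#' (reference gaps) break runs and are never selected; all-gap columns
#' are excluded before selection.
#'
#' @param spec A `conservation_spectrum` computed with a reference.
#' @param top_k Select the columns attaining the k largest kappa values.
#' @param quantile Alternatively, select columns with kappa at or above
#'   this kappa quantile (in `[0, 1]`). Exactly one of `top_k`/`quantile`
#'   must be given.
#' @param min_run Minimum region length in reference residues; shorter
#'   runs are dropped.
#' @return A data.frame of class `conserved_regions` with columns
#'   `start_ref`, `end_ref`, `peak_kappa` and `member_columns` (a list
#'   column of alignment column indices), sorted by `start_ref`. Empty
#'   selection returns a zero-row frame, not an error.
#' @export
call_conserved_regions <- function(spec, top_k = NULL, quantile = NULL,
                                   min_run = 1L) {
  stopifnot(inherits(spec, "conservation_spectrum"))
  if (is.null(top_k) == is.null(quantile))
    stop("give exactly one of top_k or quantile")
  usable <- !is.na(spec$kappa) & !is.na(spec$ref_position)
  if (!any(usable)) stop("reference mapping required (no mapped, scored columns)")
  kap <- spec$kappa[usable]

  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k <= 0L) {
      sel_cols <- integer(0)
    } else {
      thr <- sort(kap, decreasing = TRUE)[min(top_k, length(kap))]
      sel_cols <- spec$column[usable][kap >= thr]
    }
  } else {
    stopifnot(quantile >= 0, quantile <= 1)
    thr <- stats::quantile(kap, probs = quantile, names = FALSE)
    sel_cols <- spec$column[usable][kap >= thr]
  }

  empty <- structure(
    data.frame(start_ref = integer(0), end_ref = integer(0),
               peak_kappa = numeric(0)),
    class = c("conserved_regions", "data.frame"))
  empty$member_columns <- list()
  if (length(sel_cols) == 0L) return(empty)

  sel <- spec[spec$column %in% sel_cols, c("column", "ref_position", "kappa")]
  sel <- sel[order(sel$ref_position), ]
  # a run must be consecutive both in reference numbering and in alignment
  # columns: an intervening reference-gap column breaks it
  breaks <- c(0L, cumsum(diff(sel$ref_position) != 1L | diff(sel$column) != 1L))
  runs <- split(sel, breaks)
  regions <- lapply(runs, function(r) {
    data.frame(start_ref = min(r$ref_position), end_ref = max(r$ref_position),
               peak_kappa = max(r$kappa))
  })
  out <- do.call(rbind, regions)
  out$member_columns <- lapply(runs, function(r) r$column)
  rownames(out) <- NULL
  keep <- (out$end_ref - out$start_ref + 1L) >= min_run
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start_ref), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conserved_regions", "data.frame")
  out
}

#' Write a conservation spectrum as TSV
#'
#' @param spec A `conservation_spectrum`.
#' @param path Output path.
#' @param comments Optional '#'-prefixed header lines (the command-line
#'   layer records tool version, seed and conventions here).
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path, comments = character()) {
  stopifnot(inherits(spec, "conservation_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(as.data.frame(spec), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write conserved regions as 1-based inclusive TSV
#'
#' @param regions A `conserved_regions` frame.
#' @param path Output path.
#' @param comments Optional '#'-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  tab <- data.frame(
    start_ref = regions$start_ref, end_ref = regions$end_ref,
    peak_kappa = regions$peak_kappa,
    member_columns = vapply(regions$member_columns,
                            function(x) paste(x, collapse = ","), character(1L)))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write conserved regions as BED
#'
#' Converts the package's 1-based inclusive reference intervals to BED's
#' 0-based half-open convention. The BED score is the peak kappa scaled by
#' 100 and clamped to the 0-1000 BED range.
#'
#' @param regions A `conserved_regions` frame.
#' @param path Output path.
#' @param chrom Name placed in the BED chrom field (typically the
#'   reference sequence identifier).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, chrom = "ref") {
  n <- nrow(regions)
  bed <- data.frame(
    chrom = rep(chrom, n),
    start = regions$start_ref - 1L,
    end = regions$end_ref,
    name = if (n) paste0("region_", seq_len(n)) else character(0),
    score = if (n) pmax(0L, pmin(1000L, round(regions$peak_kappa * 100))) else integer(0))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
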
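# Synthetic stand-in for a vertebrate OMP-like orthologue alignment.

#' Synthetic OMP-like orthologue alignment (stand-in)
#'
#' Builds a fully synthetic stand-in for a vertebrate orthologue set of a
#' small (163-residue, ~19 kDa class) cytosolic protein such as olfactory
#' marker protein: 30 sequences, gap-free so that alignment columns
#' coincide with reference residue numbering, with the leucine-rich
#' Omega-loop span (residues 91-100) planted as a fully conserved leucine
#' block against a diverse background (flat Dirichlet column
#' frequencies). It is generated data, not the real orthologue alignment:
#' use it to exercise the spectrum/region-calling workflow and the
#' expectation that the most conserved residues fall in the 90-100 span,
#' not to draw biological conclusions about OMP itself.
#'
#' @param seed Integer seed (default 101).
#' @return List with `msa` (an `aligned_set`; reference is the first
#'   record `seq01`), `spec` (the generating `synthetic_msa_spec`) and
#'   `conserved_span` (`c(91, 100)`, the planted interval in reference
#'   numbering).
#' @examples
#' standin <- synthetic_omp_standin()
#' sp <- conservation_spectrum(standin$msa, reference_id = "seq01")
#' sp$ref_position[which.max(sp$kappa)]
#' @export
synthetic_omp_standin <- function(seed = 101L) {
  blocks <- data.frame(start = 91L, end = 100L, residue = "L",
                       stringsAsFactors = FALSE)
  spec <- synthetic_msa_spec(n_sp = 30L, length = 163L, concentration = 1,
                             planted_blocks = blocks, gap_rate = 0,
                             seed = seed)
  out <- generate_msa(spec)
  list(msa = out$msa, spec = spec, conserved_span = c(91L, 100L))
}
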
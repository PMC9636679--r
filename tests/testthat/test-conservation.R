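# Entropy forms, phi/PKV, the spectrum, and region calling.

column_msa <- function(letters_vec) {
  matrix_to_aligned_set(matrix(letters_vec, ncol = 1))
}

test_that("entropy forms match direct evaluation and handle conservation", {
  # fully conserved: S = 0, H = 0, display sentinel +Inf
  ent <- entropy_forms(column_census(column_msa(rep("K", 8)), 1))
  expect_identical(ent$entropy_raw, 0)
  expect_identical(ent$entropy_display, Inf)

  # 7:1 mixture, frozen from 0.875*ln(0.875) + 0.125*ln(0.125)
  ent2 <- entropy_forms(column_census(column_msa(strsplit("LLLLLLLA", "")[[1]]), 1))
  expect_equal(ent2$entropy_raw, -0.37677016, tolerance = 1e-7)
  expect_equal(ent2$entropy_shannon, 0.37677016, tolerance = 1e-7)
  expect_equal(ent2$entropy_display, -1 / ent2$entropy_raw)
  expect_equal(sum(ent2$p_values), 1, tolerance = 1e-12)

  # uniform two-state closed form
  ent3 <- entropy_forms(column_census(column_msa(c("L", "L", "A", "A")), 1))
  expect_equal(ent3$entropy_shannon, log(2), tolerance = 1e-12)

  # global denominator counts gapped sequences in the denominator
  msa <- aligned_set(c("a", "b", "c", "d"), c("L", "L", "L", "-"))
  cen <- column_census(msa, 1)
  ent4 <- entropy_forms(cen, p_denominator = "global", n_sp = 4)
  expect_equal(unname(ent4$p_values), 0.75)

  # all-gap census yields NA metrics, not an error
  allgap <- column_census(aligned_set(c("a", "b"), c("-", "-")), 1)
  expect_true(is.na(entropy_forms(allgap)$entropy_raw))
})

test_that("phi evaluates the rank-weighted second-moment sum", {
  expect_equal(phi(column_census(column_msa(rep("K", 8)), 1)), 1)
  expect_equal(phi(column_census(column_msa(strsplit("LLLLLLLA", "")[[1]]), 1)), 2)
  # 8 all-distinct residues: 1 + 1+4+9+16+25+36+49 = 141
  expect_equal(phi(column_census(column_msa(c("A","C","D","E","F","G","H","I")), 1)),
               141)
  expect_true(is.na(phi(column_census(aligned_set("a", "-"), 1))))
})

test_that("pkv quantities follow the closed forms", {
  cen_cons <- column_census(column_msa(rep("K", 8)), 1)
  kv <- pkv(cen_cons, 8)
  expect_equal(kv$Phi, 1 / 64)
  expect_equal(kv$kappa, 2 * log(8), tolerance = 1e-12)

  kv2 <- pkv(column_census(column_msa(strsplit("LLLLLLLA", "")[[1]]), 1), 8)
  expect_equal(kv2$E_d2, 2 / 8)
  expect_equal(kv2$Phi, 0.03125)
  expect_equal(kv2$kappa, log(32), tolerance = 1e-12)

  kv3 <- pkv(column_census(column_msa(c("A","C","D","E","F","G","H","I")), 1), 8)
  expect_equal(kv3$Phi, 141 / 64)
  expect_equal(kv3$kappa, -0.7898768, tolerance = 1e-6)  # kappa can go negative

  expect_error(pkv(cen_cons, 0), "empty alignment")
})

test_that("the spectrum combines per-column records with reference mapping", {
  msa <- aligned_set(c("a", "b"), c("MLK", "MQK"))
  sp <- conservation_spectrum(msa, reference_id = "a")
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$kappa, c(2 * log(2), -log(2 / 4), 2 * log(2)),
               tolerance = 1e-12)
  expect_equal(sp$ref_position, 1:3)
  expect_equal(sp$residue_ref, c("M", "L", "K"))
  expect_equal(attr(sp, "n_sp"), 2L)

  # row permutation leaves every record unchanged
  set.seed(21)
  cells <- random_alignment_matrix(9, 25, gap_rate = 0.1)
  m1 <- matrix_to_aligned_set(cells)
  m2 <- matrix_to_aligned_set(cells[sample(9), , drop = FALSE])
  s1 <- conservation_spectrum(m1)
  s2 <- conservation_spectrum(m2)
  expect_equal(s1$kappa, s2$kappa)
  expect_equal(s1$entropy_raw, s2$entropy_raw)

  # all-gap columns carry NA metrics and local-nsp switch works
  msa3 <- aligned_set(c("a", "b", "c"), c("ML-", "M--", "M--"))
  sp3 <- conservation_spectrum(msa3)
  expect_true(is.na(sp3$kappa[3]))
  sp3l <- conservation_spectrum(msa3, nsp = "local")
  # column 2: one non-gap residue, local n_sp = 1 -> kappa = -ln(1/1) = 0
  expect_equal(sp3l$kappa[2], 0)
  expect_equal(sp3$kappa[2], 2 * log(3))  # global convention
})

test_that("algebraic identity kappa + ln(phi) = 2 ln(N_sp) holds per column", {
  set.seed(22)
  for (rep in 1:10) {
    msa <- matrix_to_aligned_set(
      random_alignment_matrix(sample(2:12, 1), sample(5:30, 1),
                              gap_rate = 0.15, alphabet = AA20[1:6]))
    sp <- conservation_spectrum(msa)
    ok <- !is.na(sp$kappa)
    expect_true(all(abs(sp$kappa[ok] + log(sp$phi[ok]) - 2 * log(msa$n_sp))
                    < 1e-9))
    # bound: no column exceeds the fully conserved maximum
    expect_true(all(sp$kappa[ok] <= 2 * log(msa$n_sp) + 1e-12))
  }
})

test_that("region caller merges runs, honours ties, min_run and selectors", {
  # kappa profile [1,5,5,5,1] via one distinct-ish construction: use a
  # spectrum from a crafted alignment where columns 2-4 are conserved
  msa <- aligned_set(c("a", "b", "c", "d"),
                     c("ALKQA", "CLKQC", "DLKQD", "ELKQE"))
  sp <- conservation_spectrum(msa, reference_id = "a")
  reg <- call_conserved_regions(sp, top_k = 3)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_ref, 2L)
  expect_equal(reg$end_ref, 4L)
  expect_equal(reg$peak_kappa, 2 * log(4))
  expect_equal(reg$member_columns[[1]], 2:4)

  # top-1 with ties selects all tied argmax columns, merged when adjacent
  reg1 <- call_conserved_regions(sp, top_k = 1)
  expect_equal(reg1$start_ref, 2L)
  expect_equal(reg1$end_ref, 4L)

  # min_run drops short runs
  msa2 <- aligned_set(c("a", "b"), c("MAKAM", "MCKCM"))
  sp2 <- conservation_spectrum(msa2, reference_id = "a")
  reg2 <- call_conserved_regions(sp2, top_k = 3, min_run = 2)
  expect_equal(nrow(reg2), 0L)

  # reference gaps break runs
  msa3 <- aligned_set(c("r", "b", "c"), c("MK-LM", "MKQLM", "MKQLM"))
  sp3 <- conservation_spectrum(msa3, reference_id = "r")
  reg3 <- call_conserved_regions(sp3, top_k = 4)
  expect_equal(reg3$start_ref, c(1L, 3L))
  expect_equal(reg3$end_ref, c(2L, 4L))

  # zero selection is empty, not an error; selector arguments validated
  expect_equal(nrow(call_conserved_regions(sp, top_k = 0)), 0L)
  expect_error(call_conserved_regions(sp), "exactly one")
  expect_error(call_conserved_regions(sp, top_k = 1, quantile = 0.5),
               "exactly one")
})

test_that("spectrum and region exports write parseable TSV and BED", {
  msa <- aligned_set(c("a", "b"), c("MLKQ", "MQKQ"))
  sp <- conservation_spectrum(msa, reference_id = "a")
  reg <- call_conserved_regions(sp, top_k = 2)
  dir <- withr::local_tempdir()
  write_spectrum_tsv(sp, file.path(dir, "s.tsv"), comments = c("v0", "seed=1"))
  tab <- utils::read.delim(file.path(dir, "s.tsv"), comment.char = "#")
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$kappa, sp$kappa)
  first <- readLines(file.path(dir, "s.tsv"), n = 1)
  expect_match(first, "^# ")

  write_regions_tsv(reg, file.path(dir, "r.tsv"))
  rtab <- utils::read.delim(file.path(dir, "r.tsv"))
  expect_equal(rtab$start_ref, reg$start_ref)

  write_regions_bed(reg, file.path(dir, "r.bed"), chrom = "a")
  bed <- utils::read.delim(file.path(dir, "r.bed"), header = FALSE)
  expect_equal(bed$V2, reg$start_ref - 1L)  # 0-based half-open
  expect_equal(bed$V3, reg$end_ref)
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
})
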
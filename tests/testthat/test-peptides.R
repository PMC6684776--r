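test_that("the bundled FASTA fixture parses to the five marker peptides", {
  peps <- crp_marker_peptides()
  expect_equal(peps$name, c("aM1", "bM1", "hP1", "hP2", "aB1"))
  expect_equal(peps$sequence, unname(marker_seqs[peps$name]))
  expect_equal(nchar(peps$sequence), c(37L, 45L, 37L, 45L, 33L))
})

test_that("FASTA round-trips, uppercases, and rejects empty records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  tbl <- tibble::tibble(name = c("x", "y"), sequence = c("ACDEFG", "wklm"))
  write_fasta(tbl, path)
  r <- read_fasta(path)
  expect_equal(r$name, c("x", "y"))
  expect_equal(r$sequence, c("ACDEFG", "WKLM")) # uppercased
  writeLines(c(">empty", ">z", "AAA"), path)
  expect_error(read_fasta(path), "empty FASTA record")
  writeLines(c("AAA"), path)
  expect_error(read_fasta(path), "not a FASTA file")
})

test_that("peptide validation enforces the residue alphabet", {
  expect_error(crp_peptide("bad", ""), "empty")
  expect_error(crp_peptide("bad", "ACXZ"), "invalid residue")
  p <- crp_peptide("ok", "ac d e") # whitespace stripped, uppercased
  expect_equal(as.character(p), "ACDE")
})

test_that("cysteine motifs render in C-Xn notation and round-trip", {
  m_am1 <- cysteine_motif(marker_seqs["aM1"])
  expect_equal(m_am1$rendered, "C-X3-C-X7-C-X4-C-X-C-X9-C")
  m_hp2 <- cysteine_motif(marker_seqs["hP2"])
  expect_equal(
    m_hp2$rendered,
    "C-X10-C-X8-C-X3-C-X10-C-X4-C-X-C-X-C"
  )
  # hP1 shares the aM1 motif; bM1 shares the hP2 motif
  expect_equal(cysteine_motif(marker_seqs["hP1"])$rendered, m_am1$rendered)
  expect_equal(cysteine_motif(marker_seqs["bM1"])$rendered, m_hp2$rendered)
  # adjacent cysteines render as C-C (aB1 has a CC pair)
  expect_match(cysteine_motif(marker_seqs["aB1"])$rendered, "C-C")
  empty <- cysteine_motif("AAAA")
  expect_equal(empty$rendered, "")
  expect_equal(empty$n_cys, 0L)
  # rendering round-trips through the parser
  for (s in marker_seqs) {
    m <- cysteine_motif(s)
    expect_equal(parse_motif(m$rendered)$gaps, m$gaps)
  }
})

test_that("cysteine counts match the printed descriptions", {
  expect_equal(cysteine_count(marker_seqs["aB1"]), 6L)
  expect_equal(cysteine_count(marker_seqs["aM1"]), 6L)
  expect_equal(cysteine_count("C"), 1L)
})

test_that("ungapped identity is symmetric, exact on self, errors on length", {
  expect_equal(
    round(pairwise_identity(marker_seqs["bM1"], marker_seqs["hP2"]), 1),
    62.2
  )
  expect_equal(
    pairwise_identity(marker_seqs["bM1"], marker_seqs["hP2"]),
    pairwise_identity(marker_seqs["hP2"], marker_seqs["bM1"])
  )
  expect_identical(pairwise_identity("ACDE", "ACDE"), 100)
  # aM1 vs hP1: 19 of 37 positions match
  expect_equal(
    pairwise_identity(marker_seqs["aM1"], marker_seqs["hP1"]),
    100 * 19 / 37
  )
  expect_error(pairwise_identity("ACD", "ACDE"), "length")
})

test_that("peptide masses follow the residue table and water term", {
  expect_equal(peptide_mass("G", "mono"), 57.02146 + 18.0105646,
    tolerance = 1e-6
  )
  # additivity: mass(AB) = mass(A) + mass(B) - water
  w <- 18.0105646
  expect_equal(
    peptide_mass("AG", "mono"),
    peptide_mass("A", "mono") + peptide_mass("G", "mono") - w,
    tolerance = 1e-9
  )
  # disulfide arithmetic: each bridge removes two hydrogens
  free <- peptide_mass(marker_seqs["aM1"], "mono")
  oxid <- peptide_mass(marker_seqs["aM1"], "mono",
    cys_state = "disulfide", n_bonds = 3
  )
  expect_equal(free - oxid, 6 * 1.0078250319, tolerance = 1e-9)
  expect_error(
    peptide_mass("CAC", "mono", cys_state = "disulfide", n_bonds = 2),
    "n_bonds"
  )
  # nominal alkylation shift: +58 Da per cysteine (6 Cys -> +348)
  expect_equal(
    peptide_mass(marker_seqs["aB1"], "nominal", cys_state = "alkylated") -
      peptide_mass(marker_seqs["aB1"], "nominal"),
    348
  )
  expect_error(peptide_mass("AAA", cys_state = "alkylated"), "cysteine")
})

test_that("trypsin digestion of hP1 yields the three Keil-rule fragments", {
  d <- digest(marker_seqs["hP1"], "trypsin", max_missed = 0)
  expect_equal(nrow(d), 3)
  expect_equal(d$start, c(1L, 22L, 32L))
  expect_equal(d$end, c(21L, 31L, 37L))
  expect_equal(d$sequence[3], "CSTPSG")
  expect_equal(round(d$mass_mono[3]), 550)
})

test_that("hP2 with one missed cleavage contains the 1433 Da fragment", {
  d <- digest(marker_seqs["hP2"], "trypsin", max_missed = 1)
  frag <- d[d$start == 1 & d$end == 13, ]
  expect_equal(nrow(frag), 1)
  expect_equal(frag$sequence, "CEKGSEFFVGACR")
  expect_equal(frag$missed, 1L)
  expect_equal(round(frag$mass_average), 1433)
})

test_that("digestion respects enzymes, proline, and missed-cleavage counts", {
  # no cleavage before proline: K followed by P is skipped
  d <- digest("AKPGKA", "trypsin")
  expect_equal(d$sequence, c("AKPGK", "A"))
  # chymotrypsin high specificity F/W/Y; low adds L/M
  expect_equal(digest("AFGLM", "chymotrypsin")$sequence, c("AF", "GLM"))
  expect_equal(
    digest("AFGLM", "chymotrypsin", low_specificity = TRUE)$sequence,
    c("AF", "GL", "M")
  )
  # a sequence with no sites returns itself
  d0 <- digest("ACDG", "trypsin")
  expect_equal(d0$sequence, "ACDG")
  # missed cleavages enumerate contiguous joins
  d1 <- digest("AKCKDK", "trypsin", max_missed = 2)
  expect_setequal(
    d1$sequence,
    c("AK", "CK", "DK", "AKCK", "CKDK", "AKCKDK")
  )
})

test_that("complete digests tile the parent and conserve mass", {
  set.seed(71)
  aas <- names(crpfp:::residue_masses$mono)
  for (i in 1:10) {
    s <- paste(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    for (enz in c("trypsin", "chymotrypsin")) {
      d <- digest(s, enz, max_missed = 0)
      expect_equal(paste(d$sequence, collapse = ""), s)
      expect_equal(d$start[1], 1L)
      expect_equal(tail(d$end, 1), nchar(s))
      if (nrow(d) > 1) {
        expect_equal(d$start[-1], head(d$end, -1) + 1L)
      }
      # hydrolysis adds one water per cut
      expect_equal(
        sum(d$mass_mono) - (nrow(d) - 1) * 18.0105646,
        peptide_mass(s, "mono"),
        tolerance = 1e-6
      )
    }
  }
})
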
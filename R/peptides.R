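#' Amino-acid residue masses
#'
#' Standard monoisotopic and average residue (i.e. dehydrated) masses of
#' the 20 proteinogenic amino acids, in Da. A neutral peptide mass is the
#' sum of its residue masses plus one water.
#'
#' @format Named list with numeric vectors `mono` and `average`, plus
#'   `water_mono` and `water_average`.
#' @keywords internal
residue_masses <- list(
  mono = c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
    V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
    I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
    K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
    F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  ),
  average = c(
    G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152,
    V = 99.1311, T = 101.1039, C = 103.1429, L = 113.1576,
    I = 113.1576, N = 114.1026, D = 115.0874, Q = 128.1292,
    K = 128.1723, E = 129.1140, M = 131.1961, H = 137.1393,
    F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099
  ),
  water_mono = 18.0105646,
  water_average = 18.01528,
  hydrogen_mono = 1.0078250319,
  hydrogen_average = 1.00794
)

#' Validate a peptide sequence
#'
#' @param name Peptide name.
#' @param residues One-letter amino-acid string (upper- or lowercase;
#'   stored uppercase).
#' @return A `crp_peptide` object (a named character string).
#' @export
crp_peptide <- function(name, residues) {
  residues <- toupper(gsub("\\s", "", residues))
  if (nchar(residues) == 0) crp_abort("empty peptide sequence")
  bad <- setdiff(
    strsplit(residues, "")[[1]],
    names(residue_masses$mono)
  )
  if (length(bad)) {
    crp_abort(sprintf(
      "invalid residue code(s): %s", paste(unique(bad), collapse = ", ")
    ))
  }
  structure(residues, name = as.character(name), class = "crp_peptide")
}

#' @export
print.crp_peptide <- function(x, ...) {
  cat(sprintf(
    "<crp_peptide> %s (%d aa, %d Cys)\n%s\n",
    attr(x, "name"), nchar(x), cysteine_count(x), unclass(x)
  ))
  invisible(x)
}

pep_chars <- function(p) strsplit(toupper(as.character(p)), "")[[1]]

#' The five CRP marker peptides bundled with the package
#'
#' Astratides aM1 and bM1 (Radix Astragali markers), hedytides hP1 and
#' hP2 (Radix Hedysarum markers), and achyranthes aB1 — the
#' cysteine-rich marker peptides whose masses anchor the fingerprint
#' classes. Parsed from the FASTA fixture shipped in `inst/extdata`.
#'
#' @return A tibble with `name` and `sequence`.
#' @export
crp_marker_peptides <- function() {
  read_fasta(system.file("extdata", "crp_sequences.fasta",
    package = "crpfp", mustWork = TRUE
  ))
}

#' Read and write FASTA peptide files
#'
#' FASTA parsing is delegated to `Biostrings::readAAStringSet()`; record
#' names are the first whitespace-delimited header token, sequences are
#' uppercased with whitespace stripped and validated against the
#' 20-letter amino-acid alphabet. An empty record is an error.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a tibble with `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      crp_abort(sprintf("not a FASTA file: %s", conditionMessage(e)))
    }
  )
  names_ <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(nchar(seqs) == 0)) {
    crp_abort(sprintf(
      "empty FASTA record: %s", names_[which(nchar(seqs) == 0)[1]]
    ))
  }
  for (i in seq_along(seqs)) crp_peptide(names_[i], seqs[i]) # validates
  tibble::tibble(name = names_, sequence = unname(seqs))
}

#' @rdname read_fasta
#' @param peptides Tibble with `name` and `sequence` columns.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(peptides, path, width = 60) {
  set <- Biostrings::AAStringSet(
    stats::setNames(peptides$sequence, peptides$name)
  )
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Cysteine spacing motif
#'
#' The ordered counts of non-cysteine residues between consecutive
#' cysteines, rendered in the C-Xn notation used to classify CRP
#' families (defensins, hevein-like peptides, PA1b-like peptides, ...):
#' `"C-X3-C"` means three residues between two cysteines, a single
#' residue is written `"X"` without a count, and adjacent cysteines
#' render as `"C-C"`.
#'
#' @param p A [crp_peptide()] or plain sequence string.
#' @return A `crp_motif` object with fields `gaps` (integer vector),
#'   `rendered` (text), `n_cys`, `leading` and `trailing` (non-Cys
#'   offsets before the first / after the last cysteine).
#' @export
cysteine_motif <- function(p) {
  ch <- pep_chars(p)
  idx <- which(ch == "C")
  gaps <- if (length(idx) >= 2) diff(idx) - 1L else integer(0)
  structure(
    list(
      gaps = gaps,
      rendered = render_motif(gaps, length(idx)),
      n_cys = length(idx),
      leading = if (length(idx)) idx[1] - 1L else NA_integer_,
      trailing = if (length(idx)) length(ch) - idx[length(idx)] else NA_integer_
    ),
    class = "crp_motif"
  )
}

render_motif <- function(gaps, n_cys) {
  if (n_cys == 0) {
    return("")
  }
  parts <- "C"
  for (g in gaps) {
    parts <- c(parts, if (g == 0) {
      "C"
    } else if (g == 1) {
      c("X", "C")
    } else {
      c(paste0("X", g), "C")
    })
  }
  paste(parts, collapse = "-")
}

#' @rdname cysteine_motif
#' @param text A rendered motif string such as `"C-X3-C-X7-C"`.
#' @export
parse_motif <- function(text) {
  if (text == "") {
    return(structure(
      list(
        gaps = integer(0), rendered = "", n_cys = 0L,
        leading = NA_integer_, trailing = NA_integer_
      ),
      class = "crp_motif"
    ))
  }
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  gaps <- integer(0)
  pending <- NA_integer_
  n_cys <- 0L
  for (tok in parts) {
    if (tok == "C") {
      if (n_cys > 0) gaps <- c(gaps, if (is.na(pending)) 0L else pending)
      n_cys <- n_cys + 1L
      pending <- NA_integer_
    } else if (tok == "X") {
      pending <- 1L
    } else if (grepl("^X[0-9]+$", tok)) {
      pending <- as.integer(sub("X", "", tok))
    } else {
      crp_abort(sprintf("cannot parse motif token '%s'", tok))
    }
  }
  structure(
    list(
      gaps = gaps, rendered = render_motif(gaps, n_cys), n_cys = n_cys,
      leading = NA_integer_, trailing = NA_integer_
    ),
    class = "crp_motif"
  )
}

#' @export
print.crp_motif <- function(x, ...) {
  cat(sprintf("<crp_motif> %s (%d Cys)\n", x$rendered, x$n_cys))
  invisible(x)
}

#' @rdname cysteine_motif
#' @export
cysteine_count <- function(p) {
  sum(pep_chars(p) == "C")
}

#' Ungapped pairwise sequence identity
#'
#' Position-by-position identity of two equal-length sequences,
#' `100 * matches / length`. Sequences of different lengths need a real
#' alignment first — use an external aligner and compare the aligned
#' strings.
#'
#' @param a,b Peptides or sequence strings of equal length.
#' @return Identity percentage (full precision; report to 1 decimal).
#' @export
pairwise_identity <- function(a, b) {
  ca <- pep_chars(a)
  cb <- pep_chars(b)
  if (length(ca) != length(cb)) {
    crp_abort(paste(
      "sequences differ in length; align them first",
      "(e.g. with an external aligner) and compare the aligned strings"
    ))
  }
  100 * sum(ca == cb) / length(ca)
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water. Cysteine state:
#' \itemize{
#'   \item `"free"` — reduced free thiols (the default).
#'   \item `"disulfide"` — `n_bonds` disulfide bridges, each removing
#'     two hydrogens.
#'   \item `"alkylated"` — reduction plus iodoacetamide
#'     carbamidomethylation, adding 58 Da nominal (57.02146 + 1.00783
#'     monoisotopic) per cysteine: the +58 Da per cysteine increment
#'     used to count cysteines from intact-mass shifts.
#' }
#'
#' @param p A [crp_peptide()] or sequence string.
#' @param kind `"mono"` (monoisotopic), `"average"`, or `"nominal"`
#'   (monoisotopic rounded to the nearest integer, matching printed
#'   whole-Da peak lists).
#' @param cys_state `"free"`, `"disulfide"` or `"alkylated"`.
#' @param n_bonds Number of disulfide bridges when
#'   `cys_state = "disulfide"` (`<= floor(n_cys / 2)`).
#' @return Mass in Da.
#' @export
peptide_mass <- function(p, kind = c("mono", "average", "nominal"),
                         cys_state = c("free", "disulfide", "alkylated"),
                         n_bonds = NULL) {
  kind <- match.arg(kind)
  cys_state <- match.arg(cys_state)
  ch <- pep_chars(p)
  bad <- setdiff(ch, names(residue_masses$mono))
  if (length(bad)) {
    crp_abort(sprintf("invalid residue(s): %s", paste(bad, collapse = ", ")))
  }
  tab <- if (kind == "average") residue_masses$average else residue_masses$mono
  water <- if (kind == "average") {
    residue_masses$water_average
  } else {
    residue_masses$water_mono
  }
  hyd <- if (kind == "average") {
    residue_masses$hydrogen_average
  } else {
    residue_masses$hydrogen_mono
  }
  m <- sum(tab[ch]) + water
  ncys <- sum(ch == "C")
  if (cys_state == "disulfide") {
    if (is.null(n_bonds)) n_bonds <- ncys %/% 2L
    if (n_bonds > ncys %/% 2L) {
      crp_abort("n_bonds exceeds floor(n_cys / 2)")
    }
    m <- m - 2 * n_bonds * hyd
  } else if (cys_state == "alkylated") {
    if (ncys == 0) crp_abort("alkylation requires >= 1 cysteine")
    # reduction (+H) plus carbamidomethyl (+C2H3NO, 57.02146 mono);
    # nominal mode uses the whole-Da +58 per-cysteine counting rule
    shift <- switch(kind,
      average = 57.0513 + hyd,
      mono = 57.02146 + hyd,
      nominal = 58
    )
    m <- m + shift * ncys
  }
  if (kind == "nominal") round(m) else m
}

#' In-silico proteolytic digestion
#'
#' Trypsin cleaves C-terminal to K or R, chymotrypsin (high specificity)
#' C-terminal to F, W or Y; neither cleaves before proline (the Keil
#' rule). Set `low_specificity = TRUE` for the extended chymotrypsin set
#' F/W/Y/L/M. All fragments with `0 ... max_missed` internal missed
#' cleavages are returned with 1-based inclusive spans and neutral
#' masses for free-thiol cysteines; the zero-missed fragments tile the
#' parent exactly.
#'
#' @param p A [crp_peptide()] or sequence string.
#' @param enzyme `"trypsin"` or `"chymotrypsin"`.
#' @param max_missed Maximum internal missed cleavages (default 0).
#' @param low_specificity Chymotrypsin only: include L and M sites.
#' @return A tibble with `start`, `end`, `sequence`, `missed`,
#'   `mass_mono`, `mass_average`.
#' @export
digest <- function(p, enzyme = c("trypsin", "chymotrypsin"),
                   max_missed = 0, low_specificity = FALSE) {
  enzyme <- match.arg(enzyme)
  ch <- pep_chars(p)
  n <- length(ch)
  site_res <- switch(enzyme,
    trypsin = c("K", "R"),
    chymotrypsin = if (low_specificity) {
      c("F", "W", "Y", "L", "M")
    } else {
      c("F", "W", "Y")
    }
  )
  cut_after <- which(ch %in% site_res & c(ch[-1], "") != "P" &
    seq_len(n) < n)
  bounds <- c(0L, cut_after, n) # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:min(max_missed, nfrag - i)) {
      a <- bounds[i] + 1L
      b <- bounds[i + 1L + m]
      s <- paste(ch[a:b], collapse = "")
      out[[length(out) + 1]] <- tibble::tibble(
        start = a, end = b, sequence = s, missed = m,
        mass_mono = peptide_mass(s, "mono"),
        mass_average = peptide_mass(s, "average")
      )
    }
  }
  dplyr::bind_rows(out)
}
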
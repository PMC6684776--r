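# Small fixtures and independent oracles used across the suite.

# tiny two-class templates with disjoint marker peaks on a short grid
tiny_templates <- function(n_points = 400) {
  a <- class_template(
    "A",
    data.frame(center = c(2600, 4200), amplitude = c(10, 8), width = 40),
    n_points = n_points
  )
  b <- class_template(
    "B",
    data.frame(center = c(3200, 5000), amplitude = c(10, 8), width = 40),
    n_points = n_points
  )
  list(A = a, B = b)
}

# brute-force COW benefit: enumerate every interior-boundary placement and
# score it directly, with no dynamic programming
cow_brute_force <- function(query, reference, segment_length, slack) {
  n <- length(reference)
  m <- (n - 1L) %/% segment_length
  B <- c(seq(0L, by = segment_length, length.out = m), n - 1L)
  offs <- (-slack):slack
  seg_score <- function(qb) {
    total <- 0
    for (j in seq_len(m)) {
      ra <- B[j] + 1L
      rb <- B[j + 1L] + 1L
      qa <- qb[j] + 1L
      qe <- qb[j + 1L] + 1L
      if (qe - qa < 1L) {
        return(-Inf)
      }
      y <- approx(qa:qe, query[qa:qe],
        xout = seq(qa, qe, length.out = rb - ra + 1L)
      )$y
      r <- reference[ra:rb]
      cc <- if (sd(r) == 0 || sd(y) == 0) 0 else cor(r, y)
      total <- total + cc
    }
    total
  }
  combos <- do.call(
    expand.grid, rep(list(offs), max(m - 1L, 0L))
  )
  best <- -Inf
  for (i in seq_len(max(nrow(combos), 1L))) {
    u <- if (m > 1L) as.integer(combos[i, ]) else integer(0)
    qb <- B + c(0L, u, 0L)
    best <- max(best, seg_score(qb))
  }
  best
}

# the five marker peptide sequences as printed
marker_seqs <- c(
  aM1 = "VDCSGACSPFEVPPCGSRDCRCIPIGLVVGFCIYPTG",
  bM1 = "CEKPSKFFSGPCIGSSGKTQCAYLCRRGEGLQDGNCKGLKCVCAC",
  hP1 = "QGCNGPCTPFEQPPCGIQSCRCFPEVLFFGRCSTPSG",
  hP2 = "CEKGSEFFVGACRYSEGTQQCATLCSRGEGLQGGKCKGVRCYCSC",
  aB1 = "CLESGTSCIPGAPHDCCSGVCIPIVTVFYGKCY"
)
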
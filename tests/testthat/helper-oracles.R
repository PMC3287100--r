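# Independent oracles and fixture builders. The genetic-code tables here are
# typed by hand, on purpose: the oracle must not share code or constants with
# the implementation it checks.

ORACLE_FAMILIES <- list(
  F = c("TTT", "TTC"),
  Y = c("TAT", "TAC"),
  H = c("CAT", "CAC"),
  Q = c("CAA", "CAG"),
  N = c("AAT", "AAC"),
  K = c("AAA", "AAG"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  C = c("TGT", "TGC"),
  I = c("ATT", "ATC", "ATA"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  A = c("GCT", "GCC", "GCA", "GCG"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
)

# Naive ENC: per-family homozygosity by explicit loops, class means, Wright's
# sum, class-3 imputation from (F2 + F4) / 2, cap at 61.
oracle_enc <- function(counts) {
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(ORACLE_FAMILIES)) {
    fam <- ORACLE_FAMILIES[[aa]]
    x <- numeric(length(fam))
    for (i in seq_along(fam)) {
      x[i] <- if (fam[i] %in% names(counts)) counts[[fam[i]]] else 0
    }
    n <- sum(x)
    if (n < 2) next
    sum_p2 <- 0
    for (i in seq_along(x)) sum_p2 <- sum_p2 + (x[i] / n)^2
    f <- (n * sum_p2 - 1) / (n - 1)
    if (f > 0) {
      k <- as.character(length(fam))
      f_by_class[[k]] <- c(f_by_class[[k]], f)
    }
  }
  fbar <- sapply(f_by_class, function(v) if (length(v)) mean(v) else NA_real_)
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (any(is.na(fbar))) return(NA_real_)
  min(61, 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
        3 / fbar[["6"]])
}

# Naive RSCU over one family.
oracle_rscu_family <- function(x) {
  if (sum(x) == 0) return(rep(NA_real_, length(x)))
  x * length(x) / sum(x)
}

# Random 64-cell count table: Poisson counts over sense codons, occasionally
# zeroing whole families to exercise sparse inputs.
random_count_table <- function(lambda = 5, drop_family_prob = 0.1) {
  sense <- unlist(ORACLE_FAMILIES, use.names = FALSE)
  sense <- c(sense, "ATG", "TGG")
  x <- stats::rpois(length(sense), lambda)
  names(x) <- sense
  for (fam in ORACLE_FAMILIES) {
    if (stats::runif(1) < drop_family_prob) x[fam] <- 0
  }
  x
}

# Sequence with, for each amino acid, n copies of a single fixed codon
# (alphabetically first of the family, plus ATG and TGG).
one_codon_per_family_seq <- function(n = 10) {
  picks <- vapply(ORACLE_FAMILIES, function(fam) sort(fam)[1], character(1))
  paste(rep(c(picks, "ATG", "TGG"), each = n), collapse = "")
}

# Minimal GenBank flat-file text with configurable CDS locations.
genbank_fixture <- function(accession, sequence, cds_locations) {
  seq_lc <- tolower(sequence)
  chunks <- substring(seq_lc, seq(1, nchar(seq_lc), 60),
                      pmin(seq(1, nchar(seq_lc), 60) + 59, nchar(seq_lc)))
  origin <- sprintf("%9d %s", seq(1, nchar(seq_lc), 60),
                    vapply(chunks, function(ch)
                      paste(substring(ch, seq(1, nchar(ch), 10),
                                      pmin(seq(1, nchar(ch), 10) + 9,
                                           nchar(ch))),
                            collapse = " "), character(1)))
  c(
    sprintf("LOCUS       %s              %d bp    DNA     linear   VRL 01-JAN-2000",
            accession, nchar(sequence)),
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence)),
    unlist(lapply(cds_locations, function(loc)
      sprintf("     CDS             %s", loc))),
    "ORIGIN",
    origin,
    "//"
  )
}
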
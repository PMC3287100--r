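# Core codon-usage statistics on a 64-cell codon count table: composition,
# RSCU, representation classes, Wright's effective number of codons, GC
# partitions and the expected ENC curve.

#' Codon count table
#'
#' A complete 64-cell codon count table. Stop codons are never counted
#' (their cells are always zero): they carry no synonymous-usage
#' information, so `n_codons` is the number of counted sense codons.
#'
#' @param counts Named non-negative integer vector; names are DNA codons.
#'   Missing codons are filled with zero. Counts supplied for stop codons
#'   are dropped with a warning.
#' @param source_ids Character vector of contributing sequence ids.
#' @return An object of class `codon_counts` with fields `counts` (named
#'   length-64 vector in alphabetical codon order), `n_codons`, `source_ids`.
#' @export
#' @examples
#' codon_counts(c(ATG = 1, AAA = 2, TTT = 1))
codon_counts <- function(counts, source_ids = character(0)) {
  if (is.null(names(counts)) || any(!names(counts) %in% CODONS)) {
    bad <- setdiff(names(counts), CODONS)
    stop("counts must be named by DNA codons; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("negative codon counts", call. = FALSE)
  full <- stats::setNames(numeric(length(CODONS)), CODONS)
  full[names(counts)] <- full[names(counts)] + counts
  if (any(full[STOP_CODONS] > 0)) {
    warning("stop-codon counts are never counted; dropping ",
            sum(full[STOP_CODONS]), " stop codon(s)", call. = FALSE)
    full[STOP_CODONS] <- 0
  }
  structure(
    list(counts = full, n_codons = sum(full),
         source_ids = as.character(source_ids)),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts: ", x$n_codons, " codons from ",
      max(1L, length(x$source_ids)), " source(s)\n", sep = "")
  invisible(x)
}

#' Count codons in coding sequences
#'
#' Tallies the in-frame codons of one or more [coding_sequence()] records
#' into 64-cell count tables. Ambiguous codons and stop codons (terminal or
#' flagged-internal) are excluded from the counts.
#'
#' @param seqs A `coding_sequence` or list of them.
#' @param pool If `TRUE`, return a single pooled table summed across all
#'   sequences; otherwise (default) one table per sequence.
#' @return A `codon_counts` object (`pool = TRUE` or single input) or a named
#'   list of them.
#' @export
#' @examples
#' s <- coding_sequence("s1", "ATGAAATAG")
#' count_codons(s)$counts[c("ATG", "AAA")]
count_codons <- function(seqs, pool = FALSE) {
  seqs <- .as_cds_list(seqs)
  if (length(seqs) == 0L) stop("empty input list", call. = FALSE)
  one <- function(s) {
    keep <- s$codons[!s$ambiguous & !(s$codons %in% STOP_CODONS)]
    tab <- table(factor(keep, levels = CODONS))
    codon_counts(stats::setNames(as.numeric(tab), CODONS), source_ids = s$id)
  }
  tables <- lapply(seqs, one)
  if (pool) {
    total <- Reduce(`+`, lapply(tables, function(t) t$counts))
    return(codon_counts(total,
                        source_ids = vapply(seqs, `[[`, character(1), "id")))
  }
  if (length(tables) == 1L) return(tables[[1L]])
  stats::setNames(tables, vapply(seqs, `[[`, character(1), "id"))
}

.nt_at <- function(codons, pos) substr(codons, pos, pos)

#' Nucleotide composition profile of a codon count table
#'
#' Computes overall nucleotide percentages over all three positions of the
#' counted (sense) codons, the percentages at the third position of the 59
#' synonymous sense codons only (excluding ATG, TGG and stops, as in GC3s),
#' and the GC content pooled over codon positions 1 and 2 (GC12) and at the
#' synonymous third positions (GC3).
#'
#' @param counts A [codon_counts()] table with `n_codons >= 1`.
#' @return An object of class `composition_profile`: list with `overall`
#'   (named percentages T, C, A, G), `third_syn` (same names, `NA` when the
#'   table holds no synonymous sense codon), `gc12`, `gc3`, `n_codons`,
#'   `n_syn`.
#' @export
#' @examples
#' cc <- count_codons(coding_sequence("a", "GCTGCTGCT"))
#' composition(cc)$third_syn
composition <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_codons < 1) stop("empty codon count table", call. = FALSE)
  x <- counts$counts[SENSE_CODONS]
  nts <- c("T", "C", "A", "G")

  slot_tab <- function(codon_set, pos) {
    cnt <- counts$counts[codon_set]
    vapply(nts, function(b)
      sum(cnt[.nt_at(codon_set, pos) == b]), numeric(1))
  }
  overall_tab <- slot_tab(SENSE_CODONS, 1) + slot_tab(SENSE_CODONS, 2) +
    slot_tab(SENSE_CODONS, 3)
  overall <- 100 * overall_tab / sum(overall_tab)

  n_syn <- sum(counts$counts[SYN_SENSE_CODONS])
  if (n_syn > 0) {
    third_tab <- slot_tab(SYN_SENSE_CODONS, 3)
    third_syn <- 100 * third_tab / n_syn
    gc3 <- unname(third_syn["G"] + third_syn["C"])
  } else {
    third_syn <- stats::setNames(rep(NA_real_, 4), nts)
    gc3 <- NA_real_
  }

  pos12 <- slot_tab(SENSE_CODONS, 1) + slot_tab(SENSE_CODONS, 2)
  gc12 <- unname(100 * (pos12["G"] + pos12["C"]) / sum(pos12))

  structure(
    list(overall = overall, third_syn = third_syn, gc12 = gc12, gc3 = gc3,
         n_codons = counts$n_codons, n_syn = n_syn),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("composition_profile over", x$n_codons, "codons\n")
  cat("  overall %:  ", paste(sprintf("%s=%.2f", names(x$overall), x$overall),
                              collapse = " "), "\n")
  cat("  third syn %:", paste(sprintf("%s=%.2f", names(x$third_syn),
                                      x$third_syn), collapse = " "), "\n")
  cat(sprintf("  GC12 = %.2f%%  GC3 = %.2f%%\n", x$gc12, x$gc3))
  invisible(x)
}

#' GC content at codon positions 1+2 and at synonymous third positions
#'
#' @param counts A [codon_counts()] table.
#' @return Named numeric vector `c(gc12 = , gc3 = )`, in percent.
#' @export
#' @examples
#' gc_partition(count_codons(coding_sequence("a", "GCGGCG")))
gc_partition <- function(counts) {
  p <- composition(counts)
  c(gc12 = p$gc12, gc3 = p$gc3)
}

#' Relative synonymous codon usage
#'
#' For amino acid family i with degeneracy n_i, total count X_i and codon
#' count x_ij, RSCU_ij = x_ij * n_i / X_i: the observed count relative to the
#' count expected if all synonymous codons were used equally. Values within a
#' family sum to the family's degeneracy; RSCU does not depend on amino acid
#' composition or sequence length. Families absent from the table (X_i = 0)
#' yield `NA` values and are listed in the `undefined` attribute.
#'
#' @param counts A [codon_counts()] table with `n_codons >= 1`.
#' @return An object of class `rscu_vector`: a named numeric vector over the
#'   59 synonymous sense codons (alphabetical), with attribute `undefined`
#'   (codons of absent families).
#' @export
#' @examples
#' v <- rscu(codon_counts(c(TTT = 3, TTC = 1)))
#' v[c("TTT", "TTC")]
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_codons < 1) stop("empty codon count table", call. = FALSE)
  vals <- stats::setNames(rep(NA_real_, length(SYN_SENSE_CODONS)),
                          SYN_SENSE_CODONS)
  undefined <- character(0)
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    x <- counts$counts[fam]
    total <- sum(x)
    if (total == 0) {
      undefined <- c(undefined, fam)
    } else {
      vals[fam] <- x * length(fam) / total
    }
  }
  structure(vals, undefined = undefined, class = c("rscu_vector", "numeric"))
}

#' Classify codons as over-/under-represented
#'
#' Applies the conventional strict thresholds: RSCU > 1.6 is over-represented,
#' RSCU < 0.6 under-represented, anything else (including the boundaries)
#' normal; codons of absent families are `undefined`.
#'
#' @param v An [rscu()] vector.
#' @return Named character vector over the 59 codons with values in
#'   `c("over", "under", "normal", "undefined")`.
#' @export
#' @examples
#' classify_representation(rscu(codon_counts(c(TTT = 9, TTC = 1))))[["TTT"]]
classify_representation <- function(v) {
  stopifnot(inherits(v, "rscu_vector"))
  out <- ifelse(is.na(v), "undefined",
                ifelse(v > 1.6, "over", ifelse(v < 0.6, "under", "normal")))
  stats::setNames(as.character(out), names(v))
}

#' Effective number of codons (ENC)
#'
#' Wright's estimator of absolute codon usage bias, ranging from 20 (one
#' codon per amino acid) to 61 (all synonymous codons used equally). For each
#' amino-acid family with total count n >= 2 and within-family frequencies
#' p_j, the homozygosity is F = (n * sum(p_j^2) - 1) / (n - 1); families with
#' n < 2 or F <= 0 are excluded. With F_k the mean homozygosity of the
#' degeneracy-k families,
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' capped at 61. If no 3-fold family (Ile) is usable, F_3 is imputed as
#' (F_2 + F_4)/2 — the standard practice, since Ile is the lone 3-fold family
#' and often sparse. If the 2-, 4- or 6-fold class has no usable family the
#' ENC is reported missing (`NA`) with diagnostics rather than imputed.
#'
#' @param counts A [codon_counts()] table with `n_codons >= 1`.
#' @return An object of class `enc_result`: list with `enc` (numeric, possibly
#'   `NA`), `f_bar` (named mean homozygosities for classes 2/3/4/6),
#'   `families_used` (per-class counts) and `imputed_classes`.
#' @export
#' @examples
#' enc(codon_counts(c(TTT = 4, GAT = 3, GAC = 1)))$enc
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_codons < 1) stop("empty codon count table", call. = FALSE)

  fam_F <- rep(NA_real_, length(SYN_FAMILIES))
  names(fam_F) <- names(SYN_FAMILIES)
  for (aa in names(SYN_FAMILIES)) {
    x <- counts$counts[SYN_FAMILIES[[aa]]]
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f > 0) fam_F[aa] <- f
  }

  classes <- c("2", "3", "4", "6")
  f_bar <- stats::setNames(rep(NA_real_, 4), classes)
  families_used <- stats::setNames(integer(4), classes)
  for (k in classes) {
    in_class <- names(FAMILY_DEGENERACY)[FAMILY_DEGENERACY == as.integer(k)]
    usable <- fam_F[in_class]
    usable <- usable[!is.na(usable)]
    families_used[k] <- length(usable)
    if (length(usable)) f_bar[k] <- mean(usable)
  }

  imputed <- character(0)
  if (is.na(f_bar["3"]) && !is.na(f_bar["2"]) && !is.na(f_bar["4"])) {
    f_bar["3"] <- (f_bar["2"] + f_bar["4"]) / 2
    imputed <- "3"
  }

  enc_val <- NA_real_
  if (!anyNA(f_bar)) {
    enc_val <- 2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] +
      5 / f_bar[["4"]] + 3 / f_bar[["6"]]
    enc_val <- min(enc_val, 61)
  }

  structure(
    list(enc = enc_val, f_bar = f_bar, families_used = families_used,
         imputed_classes = imputed),
    class = "enc_result"
  )
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("ENC = %s  (F2=%.4f F3=%.4f F4=%.4f F6=%.4f%s)\n",
              ifelse(is.na(x$enc), "NA", sprintf("%.2f", x$enc)),
              x$f_bar[["2"]], x$f_bar[["3"]], x$f_bar[["4"]], x$f_bar[["6"]],
              if (length(x$imputed_classes))
                paste0("; imputed class ",
                       paste(x$imputed_classes, collapse = ",")) else ""))
  invisible(x)
}

#' Expected ENC under GC3 compositional constraint alone
#'
#' The ENC expected when nucleotide composition at the synonymous third
#' position is the only force shaping codon choice:
#' \deqn{ENC_{exp}(s) = 2 + s + 29 / (s^2 + (1-s)^2)}
#' with s the GC3 fraction. Strains falling clearly below this curve show
#' codon usage bias beyond what mutation pressure alone explains.
#'
#' @param gc3 GC3 fraction(s) in \[0, 1\]. Vectorized.
#' @return Expected ENC value(s).
#' @export
#' @examples
#' expected_enc(0.5)  # 60.5
expected_enc <- function(gc3) {
  if (any(is.na(gc3)) || any(gc3 < 0) || any(gc3 > 1)) {
    stop("gc3 must be a fraction in [0, 1]", call. = FALSE)
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}
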
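# Synthetic coding-sequence cohorts with independently controllable
# mutational composition (per-position nucleotide probabilities) and
# within-family codon selection (target RSCU preferences). Amino-acid
# sequence and synonymous choice are drawn separately, so amino-acid
# composition and codon preference can be varied independently — the
# property that makes RSCU's invariances testable.

#' Position-wise mutation model
#'
#' Nucleotide probabilities at each of the three codon positions, embodying
#' compositional (mutation-pressure) constraints on codon choice.
#'
#' @param pos_probs 3 x 4 numeric matrix; rows are codon positions 1-3,
#'   columns named A, C, G, T; each row sums to 1. Defaults to uniform.
#' @return An object of class `mutation_model`.
#' @export
#' @examples
#' mutation_model()  # uniform composition
mutation_model <- function(pos_probs = matrix(0.25, 3, 4,
                                              dimnames = list(NULL,
                                                              c("A", "C",
                                                                "G", "T")))) {
  pos_probs <- as.matrix(pos_probs)
  if (!identical(dim(pos_probs), c(3L, 4L))) {
    stop("pos_probs must be a 3 x 4 matrix (positions x A,C,G,T)",
         call. = FALSE)
  }
  if (is.null(colnames(pos_probs))) colnames(pos_probs) <- c("A", "C", "G", "T")
  pos_probs <- pos_probs[, c("A", "C", "G", "T")]
  if (any(pos_probs < 0) || any(abs(rowSums(pos_probs) - 1) > 1e-12)) {
    stop("each position's probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  structure(list(pos_probs = pos_probs), class = "mutation_model")
}

#' Mutation model from target GC content
#'
#' Convenience constructor: all three positions (or only the third) get
#' P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#'
#' @param gc GC fraction in \[0, 1\].
#' @param third_only If `TRUE`, positions 1-2 stay uniform and only the third
#'   position is skewed.
#' @return A [mutation_model()].
#' @export
mutation_model_gc <- function(gc, third_only = FALSE) {
  stopifnot(gc >= 0, gc <= 1)
  skew <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  m <- rbind(skew, skew, skew)
  if (third_only) m[1:2, ] <- 0.25
  mutation_model(m)
}

#' Within-family selection model
#'
#' Target RSCU preferences over the 59 synonymous sense codons: within each
#' amino-acid family the values sum to the family's degeneracy, and the
#' within-family codon choice probabilities are values / degeneracy. This is
#' the "translational selection" side of the generator.
#'
#' @param target_rscu Named numeric vector over the 59 synonymous sense
#'   codons (any order); non-negative, each family summing to its
#'   degeneracy. Defaults to uniform usage (all 1.0).
#' @return An object of class `selection_model`.
#' @export
#' @examples
#' selection_model()  # neutral: every RSCU target = 1
selection_model <- function(target_rscu = NULL) {
  if (is.null(target_rscu)) {
    target_rscu <- stats::setNames(rep(1, length(SYN_SENSE_CODONS)),
                                   SYN_SENSE_CODONS)
  }
  if (is.null(names(target_rscu)) ||
      !setequal(names(target_rscu), SYN_SENSE_CODONS)) {
    stop("target_rscu must be named by the 59 synonymous sense codons",
         call. = FALSE)
  }
  target_rscu <- target_rscu[SYN_SENSE_CODONS]
  if (any(target_rscu < 0)) stop("target RSCU values must be >= 0",
                                 call. = FALSE)
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    if (abs(sum(target_rscu[fam]) - length(fam)) > 1e-9) {
      stop("family ", aa, ": target RSCU must sum to its degeneracy (",
           length(fam), ")", call. = FALSE)
    }
  }
  structure(list(target_rscu = target_rscu), class = "selection_model")
}

#' Selection model concentrated on one codon per family
#'
#' Builds a maximally biased [selection_model()]: within each family all mass
#' goes to a single codon (by default the alphabetically first), the target
#' RSCU of the chosen codon being the family's degeneracy.
#'
#' @param preferred Optional named character vector `amino_acid -> codon`
#'   overriding the default choice for some families.
#' @return A [selection_model()].
#' @export
selection_model_concentrated <- function(preferred = NULL) {
  target <- stats::setNames(rep(0, length(SYN_SENSE_CODONS)),
                            SYN_SENSE_CODONS)
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    pick <- if (!is.null(preferred) && aa %in% names(preferred)) {
      preferred[[aa]]
    } else fam[1L]
    if (!pick %in% fam) stop("codon ", pick, " does not encode ", aa,
                             call. = FALSE)
    target[pick] <- length(fam)
  }
  selection_model(target)
}

#' Cohort specification
#'
#' @param n_strains Number of sequences to generate (>= 1).
#' @param n_codons Amino-acid-coding codons per sequence (>= 1); a terminal
#'   stop codon is appended on top of these.
#' @param w Mixture weight in \[0, 1\]: 0 = codon choice driven purely by the
#'   mutation model, 1 = purely by the selection model.
#' @param amino_acid_profile Named probability vector over the 20 amino acids
#'   (one-letter codes, the 18 multi-codon families plus M and W), summing
#'   to 1. Defaults to uniform.
#' @param seed Integer seed; the cohort is deterministic given the spec.
#' @param label Optional group label stored in each sequence's `meta`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_strains, n_codons, w = 0,
                        amino_acid_profile = NULL, seed = 1L, label = NULL) {
  stopifnot(n_strains >= 1, n_codons >= 1, w >= 0, w <= 1)
  if (is.null(amino_acid_profile)) {
    amino_acid_profile <- stats::setNames(
      rep(1 / length(COHORT_AMINO_ACIDS), length(COHORT_AMINO_ACIDS)),
      COHORT_AMINO_ACIDS)
  }
  if (is.null(names(amino_acid_profile)) ||
      !setequal(names(amino_acid_profile), COHORT_AMINO_ACIDS)) {
    stop("amino_acid_profile must be named by the 20 amino acids",
         call. = FALSE)
  }
  amino_acid_profile <- amino_acid_profile[COHORT_AMINO_ACIDS]
  if (any(amino_acid_profile < 0) ||
      abs(sum(amino_acid_profile) - 1) > 1e-12) {
    stop("amino_acid_profile must be a probability vector", call. = FALSE)
  }
  structure(
    list(n_strains = as.integer(n_strains), n_codons = as.integer(n_codons),
         w = w, amino_acid_profile = amino_acid_profile,
         seed = as.integer(seed), label = label),
    class = "cohort_spec"
  )
}

# Within-family codon probabilities under the mutation model: the product of
# the three positional nucleotide probabilities, renormalized in the family.
.mutation_family_probs <- function(mut, codons) {
  pp <- mut$pos_probs
  raw <- vapply(codons, function(cd) {
    pp[1, substr(cd, 1, 1)] * pp[2, substr(cd, 2, 2)] *
      pp[3, substr(cd, 3, 3)]
  }, numeric(1))
  raw
}

# Mixed within-family codon choice distribution for every amino acid.
.codon_choice_probs <- function(mut, sel, w) {
  out <- list()
  for (aa in COHORT_AMINO_ACIDS) {
    fam <- AA_CODONS[[aa]]
    p_mut <- .mutation_family_probs(mut, fam)
    if (sum(p_mut) > 0) p_mut <- p_mut / sum(p_mut)
    if (aa %in% names(SYN_FAMILIES)) {
      p_sel <- sel$target_rscu[fam] / length(fam)
    } else {
      p_sel <- stats::setNames(1, fam)  # Met, Trp: single codon
    }
    p <- (1 - w) * p_mut + w * p_sel
    if (sum(p) <= 0) {
      stop("family ", aa, " has zero probability mass under both models",
           call. = FALSE)
    }
    out[[aa]] <- p / sum(p)
  }
  out
}

#' Simulate a cohort of coding sequences
#'
#' For each codon slot an amino acid is drawn from the spec's profile; the
#' codon within the family is then drawn from the mixture
#' `(1 - w) * P_mut(codon | family) + w * P_sel(codon | family)`, each
#' conditional renormalized within the family. Stop codons are never
#' generated internally; one terminal stop, drawn from the mutation model
#' restricted to the three stops, is appended to each sequence. Output is
#' deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param mut A [mutation_model()] (default uniform).
#' @param sel A [selection_model()] (default neutral).
#' @return List of [coding_sequence()] records with `w`, `seed` and any group
#'   label in `meta`.
#' @export
#' @examples
#' cohort <- simulate_cds(cohort_spec(2, 100, seed = 7))
#' length(cohort[[1]]$codons)  # 100 + terminal stop
simulate_cds <- function(spec, mut = mutation_model(),
                         sel = selection_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(mut, "mutation_model"),
            inherits(sel, "selection_model"))
  choice <- .codon_choice_probs(mut, sel, spec$w)
  stop_p <- .mutation_family_probs(mut, STOP_CODONS)
  stop_p <- if (sum(stop_p) > 0) stop_p / sum(stop_p) else
    stats::setNames(rep(1 / 3, 3), STOP_CODONS)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  prof <- spec$amino_acid_profile
  out <- vector("list", spec$n_strains)
  for (i in seq_len(spec$n_strains)) {
    aas <- sample(names(prof), spec$n_codons, replace = TRUE, prob = prof)
    codons <- character(spec$n_codons)
    for (aa in unique(aas)) {
      idx <- which(aas == aa)
      fam_p <- choice[[aa]]
      codons[idx] <- sample(names(fam_p), length(idx), replace = TRUE,
                            prob = fam_p)
    }
    terminal <- sample(STOP_CODONS, 1L, prob = stop_p)
    id <- sprintf("%ssim%03d",
                  if (is.null(spec$label)) "" else paste0(spec$label, "_"), i)
    out[[i]] <- coding_sequence(
      id, paste0(c(codons, terminal), collapse = ""),
      meta = list(group = spec$label, w = spec$w, seed = spec$seed))
  }
  out
}

#' Simulate labeled groups of cohorts
#'
#' Generates one cohort per spec (each with its own models and label) and
#' returns their union; group labels travel in each sequence's `meta` for
#' downstream coloring and centroid checks.
#'
#' @param specs List of [cohort_spec()]s (>= 2), each with a distinct label.
#' @param muts List of [mutation_model()]s aligned with `specs`, or a single
#'   model recycled.
#' @param sels List of [selection_model()]s aligned with `specs`, or a single
#'   model recycled.
#' @return List of [coding_sequence()] records (all groups concatenated).
#' @export
simulate_groups <- function(specs, muts = mutation_model(),
                            sels = selection_model()) {
  if (length(specs) < 2L) stop("need at least 2 group specs", call. = FALSE)
  if (inherits(muts, "mutation_model")) muts <- rep(list(muts), length(specs))
  if (inherits(sels, "selection_model")) sels <- rep(list(sels), length(specs))
  stopifnot(length(muts) == length(specs), length(sels) == length(specs))
  labels <- vapply(specs, function(s)
    if (is.null(s$label)) NA_character_ else s$label, character(1))
  if (anyNA(labels)) {
    stop("every group spec needs a label", call. = FALSE)
  }
  out <- list()
  for (i in seq_along(specs)) {
    out <- c(out, simulate_cds(specs[[i]], muts[[i]], sels[[i]]))
  }
  out
}
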
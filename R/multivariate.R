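# Cross-strain analysis: PCA on the strains x 59 RSCU matrix and the Pearson
# correlation suite over composition variables.

#' Assemble an RSCU matrix from per-strain vectors
#'
#' Rows are strains, columns the 59 synonymous sense codons in alphabetical
#' order. Cells undefined in a strain's vector (amino-acid family absent)
#' are imputed with the family-neutral value 1.0 and reported in a warning:
#' an absent family carries no preference information, and 1.0 is the value
#' of equal synonymous usage.
#'
#' @param vectors List of [rscu()] vectors.
#' @param ids Character vector of strain ids, same length as `vectors`.
#' @return Numeric matrix (strains x 59) with `dimnames = list(ids, codons)`
#'   and attribute `imputed` (list of imputed codons per strain).
#' @export
build_rscu_matrix <- function(vectors, ids) {
  if (length(vectors) != length(ids)) {
    stop("ids and vectors must have equal length", call. = FALSE)
  }
  if (length(vectors) < 2L) {
    stop("need at least 2 strains to build an RSCU matrix", call. = FALSE)
  }
  ok <- vapply(vectors, function(v)
    inherits(v, "rscu_vector") && length(v) == length(SYN_SENSE_CODONS) &&
      identical(names(v), SYN_SENSE_CODONS), logical(1))
  if (!all(ok)) {
    stop("input ", which(!ok)[1L],
         " is not a 59-codon rscu_vector", call. = FALSE)
  }
  m <- do.call(rbind, lapply(vectors, as.numeric))
  dimnames(m) <- list(as.character(ids), SYN_SENSE_CODONS)
  imputed <- lapply(vectors, function(v) names(v)[is.na(v)])
  names(imputed) <- ids
  n_imp <- sum(lengths(imputed))
  if (n_imp > 0) {
    m[is.na(m)] <- 1.0
    warning(n_imp, " undefined RSCU cell(s) imputed at the neutral value 1.0",
            call. = FALSE)
  }
  attr(m, "imputed") <- imputed
  m
}

#' Principal component analysis of an RSCU matrix
#'
#' Column-centered PCA of the strains x 59 RSCU matrix. By default the
#' decomposition uses the covariance of the centered values (RSCU is already
#' a common dimensionless scale); `scaling = "correlation"` standardizes each
#' codon column to unit variance first. Component signs are fixed by the
#' convention that the loading of largest magnitude in each component is
#' positive, making results deterministic across platforms.
#'
#' @param m Matrix from [build_rscu_matrix()] (>= 3 strains for meaningful
#'   variance fractions).
#' @param scaling `"covariance"` (default) or `"correlation"`.
#' @return An object of class `pca_result`: list with `coordinates` (strain
#'   scores; columns PC1, PC2, ...), `variance_fraction`, `loadings`
#'   (59 x k) and `scaling`. A zero-variance input yields `NA` variance
#'   fractions.
#' @export
pca_rscu <- function(m, scaling = c("covariance", "correlation")) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(m), ncol(m) == length(SYN_SENSE_CODONS))
  if (nrow(m) < 3L) {
    warning("fewer than 3 strains: variance fractions are not meaningful",
            call. = FALSE)
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  if (total_var < 1e-12) {
    k <- min(nrow(m) - 1L, ncol(m))
    return(structure(
      list(coordinates = matrix(0, nrow(m), max(k, 1L),
                                dimnames = list(rownames(m), NULL)),
           variance_fraction = rep(NA_real_, max(k, 1L)),
           loadings = NULL, scaling = scaling),
      class = "pca_result"))
  }
  if (scaling == "correlation") {
    sds <- apply(m, 2, stats::sd)
    if (any(sds < 1e-12)) {
      stop("correlation scaling impossible: ",
           sum(sds < 1e-12), " zero-variance codon column(s)", call. = FALSE)
    }
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = (scaling == "correlation"))
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(fit$rotation))) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  colnames(fit$x) <- paste0("PC", seq_len(ncol(fit$x)))
  structure(
    list(coordinates = fit$x, variance_fraction = vf,
         loadings = fit$rotation, scaling = scaling),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat("pca_result (", x$scaling, " scaling): ", nrow(x$coordinates),
      " strains\n", sep = "")
  if (!all(is.na(vf))) {
    cat(sprintf("  PC1 %.2f%%, PC2 %.2f%% of total variance\n",
                100 * vf[1], 100 * vf[2]))
  } else cat("  zero-variance input: variance fractions undefined\n")
  invisible(x)
}

#' Pearson product-moment correlation with t-test p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite values.
#' @return List with `r`, `p` (two-sided, t-distribution with n-2 df) and `n`.
#'   Zero variance in either argument yields `r = NA`, `p = NA`.
#' @export
#' @examples
#' pearson(1:10, 2 * (1:10) + 3)$r
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite observations", call. = FALSE)
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlation suite over composition profiles
#'
#' All pairwise Pearson correlations between the overall nucleotide contents
#' (T%, C%, A%, G%) and the synonymous third-position contents (T3%, C3%,
#' A3%, G3%), plus GC12 vs GC3, and ENC vs GC3 when per-strain ENC values are
#' supplied.
#'
#' @param profiles List of [composition()] profiles (>= 3).
#' @param enc_values Optional numeric vector of per-strain ENC values aligned
#'   with `profiles`.
#' @return Data frame with columns `variable_x`, `variable_y`, `r`, `p`, `n`.
#' @export
correlation_suite <- function(profiles, enc_values = NULL) {
  ok <- vapply(profiles, inherits, logical(1), "composition_profile")
  if (!all(ok)) stop("profiles must be composition_profile objects",
                     call. = FALSE)
  if (length(profiles) < 3L) stop("need at least 3 profiles", call. = FALSE)
  nts <- c("T", "C", "A", "G")
  tab <- data.frame(
    sapply(nts, function(b) vapply(profiles, function(p)
      p$overall[[b]], numeric(1))),
    sapply(nts, function(b) vapply(profiles, function(p)
      p$third_syn[[b]], numeric(1))),
    gc12 = vapply(profiles, `[[`, numeric(1), "gc12"),
    gc3 = vapply(profiles, `[[`, numeric(1), "gc3")
  )
  names(tab)[1:8] <- c(paste0(nts, "%"), paste0(nts, "3%"))
  pairs <- expand.grid(variable_x = paste0(nts, "%"),
                       variable_y = paste0(nts, "3%"),
                       stringsAsFactors = FALSE)
  pairs <- rbind(pairs, data.frame(variable_x = "gc12", variable_y = "gc3"))
  if (!is.null(enc_values)) {
    if (length(enc_values) != length(profiles)) {
      stop("enc_values must align with profiles", call. = FALSE)
    }
    tab$enc <- enc_values
    pairs <- rbind(pairs, data.frame(variable_x = "enc", variable_y = "gc3"))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pearson(tab[[pairs$variable_x[i]]], tab[[pairs$variable_y[i]]])
    data.frame(variable_x = pairs$variable_x[i],
               variable_y = pairs$variable_y[i],
               r = pr$r, p = pr$p, n = pr$n)
  })
  do.call(rbind, res)
}
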
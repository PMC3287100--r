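# Virus-vs-host codon usage concordance against a bundled host reference.

#' Load a bundled host RSCU reference table
#'
#' The package ships `"human-Table2"`, a published human RSCU reference over
#' the 59 synonymous sense codons, frozen at its printed two-decimal values
#' so comparisons are download-free and stable.
#'
#' @param name Reference label; currently only `"human-Table2"`.
#' @return An object of class `host_reference`: named numeric vector over the
#'   59 codons with attributes `name` and `amino_acid`.
#' @export
#' @examples
#' ref <- load_host_reference("human-Table2")
#' ref[["CTG"]]
load_host_reference <- function(name = "human-Table2") {
  available <- c("human-Table2")
  if (!name %in% available) {
    stop("unknown host reference '", name, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", "human_rscu_reference.csv",
                      package = "codonbias", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$rscu, tab$codon)[SYN_SENSE_CODONS]
  structure(vals, name = name,
            amino_acid = CODON_AA[SYN_SENSE_CODONS],
            class = c("host_reference", "numeric"))
}

#' Published pooled HBV RSCU profile
#'
#' The pooled hepatitis B virus RSCU column published alongside the bundled
#' human reference, exposed for worked examples and cross-checks.
#'
#' @return An [rscu()]-style vector over the 59 synonymous sense codons.
#' @export
hbv_pooled_rscu <- function() {
  path <- system.file("extdata", "human_rscu_reference.csv",
                      package = "codonbias", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$hbv_rscu, tab$codon)[SYN_SENSE_CODONS]
  structure(vals, undefined = character(0),
            class = c("rscu_vector", "numeric"))
}

#' Compare a viral RSCU vector against a host reference
#'
#' A codon is *coincident* when virus and host sit on the same side of the
#' neutral value 1 (both >= 1 or both <= 1) and *antagonistic* otherwise.
#' Per family, the report counts both classes and flags whether the
#' most-preferred codon (argmax RSCU) is the same in virus and host. Codons
#' the virus uses freely (RSCU > 1) that the host under-represents
#' (RSCU < 0.6) are listed in `highly_used_against_host`.
#'
#' @param virus An [rscu()] vector.
#' @param host A [load_host_reference()] table.
#' @return An object of class `comparison_report`: list with `per_codon`
#'   (data frame: codon, amino_acid, virus, host, class), `per_family`
#'   (data frame: amino_acid, n_coincident, n_antagonistic,
#'   preferred_match) and `highly_used_against_host` (character vector).
#' @export
compare_rscu <- function(virus, host) {
  stopifnot(inherits(virus, "rscu_vector"), inherits(host, "host_reference"))
  defined <- names(virus)[!is.na(virus)]
  v <- as.numeric(virus[defined])
  h <- as.numeric(host[defined])
  coincident <- (v >= 1 & h >= 1) | (v <= 1 & h <= 1)
  per_codon <- data.frame(
    codon = defined,
    amino_acid = unname(CODON_AA[defined]),
    virus = v, host = h,
    class = ifelse(coincident, "coincident", "antagonistic"),
    stringsAsFactors = FALSE
  )
  fam_split <- split(per_codon, per_codon$amino_acid)
  per_family <- do.call(rbind, lapply(fam_split, function(d) {
    data.frame(
      amino_acid = d$amino_acid[1L],
      n_coincident = sum(d$class == "coincident"),
      n_antagonistic = sum(d$class == "antagonistic"),
      preferred_match = d$codon[which.max(d$virus)] ==
        d$codon[which.max(d$host)],
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_family) <- NULL
  structure(
    list(per_codon = per_codon, per_family = per_family,
         highly_used_against_host = per_codon$codon[v > 1 & h < 0.6]),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report: ", sum(x$per_codon$class == "coincident"),
      " coincident / ", sum(x$per_codon$class == "antagonistic"),
      " antagonistic codons\n", sep = "")
  if (length(x$highly_used_against_host)) {
    cat("  highly used against host: ",
        paste(x$highly_used_against_host, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Pearson similarity between viral and host RSCU vectors
#'
#' @param virus An [rscu()] vector.
#' @param host A [load_host_reference()] table.
#' @return Correlation in \[-1, 1\] over the codons defined in the virus
#'   vector, or `NA` if either restriction is constant.
#' @export
similarity_score <- function(virus, host) {
  stopifnot(inherits(virus, "rscu_vector"), inherits(host, "host_reference"))
  defined <- names(virus)[!is.na(virus)]
  if (length(defined) < 2L) {
    stop("need at least 2 defined codons in common", call. = FALSE)
  }
  v <- as.numeric(virus[defined])
  h <- as.numeric(host[defined])
  if (stats::sd(v) < 1e-15 || stats::sd(h) < 1e-15) return(NA_real_)
  stats::cor(v, h)
}
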
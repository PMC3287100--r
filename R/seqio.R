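# Reading, validating and normalizing coding sequences.

#' Validation policy for coding-sequence ingestion
#'
#' Controls how [coding_sequence()] and the file readers treat records whose
#' length is not a multiple of 3, records with an internal stop codon, and
#' codons containing ambiguity symbols (anything outside A/C/G/T).
#'
#' @param on_bad_length `"error"` (default) or `"truncate-trailing"` (drop the
#'   1-2 trailing nucleotides that break the frame).
#' @param on_internal_stop `"warn-and-keep"` (default: keep the record, set its
#'   `internal_stop` flag and emit a warning) or `"error"`.
#' @param on_ambiguous `"skip-codon"` (default: keep the codon in the record
#'   but flag it so downstream counts ignore it) or `"error"`.
#' @return An object of class `validation_policy`.
#' @export
#' @examples
#' validation_policy()
#' validation_policy(on_bad_length = "truncate-trailing")
validation_policy <- function(on_bad_length = c("error", "truncate-trailing"),
                              on_internal_stop = c("warn-and-keep", "error"),
                              on_ambiguous = c("skip-codon", "error")) {
  structure(
    list(
      on_bad_length = match.arg(on_bad_length),
      on_internal_stop = match.arg(on_internal_stop),
      on_ambiguous = match.arg(on_ambiguous)
    ),
    class = "validation_policy"
  )
}

#' Construct a validated coding sequence
#'
#' Normalizes a nucleotide string (uppercase, U -> T), checks it against a
#' [validation_policy()], and splits it into in-frame codons. Codons containing
#' any symbol outside A/C/G/T are flagged ambiguous and excluded from all
#' downstream counting; a terminal stop codon is retained in the record but
#' never enters codon statistics (stop codons carry no synonymous-usage
#' information).
#'
#' @param id Record identifier (accession or user label).
#' @param sequence Nucleotide string over A/C/G/T/U plus IUPAC ambiguity codes.
#' @param policy A [validation_policy()].
#' @param meta Optional named list of labels (country, genotype, ...) carried
#'   through to reports.
#' @return An object of class `coding_sequence` with fields `id`, `sequence`,
#'   `codons`, `ambiguous` (logical per codon), `internal_stop` flag and
#'   `meta`.
#' @export
#' @examples
#' cs <- coding_sequence("s1", "ATGAAATAG")
#' cs$codons
coding_sequence <- function(id, sequence, policy = validation_policy(),
                            meta = list()) {
  stopifnot(inherits(policy, "validation_policy"))
  seq <- chartr("u", "t", toupper(as.character(sequence)))
  seq <- chartr("U", "T", seq)
  seq <- gsub("[ \t\r\n]", "", seq)
  if (nchar(seq) == 0L) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }

  if (nchar(seq) %% 3L != 0L) {
    if (policy$on_bad_length == "error") {
      stop("record '", id, "': length ", nchar(seq),
           " is not a multiple of 3", call. = FALSE)
    }
    seq <- substr(seq, 1L, 3L * (nchar(seq) %/% 3L))
    if (nchar(seq) == 0L) {
      stop("record '", id, "': fewer than 3 nucleotides", call. = FALSE)
    }
  }

  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  ambiguous <- grepl("[^ACGT]", codons)
  if (any(ambiguous) && policy$on_ambiguous == "error") {
    first <- which(ambiguous)[1L]
    stop("record '", id, "': ambiguous codon '", codons[first],
         "' at codon ", first, " (nucleotide ", 3L * first - 2L, ")",
         call. = FALSE)
  }

  internal <- !ambiguous & codons %in% STOP_CODONS
  internal[n] <- FALSE
  internal_stop <- any(internal)
  if (internal_stop) {
    first <- which(internal)[1L]
    if (policy$on_internal_stop == "error") {
      stop("record '", id, "': internal stop codon '", codons[first],
           "' at codon ", first, call. = FALSE)
    }
    warning("record '", id, "': internal stop codon '", codons[first],
            "' at codon ", first, " (kept; flagged)", call. = FALSE)
  }

  structure(
    list(id = as.character(id), sequence = seq, codons = codons,
         ambiguous = ambiguous, internal_stop = internal_stop,
         meta = as.list(meta)),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("coding_sequence '", x$id, "': ", length(x$codons), " codons (",
      sum(x$ambiguous), " ambiguous", if (x$internal_stop)
        ", internal stop flagged" else "", ")\n", sep = "")
  invisible(x)
}

.as_cds_list <- function(seqs) {
  if (inherits(seqs, "coding_sequence")) return(list(seqs))
  if (!is.list(seqs) || !all(vapply(seqs, inherits, logical(1),
                                    "coding_sequence"))) {
    stop("expected a coding_sequence or a list of them", call. = FALSE)
  }
  seqs
}

#' Read coding sequences from a FASTA file
#'
#' Each FASTA record becomes one validated [coding_sequence()]; record order
#' is preserved and U is normalized to T.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param policy A [validation_policy()].
#' @return List of `coding_sequence` objects.
#' @export
read_fasta <- function(path, policy = validation_policy()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- coding_sequence(ids[i], as.character(set[[i]]), policy)
  }
  out
}

#' Write coding sequences to FASTA
#'
#' Writes the normalized (DNA-alphabet) sequences; re-reading the file yields
#' identical codon lists.
#'
#' @param seqs A `coding_sequence` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- .as_cds_list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$sequence)))
  writeLines(lines, path)
  invisible(path)
}

# ---- GenBank flat files -----------------------------------------------------

# Parse a GenBank location string into a nucleotide sequence extractor.
# Supports N, N..M, join(...), complement(...) and their nesting. Remote
# references ("ACC:1..10") and partial markers ("<", ">") are rejected: their
# coordinates cannot be honored from a single record.
.extract_location <- function(loc, genome, id) {
  loc <- gsub("[ \t]", "", loc)
  if (grepl("[<>]", loc)) {
    stop("record '", id, "': partial location '", loc,
         "' is not supported", call. = FALSE)
  }
  if (grepl(":", loc, fixed = TRUE)) {
    stop("record '", id, "': remote location '", loc,
         "' is not supported", call. = FALSE)
  }
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    s <- .extract_location(inner, genome, id)
    return(.revcomp(s))
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- .split_toplevel(inner)
    return(paste0(vapply(parts, .extract_location, character(1),
                         genome = genome, id = id), collapse = ""))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
    if (ab[2L] < ab[1L] || ab[2L] > nchar(genome)) {
      stop("record '", id, "': location '", loc,
           "' outside sequence of length ", nchar(genome), call. = FALSE)
    }
    return(substr(genome, ab[1L], ab[2L]))
  }
  if (grepl("^[0-9]+$", loc)) {
    pos <- as.integer(loc)
    if (pos > nchar(genome)) {
      stop("record '", id, "': position ", pos, " outside sequence",
           call. = FALSE)
    }
    return(substr(genome, pos, pos))
  }
  stop("record '", id, "': unsupported location '", loc, "'", call. = FALSE)
}

# Split "a..b,join(c..d,e..f),g..h" at top-level commas only.
.split_toplevel <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  mapply(function(a, b) paste0(chars[a:b], collapse = ""), starts, ends)
}

.revcomp <- function(s) {
  chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# Split a GenBank flat file into records and pull out the pieces the CDS
# extractor needs: accession, CDS location strings, and the ORIGIN sequence.
.parse_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec_end <- grep("^//", lines)
  if (length(rec_end) == 0L) rec_end <- length(lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  records <- list()
  for (r in seq_along(rec_end)) {
    chunk <- lines[rec_start[r]:rec_end[r]]
    if (!any(grepl("^LOCUS", chunk))) next
    acc_line <- grep("^(ACCESSION|LOCUS)", chunk, value = TRUE)[1L]
    acc <- strsplit(trimws(acc_line), "\\s+")[[1L]][2L]

    origin_at <- grep("^ORIGIN", chunk)
    seq_txt <- ""
    if (length(origin_at)) {
      seq_lines <- chunk[(origin_at[1L] + 1L):length(chunk)]
      seq_lines <- seq_lines[!grepl("^//", seq_lines)]
      seq_txt <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    }

    feat_at <- grep("^FEATURES", chunk)
    cds_locs <- character(0)
    if (length(feat_at)) {
      feat_end <- if (length(origin_at)) origin_at[1L] - 1L else length(chunk)
      feats <- chunk[(feat_at[1L] + 1L):feat_end]
      is_key <- grepl("^ {5}\\S", feats)
      key_at <- which(is_key)
      keys <- sub("^ {5}(\\S+).*$", "\\1", feats[key_at])
      for (k in which(keys == "CDS")) {
        i <- key_at[k]
        loc <- sub("^ {5}\\S+\\s*", "", feats[i])
        j <- i + 1L
        # location may continue over lines until a qualifier or next key
        while (j <= length(feats) && !is_key[j] &&
               !grepl("^\\s*/", feats[j])) {
          loc <- paste0(loc, trimws(feats[j]))
          j <- j + 1L
        }
        cds_locs <- c(cds_locs, loc)
      }
    }
    records[[length(records) + 1L]] <-
      list(accession = acc, cds = cds_locs, sequence = seq_txt)
  }
  if (length(records) == 0L) {
    stop("no GenBank records found in ", path, call. = FALSE)
  }
  records
}

#' Read CDS features from a GenBank flat file
#'
#' Extracts every annotated CDS from each record, honoring the location
#' grammar (`join`, `complement`, nesting). With
#' `join_mode = "concatenate-all-cds"` (the default) all CDS of a record are
#' concatenated into a single coding sequence — each CDS contributing its own
#' reading frame, so genomic regions shared by overlapping genes are counted
#' once per gene that spans them. With `"per-cds"` each CDS feature becomes
#' its own record.
#'
#' @param path Path to a GenBank flat file with at least one CDS feature.
#' @param policy A [validation_policy()].
#' @param join_mode `"concatenate-all-cds"` or `"per-cds"`.
#' @return List of [coding_sequence()] objects.
#' @export
read_genbank_cds <- function(path, policy = validation_policy(),
                             join_mode = c("concatenate-all-cds", "per-cds")) {
  join_mode <- match.arg(join_mode)
  records <- .parse_genbank(path)
  out <- list()
  for (rec in records) {
    if (length(rec$cds) == 0L) {
      stop("record '", rec$accession, "': no CDS features", call. = FALSE)
    }
    if (nchar(rec$sequence) == 0L) {
      stop("record '", rec$accession, "': no ORIGIN sequence", call. = FALSE)
    }
    pieces <- vapply(rec$cds, .extract_location, character(1),
                     genome = rec$sequence, id = rec$accession)
    if (join_mode == "concatenate-all-cds") {
      out[[length(out) + 1L]] <- coding_sequence(
        rec$accession, paste0(pieces, collapse = ""), policy)
    } else {
      for (i in seq_along(pieces)) {
        out[[length(out) + 1L]] <- coding_sequence(
          paste0(rec$accession, ".CDS", i), pieces[i], policy)
      }
    }
  }
  out
}
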
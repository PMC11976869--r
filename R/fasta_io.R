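#' Read a protein FASTA file into a Proteome
#'
#' Parses a (possibly gzip-compressed) multi-record protein FASTA file.
#' Headers in the UniProt style `sp|ACC|NAME` or `tr|ACC|NAME` yield `ACC`
#' as the accession; any other header uses its first whitespace-delimited
#' token. Sequences are uppercased and a trailing stop character (`*`) is
#' stripped. The twenty standard amino-acid letters plus the tolerated
#' ambiguity/nonstandard letters X, U, B, Z and O are accepted; anything
#' else (whitespace, digits, internal `*`, other symbols) makes a record
#' invalid.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid What to do with an invalid record: `"error"` (default)
#'   stops naming the offending record; `"skip"` drops it and reports the
#'   number dropped via a message.
#' @return A [Proteome] object: a data frame with columns `accession`,
#'   `description` and `sequence`, one row per retained record, in file
#'   order, with the source path kept as an attribute.
#' @seealso [write_fasta()], [proteome()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|A demo", "MAKR", ">sp|P2|B", "GGG"), fa)
#' p <- read_fasta(fa)
#' p$accession
#' @export
read_fasta <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  seqs <- as.character(raw)

  accession <- vapply(headers, parse_fasta_accession, character(1),
                      USE.NAMES = FALSE)
  description <- vapply(headers, parse_fasta_description, character(1),
                        USE.NAMES = FALSE)

  keep <- rep(TRUE, length(seqs))
  clean <- character(length(seqs))
  for (i in seq_along(seqs)) {
    res <- try(sanitize_sequence(seqs[[i]]), silent = TRUE)
    if (inherits(res, "try-error")) {
      msg <- conditionMessage(attr(res, "condition"))
      if (on_invalid == "error") {
        stop("invalid record '", accession[i], "': ", msg, call. = FALSE)
      }
      keep[i] <- FALSE
    } else {
      clean[i] <- res
    }
  }
  if (any(!keep)) {
    message(sum(!keep), " invalid record(s) skipped")
  }
  accession <- accession[keep]
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    stop("duplicate accession(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  proteome(accession = accession,
           description = description[keep],
           sequence = clean[keep],
           source_path = path)
}

#' Write a Proteome to a FASTA file
#'
#' Records are written in order, wrapped at 60 columns. Headers are the
#' accession followed, when present, by a space and the description, so
#' that [read_fasta()] recovers accessions and sequences exactly.
#'
#' @param proteome A [Proteome].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is_proteome(proteome))
  x <- Biostrings::BStringSet(proteome$sequence)
  desc <- proteome$description
  names(x) <- ifelse(is.na(desc) | !nzchar(desc),
                     proteome$accession,
                     paste(proteome$accession, desc))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Construct a Proteome
#'
#' A `Proteome` is an ordered collection of protein records with pairwise
#' distinct accessions, held as a data frame with columns `accession`,
#' `description` and `sequence`.
#'
#' @param accession Character vector of unique identifiers.
#' @param description Character vector of free-text descriptions (recycled
#'   from `""` if missing).
#' @param sequence Character vector of amino-acid sequences; each is
#'   sanitized (uppercased, trailing `*` stripped, validated).
#' @param source_path Optional provenance string.
#' @return A `Proteome` data frame.
#' @export
proteome <- function(accession, sequence, description = "",
                     source_path = NA_character_) {
  accession <- as.character(accession)
  sequence <- vapply(as.character(sequence), sanitize_sequence,
                     character(1), USE.NAMES = FALSE)
  description <- rep_len(as.character(description), length(accession))
  if (length(sequence) != length(accession)) {
    stop("accession and sequence lengths differ", call. = FALSE)
  }
  if (anyDuplicated(accession)) {
    stop("accessions must be pairwise distinct", call. = FALSE)
  }
  out <- data.frame(accession = accession,
                    description = description,
                    sequence = sequence,
                    stringsAsFactors = FALSE)
  attr(out, "source_path") <- source_path
  class(out) <- c("Proteome", "data.frame")
  out
}

#' @rdname proteome
#' @param x Object to test or print.
#' @export
is_proteome <- function(x) inherits(x, "Proteome")

#' @export
print.Proteome <- function(x, ...) {
  cat("Proteome: ", nrow(x), " protein record(s)\n", sep = "")
  src <- attr(x, "source_path")
  if (!is.na(src)) cat("source: ", src, "\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(x, 5)
    for (i in seq_len(nrow(show))) {
      s <- show$sequence[i]
      cat(sprintf("  %-12s %5d aa  %s%s\n", show$accession[i], nchar(s),
                  substr(s, 1, 30), if (nchar(s) > 30) "..." else ""))
    }
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Sanitize an amino-acid sequence
#'
#' Uppercases, strips a trailing stop character (`*`), and validates that
#' only the 20 standard residues plus X, U, B, Z, O remain. Idempotent:
#' sanitizing a sanitized sequence is a no-op.
#'
#' @param seq A single character string.
#' @return The sanitized sequence.
#' @export
sanitize_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  s <- sub("\\*+$", "", s)
  if (!nzchar(s)) stop("sequence empty after sanitization", call. = FALSE)
  bad <- gsub(paste0("[", AA_ALLOWED, "]"), "", s)
  if (nzchar(bad)) {
    stop("illegal character(s) in sequence: ",
         paste(sQuote(unique(strsplit(bad, "")[[1]])), collapse = ", "),
         call. = FALSE)
  }
  s
}

# 20 standard residues plus tolerated nonstandard/ambiguity codes; kept as a
# regex character-class body.
AA_ALLOWED <- "ACDEFGHIKLMNPQRSTVWYXUBZO"

#' @rdname proteome
#' @export
n_records <- function(x) {
  stopifnot(is_proteome(x))
  nrow(x)
}

parse_fasta_accession <- function(header) {
  m <- regmatches(header, regexec("^(?:sp|tr)\\|([^| ]+)\\|", header))[[1]]
  if (length(m) == 2L) return(m[2])
  strsplit(trimws(header), "\\s+")[[1]][1]
}

parse_fasta_description <- function(header) {
  rest <- sub("^\\S+\\s*", "", trimws(header))
  rest
}
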
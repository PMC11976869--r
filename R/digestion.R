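#' Define a protease cleavage rule
#'
#' A cleavage rule is a protease specificity: the set of residues it
#' recognizes, whether it cuts C-terminal or N-terminal to a matched
#' residue, and optionally whether cleavage is suppressed when the
#' following residue is proline.
#'
#' @param residues Character vector (or single string) of one-letter
#'   residue codes; must be non-empty uppercase letters.
#' @param terminus `"C"` to cut after a matched residue, `"N"` to cut
#'   before it.
#' @param name Display name for the rule.
#' @param proline_block If `TRUE`, suppress a cut when the residue
#'   immediately following the cut position is `P`. Off by default: the
#'   in-silico specificities modelled here are bare residue rules.
#' @return A `CleavageRule` object.
#' @seealso [compile_rule()] for presets and the grammar string form.
#' @export
cleavage_rule <- function(residues, terminus = c("C", "N"), name = NULL,
                          proline_block = FALSE) {
  terminus <- match.arg(terminus)
  residues <- unique(toupper(unlist(strsplit(as.character(residues), ""))))
  residues <- residues[nzchar(residues)]
  if (length(residues) == 0L) {
    stop("cleavage rule needs a non-empty residue set", call. = FALSE)
  }
  if (!all(residues %in% LETTERS)) {
    stop("residues must be uppercase letters, got: ",
         paste(setdiff(residues, LETTERS), collapse = ", "), call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste0(paste(sort(residues), collapse = ""), "@", terminus,
                   if (proline_block) "/P" else "")
  }
  structure(list(name = name,
                 residues = sort(residues),
                 terminus = terminus,
                 proline_block = isTRUE(proline_block)),
            class = "CleavageRule")
}

#' @export
print.CleavageRule <- function(x, ...) {
  cat("CleavageRule '", x$name, "': {",
      paste(x$residues, collapse = ","), "} @ ", x$terminus,
      if (x$proline_block) " (proline block)" else "", "\n", sep = "")
  invisible(x)
}

# Preset specificities. 'gluc' is the conventional glutamate rule;
# 'gluc_paper' is the {F,Y,W,I} variant some published simulations print
# under the GluC label, shipped so either can be reproduced.
RULE_PRESETS <- list(
  trypsin    = list(residues = c("K", "R"), terminus = "C"),
  lysc       = list(residues = "K",         terminus = "C"),
  argc       = list(residues = "R",         terminus = "C"),
  gluc       = list(residues = "E",         terminus = "C"),
  gluc_paper = list(residues = c("F", "Y", "W", "I"), terminus = "C")
)

#' Compile a cleavage rule from a preset name or grammar string
#'
#' Accepts either a preset (`"trypsin"` = \{K,R\}@C, `"lysc"` = \{K\}@C,
#' `"argc"` = \{R\}@C, `"gluc"` = \{E\}@C, `"gluc_paper"` = \{F,Y,W,I\}@C)
#' or a grammar string `"<residues>@<C|N>[/P]"`, e.g. `"KR@C"` for trypsin
#' or `"K@N"` for an N-terminal lysine protease; the optional `/P` suffix
#' enables the proline block.
#'
#' @param spec Preset name or grammar string.
#' @return A [cleavage_rule()] object.
#' @examples
#' compile_rule("trypsin")
#' compile_rule("K@N")
#' @export
compile_rule <- function(spec) {
  if (inherits(spec, "CleavageRule")) return(spec)
  stopifnot(is.character(spec), length(spec) == 1L)
  key <- tolower(spec)
  if (key %in% names(RULE_PRESETS)) {
    p <- RULE_PRESETS[[key]]
    return(cleavage_rule(p$residues, p$terminus, name = key))
  }
  m <- regmatches(spec, regexec("^([A-Za-z]*)@([CNcn])(/[Pp])?$", spec))[[1]]
  if (length(m) == 0L) {
    stop("unknown preset or malformed rule spec: '", spec,
         "' (expected a preset name or \"<residues>@<C|N>[/P]\")",
         call. = FALSE)
  }
  if (!nzchar(m[2])) {
    stop("empty residue set in rule spec '", spec, "'", call. = FALSE)
  }
  cleavage_rule(m[2], toupper(m[3]), name = spec,
                proline_block = nzchar(m[4]))
}

#' Digestion criteria: missed-cleavage cap and peptide length window
#'
#' Defaults follow the in-silico digestion criteria used throughout the
#' package: at most 2 missed cleavages and peptide lengths between 6 and
#' 60 residues. A common search-engine style alternative is
#' `digest_config(2, 7, 30)`.
#'
#' @param max_missed Maximum number of internal uncleaved sites (>= 0).
#' @param min_len,max_len Inclusive peptide length window.
#' @return A `DigestConfig` object.
#' @export
digest_config <- function(max_missed = 2L, min_len = 6L, max_len = 60L) {
  max_missed <- as.integer(max_missed)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  if (is.na(min_len) || min_len < 1L) {
    stop("min_len must be a positive integer", call. = FALSE)
  }
  if (is.na(max_len) || max_len < min_len) {
    stop("max_len must be >= min_len", call. = FALSE)
  }
  structure(list(max_missed = max_missed, min_len = min_len,
                 max_len = max_len),
            class = "DigestConfig")
}

#' @export
print.DigestConfig <- function(x, ...) {
  cat("DigestConfig: <=", x$max_missed, "missed cleavages, lengths",
      x$min_len, "-", x$max_len, "\n")
  invisible(x)
}

#' Locate cleavage sites in a sequence
#'
#' Returns the cut positions as 0-based inter-residue offsets: a cut at
#' offset `i` falls between residues `i` and `i + 1`. For a C-terminal
#' rule a matched final residue produces no cut (it coincides with the
#' protein terminus); for an N-terminal rule a matched first residue
#' likewise produces none. Nonstandard residues (X, U, B, Z, O) never
#' match unless explicitly listed in the rule.
#'
#' @param sequence Sanitized amino-acid string.
#' @param rule A [cleavage_rule()].
#' @return Strictly increasing integer vector of offsets in
#'   `1 .. nchar(sequence) - 1`; empty when nothing matches.
#' @examples
#' find_sites("MAKRTT", compile_rule("trypsin"))  # 3, 4
#' @export
find_sites <- function(sequence, rule) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(rule, "CleavageRule"))
  n <- nchar(sequence)
  if (n < 2L) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- which(chars %in% rule$residues)
  if (rule$terminus == "C") {
    cuts <- idx[idx < n]
    if (rule$proline_block && length(cuts)) {
      cuts <- cuts[chars[cuts + 1L] != "P"]
    }
  } else {
    pos <- idx[idx > 1L]
    if (rule$proline_block && length(pos)) {
      pos <- pos[chars[pos] != "P"]
    }
    cuts <- pos - 1L
  }
  sort(unique(as.integer(cuts)))
}

#' Digest a protein into fully specific peptides
#'
#' Enumerates every fully specific peptide — both boundaries at cleavage
#' sites or protein termini — with at most `config$max_missed` internal
#' uncleaved sites and length within the configured window. Peptides are
#' positional occurrences: identical sequences at different coordinates
#' are distinct rows. No semi-specific or non-specific products and no
#' modifications are considered.
#'
#' @param protein A sequence string, a one-row [Proteome], or a list with
#'   `accession` and `sequence` elements.
#' @param rule A [cleavage_rule()] or spec accepted by [compile_rule()].
#' @param config A [digest_config()].
#' @param accession Accession to report when `protein` is a bare string.
#' @return A data frame with columns `protein`, `start`, `end`, `length`,
#'   `missed`, `sequence`; coordinates 1-based inclusive; rows ordered by
#'   `(start, end)`.
#' @examples
#' digest("MAKRTT", "trypsin", digest_config(2, 1, 60))
#' @export
digest <- function(protein, rule, config = digest_config(),
                   accession = "protein1") {
  if (is_proteome(protein)) {
    stopifnot(nrow(protein) == 1L)
    accession <- protein$accession
    sequence <- protein$sequence
  } else if (is.list(protein)) {
    accession <- protein$accession
    sequence <- protein$sequence
  } else {
    sequence <- protein
  }
  rule <- compile_rule(rule)
  stopifnot(inherits(config, "DigestConfig"))
  sites <- find_sites(sequence, rule)
  pep <- enumerate_peptides(nchar(sequence), sites, config)
  if (nrow(pep) == 0L) {
    return(data.frame(protein = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      missed = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(protein = rep(accession, nrow(pep)),
             start = pep$start,
             end = pep$end,
             length = pep$end - pep$start + 1L,
             missed = pep$missed,
             sequence = substring(sequence, pep$start, pep$end),
             stringsAsFactors = FALSE)
}

# Enumerate (start, end, missed) triples for a sequence of length n with
# internal cut offsets `sites`, under `config`. Fragment boundaries are
# c(0, sites, n); a peptide spanning fragments i..j has j - i internal
# missed sites.
enumerate_peptides <- function(n, sites, config) {
  bounds <- c(0L, sites, n)
  m <- length(bounds) - 1L  # number of zero-missed fragments
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (k in 0:min(config$max_missed, m - 1L)) {
    i <- seq_len(m - k)
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + 1L + k])
    missed <- c(missed, rep(k, m - k))
  }
  len <- ends - starts + 1L
  keep <- len >= config$min_len & len <= config$max_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    missed = missed[keep])
  out[order(out$start, out$end), , drop = FALSE]
}

#' Analytic count of unfiltered fully specific peptides
#'
#' For a protein with `s` internal cleavage sites and a missed-cleavage
#' cap `k`, the number of fully specific peptides before any length
#' filtering is `sum_{j=0}^{min(k, s)} (s + 1 - j)`. Serves as a
#' closed-form check on [digest()].
#'
#' @param n_internal_sites Integer vector `s >= 0`.
#' @param max_missed Integer vector `k >= 0`.
#' @return Integer vector of counts.
#' @examples
#' count_unfiltered(3, 2)  # 4 + 3 + 2 = 9
#' @export
count_unfiltered <- function(n_internal_sites, max_missed) {
  s <- as.integer(n_internal_sites)
  k <- as.integer(max_missed)
  if (any(is.na(s)) || any(is.na(k)) || any(s < 0L) || any(k < 0L)) {
    stop("n_internal_sites and max_missed must be non-negative",
         call. = FALSE)
  }
  mapply(function(si, ki) {
    j <- 0:min(ki, si)
    sum(si + 1L - j)
  }, s, k)
}

#' Write a peptide table as TSV
#'
#' @param peptides Data frame from [digest()] (or row-bound digests).
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path, comments = NULL) {
  write_tsv_commented(peptides, path, comments)
}
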
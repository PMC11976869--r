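#' Digest an entire proteome and summarize peptide yield
#'
#' Applies [digest()] to every record and aggregates: peptide occurrence
#' counts per protein (zeros kept for uncovered proteins), the
#' proteome-wide occurrence total, the number of distinct peptide
#' sequences, and protein-level coverage (proteins yielding at least one
#' passing peptide). Deterministic for fixed inputs.
#'
#' @param proteome A [proteome()].
#' @param rule A [cleavage_rule()] or spec accepted by [compile_rule()].
#' @param config A [digest_config()].
#' @return A `DigestSummary`: list with `rule_name`, `per_protein` (named
#'   integer vector over all accessions), `total_peptides`,
#'   `distinct_sequences`, `n_proteins_covered`, `n_proteins_total`.
#' @export
digest_proteome <- function(proteome, rule, config = digest_config()) {
  stopifnot(is_proteome(proteome))
  if (nrow(proteome) == 0L) stop("empty proteome", call. = FALSE)
  rule <- compile_rule(rule)
  counts <- integer(nrow(proteome))
  seq_pool <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    pep <- digest(proteome$sequence[i], rule, config,
                  accession = proteome$accession[i])
    counts[i] <- nrow(pep)
    seq_pool[[i]] <- pep$sequence
  }
  names(counts) <- proteome$accession
  structure(list(rule_name = rule$name,
                 per_protein = counts,
                 total_peptides = sum(counts),
                 distinct_sequences = length(unique(unlist(seq_pool))),
                 n_proteins_covered = sum(counts > 0L),
                 n_proteins_total = nrow(proteome)),
            class = "DigestSummary")
}

#' @export
print.DigestSummary <- function(x, ...) {
  cat("DigestSummary [", x$rule_name, "]\n", sep = "")
  cat("  peptide occurrences: ", x$total_peptides,
      " (", x$distinct_sequences, " distinct sequences)\n", sep = "")
  cat("  proteins covered:    ", x$n_proteins_covered, "/",
      x$n_proteins_total,
      sprintf(" (%.1f%%)\n", coverage_pct(x)), sep = "")
  invisible(x)
}

#' Protein-level proteome coverage
#'
#' Percentage of database proteins yielding at least one peptide passing
#' the digestion criteria. This is protein-level presence, not
#' residue-level sequence coverage.
#'
#' @param summary A `DigestSummary` from [digest_proteome()].
#' @return Percentage in `[0, 100]`.
#' @export
coverage_pct <- function(summary) {
  stopifnot(inherits(summary, "DigestSummary"))
  if (summary$n_proteins_total == 0L) stop("empty summary", call. = FALSE)
  100 * summary$n_proteins_covered / summary$n_proteins_total
}

#' Complexity of one digest relative to a reference protease
#'
#' Computes the total-peptide ratio and the ratio of median peptides per
#' protein against a reference digest of the same proteome (conventionally
#' trypsin). Medians are taken over all proteins in the database, zeros
#' included; the per-protein vectors are available in the summaries if the
#' zero-excluding convention is wanted instead.
#'
#' @param summary,reference `DigestSummary` objects over the same protein
#'   universe.
#' @return A one-row data frame: `rule`, `reference`, `total_peptides`,
#'   `distinct_sequences`, `peptide_ratio`, `median_per_protein_ratio`,
#'   `coverage_pct`.
#' @export
relative_complexity <- function(summary, reference) {
  stopifnot(inherits(summary, "DigestSummary"),
            inherits(reference, "DigestSummary"))
  if (!identical(sort(names(summary$per_protein)),
                 sort(names(reference$per_protein)))) {
    stop("summaries cover different protein universes", call. = FALSE)
  }
  if (reference$total_peptides == 0L) {
    stop("reference digest produced no peptides", call. = FALSE)
  }
  ref_med <- stats::median(reference$per_protein)
  med <- stats::median(summary$per_protein)
  med_ratio <- if (ref_med == 0) {
    warning("reference median peptides per protein is 0; ratio is NA")
    NA_real_
  } else {
    med / ref_med
  }
  data.frame(rule = summary$rule_name,
             reference = reference$rule_name,
             total_peptides = summary$total_peptides,
             distinct_sequences = summary$distinct_sequences,
             peptide_ratio = summary$total_peptides / reference$total_peptides,
             median_per_protein_ratio = med_ratio,
             coverage_pct = coverage_pct(summary),
             stringsAsFactors = FALSE)
}

#' Scan single-residue protease specificities across a proteome
#'
#' Digests the proteome with every single-residue rule (20 standard
#' residues crossed with C- and N-terminal cleavage) plus the named
#' presets, and reports each relative to a reference rule. Rows are
#' sorted by increasing peptide ratio; the reference row has ratio 1.
#'
#' @param proteome A [proteome()].
#' @param config A [digest_config()].
#' @param reference Rule (or spec) everything is normalized to.
#' @param termini Which cleavage termini to scan.
#' @param include_presets Also include the named presets.
#' @return Data frame of [relative_complexity()] rows.
#' @export
residue_scan <- function(proteome, config = digest_config(),
                         reference = "trypsin", termini = c("C", "N"),
                         include_presets = TRUE) {
  stopifnot(is_proteome(proteome))
  if (nrow(proteome) == 0L) stop("empty proteome", call. = FALSE)
  termini <- match.arg(termini, several.ok = TRUE)
  reference <- compile_rule(reference)
  ref_sum <- digest_proteome(proteome, reference, config)

  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rules <- list()
  for (t in termini) {
    for (a in aa20) {
      rules[[paste0(a, "@", t)]] <- cleavage_rule(a, t)
    }
  }
  if (include_presets) {
    for (p in names(RULE_PRESETS)) rules[[p]] <- compile_rule(p)
  }
  rules[[reference$name]] <- reference

  rows <- lapply(rules, function(r) {
    s <- if (identical(r$name, reference$name)) ref_sum
         else digest_proteome(proteome, r, config)
    relative_complexity(s, ref_sum)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$peptide_ratio, out$rule), , drop = FALSE]
}
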
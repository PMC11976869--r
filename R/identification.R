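#' Validate or construct an identification table
#'
#' A long-format stand-in for a search-engine export: one row per
#' (protein, peptide, condition, replicate) with a positive abundance
#' (`NA` allowed, meaning identified but not quantified) and a q-value in
#' `[0, 1]`.
#'
#' @param x A data frame with columns `protein`, `peptide`, `condition`,
#'   `replicate`, `abundance`, `q_value`.
#' @return The validated data frame (classed `IdentificationTable`).
#' @export
identification_table <- function(x) {
  req <- c("protein", "peptide", "condition", "replicate",
           "abundance", "q_value")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[req]
  x$replicate <- as.integer(x$replicate)
  if (any(!is.na(x$abundance) & x$abundance <= 0)) {
    stop("abundances must be positive where present", call. = FALSE)
  }
  if (any(is.na(x$q_value)) || any(x$q_value < 0 | x$q_value > 1)) {
    stop("q_value must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(x$protein, x$peptide, x$condition, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(protein, peptide, condition, replicate) rows must be unique",
         call. = FALSE)
  }
  class(x) <- c("IdentificationTable", "data.frame")
  x
}

#' Read an identification table from TSV/CSV
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated. Leading `#` comment lines are skipped.
#' @param col_map Optional named character vector mapping required column
#'   names to the names used in the file, e.g.
#'   `c(protein = "Protein.Group", q_value = "qval")`.
#' @return An [identification_table()].
#' @export
read_identifications <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df)) {
        stop("mapped column not in file: ", col_map[[std]], call. = FALSE)
      }
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  identification_table(df)
}

#' @rdname read_identifications
#' @param table An [identification_table()].
#' @param comments Optional `#` comment lines to prepend.
#' @export
write_identifications <- function(table, path, comments = NULL) {
  write_tsv_commented(table, path, comments)
}

#' Filter identifications to high confidence
#'
#' Retains rows with `q_value` strictly below the threshold (the
#' conventional "high confidence" cut is q < 0.01).
#'
#' @param table An [identification_table()].
#' @param q_threshold Threshold in `(0, 1]`.
#' @return The filtered table; retained/total counts are reported via a
#'   message.
#' @export
filter_confident <- function(table, q_threshold = 0.01) {
  table <- identification_table(table)
  if (!is.numeric(q_threshold) || length(q_threshold) != 1L ||
      q_threshold <= 0 || q_threshold > 1) {
    stop("q_threshold must lie in (0, 1]", call. = FALSE)
  }
  keep <- table$q_value < q_threshold
  message("filter_confident: ", sum(keep), "/", nrow(table),
          " rows at q < ", q_threshold)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("IdentificationTable", "data.frame")
  out
}

#' Per-replicate and per-condition identification counts
#'
#' Counts distinct proteins and distinct peptides per replicate, then the
#' replicate mean and standard deviation per condition.
#'
#' @param table An [identification_table()] (typically already filtered
#'   with [filter_confident()]).
#' @return List with `per_replicate` and `per_condition` data frames.
#' @export
summarize_counts <- function(table) {
  table <- identification_table(table)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  key <- interaction(table$condition, table$replicate, drop = TRUE)
  per_rep <- do.call(rbind, lapply(split(table, key), function(d) {
    data.frame(condition = d$condition[1],
               replicate = d$replicate[1],
               n_proteins = length(unique(d$protein)),
               n_peptides = length(unique(paste(d$protein, d$peptide))),
               stringsAsFactors = FALSE)
  }))
  per_rep <- per_rep[order(per_rep$condition, per_rep$replicate), ]
  rownames(per_rep) <- NULL
  per_cond <- do.call(rbind, lapply(split(per_rep, per_rep$condition),
                                    function(d) {
    data.frame(condition = d$condition[1],
               n_replicates = nrow(d),
               mean_proteins = mean(d$n_proteins),
               sd_proteins = stats::sd(d$n_proteins),
               mean_peptides = mean(d$n_peptides),
               sd_peptides = stats::sd(d$n_peptides),
               stringsAsFactors = FALSE)
  }))
  rownames(per_cond) <- NULL
  list(per_replicate = per_rep, per_condition = per_cond)
}

#' Replicate coefficients of variation
#'
#' For one condition, computes for each entity quantified in at least
#' `min_replicates` replicates the percent CV, `100 * sd / mean`, over
#' raw abundances (sample standard deviation, n - 1 denominator). At
#' `level = "protein"` the per-replicate abundance of a protein is the
#' sum of its peptide abundances; at `level = "peptide"` each
#' (protein, peptide) pair is an entity. `log_scale = TRUE` computes the
#' CV on log10 abundances instead of raw values.
#'
#' @param table An [identification_table()].
#' @param condition Condition label to analyse.
#' @param min_replicates Minimum replicates with a non-missing abundance.
#' @param level `"protein"` or `"peptide"`.
#' @param log_scale Compute the CV on log10-transformed abundances.
#' @return Data frame with columns `protein` (and `peptide` at peptide
#'   level), `n_quantified`, `cv_pct`. Entities below `min_replicates`
#'   are omitted and their count reported via a message.
#' @export
cv_per_protein <- function(table, condition, min_replicates = 2L,
                           level = c("protein", "peptide"),
                           log_scale = FALSE) {
  table <- identification_table(table)
  level <- match.arg(level)
  d <- table[table$condition == condition & !is.na(table$abundance), ,
             drop = FALSE]
  if (nrow(d) == 0L) {
    message("cv_per_protein: no quantified rows in condition '",
            condition, "'")
    return(data.frame(protein = character(0), n_quantified = integer(0),
                      cv_pct = numeric(0)))
  }
  if (level == "protein") {
    agg <- stats::aggregate(abundance ~ protein + replicate, data = d, sum)
    ent <- agg$protein
  } else {
    agg <- stats::aggregate(abundance ~ protein + peptide + replicate,
                            data = d, sum)
    ent <- paste(agg$protein, agg$peptide, sep = "\r")
  }
  if (log_scale) agg$abundance <- log10(agg$abundance)
  groups <- split(agg$abundance, ent)
  n_q <- lengths(groups)
  keep <- n_q >= min_replicates
  if (any(!keep)) {
    message("cv_per_protein: ", sum(!keep), " entit(ies) below ",
            min_replicates, " quantified replicates omitted")
  }
  cv <- vapply(groups[keep], function(v) 100 * stats::sd(v) / mean(v),
               numeric(1))
  ids <- names(groups)[keep]
  out <- if (level == "protein") {
    data.frame(protein = ids, n_quantified = unname(n_q[keep]),
               cv_pct = unname(cv), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(ids, "\r", fixed = TRUE)
    data.frame(protein = vapply(parts, `[`, "", 1),
               peptide = vapply(parts, `[`, "", 2),
               n_quantified = unname(n_q[keep]),
               cv_pct = unname(cv), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$protein), , drop = FALSE]
}

#' Proportion of identified entities quantified in every replicate
#'
#' "Quantified" means a non-missing abundance in every replicate of the
#' condition (the replicate universe is the set of replicate labels seen
#' in that condition). The default entity is the peptide.
#'
#' @inheritParams cv_per_protein
#' @return Fraction in `[0, 1]`.
#' @export
proportion_quantified <- function(table, condition,
                                  level = c("peptide", "protein")) {
  table <- identification_table(table)
  level <- match.arg(level)
  d <- table[table$condition == condition, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows in condition '", condition, "'",
                          call. = FALSE)
  reps <- unique(d$replicate)
  ent <- if (level == "peptide") paste(d$protein, d$peptide, sep = "\r")
         else d$protein
  ok <- !is.na(d$abundance)
  complete <- vapply(split(data.frame(rep = d$replicate, ok = ok), ent),
                     function(g) {
                       quant <- unique(g$rep[g$ok])
                       length(setdiff(reps, quant)) == 0L
                     }, logical(1))
  mean(complete)
}

#' Quantitative rank-abundance table
#'
#' Proteins ordered by decreasing mean abundance across the replicates of
#' a condition (per-replicate protein abundance is the sum of its peptide
#' abundances; the mean is over replicates where the protein was
#' quantified). Rank 1 is the most abundant; ties break by accession so
#' output is deterministic.
#'
#' @inheritParams cv_per_protein
#' @return Data frame `protein`, `mean_abundance`, `rank`.
#' @export
rank_abundance <- function(table, condition) {
  table <- identification_table(table)
  d <- table[table$condition == condition & !is.na(table$abundance), ,
             drop = FALSE]
  if (nrow(d) == 0L) stop("no quantified rows in condition '", condition,
                          "'", call. = FALSE)
  agg <- stats::aggregate(abundance ~ protein + replicate, data = d, sum)
  mean_ab <- tapply(agg$abundance, agg$protein, mean)
  out <- data.frame(protein = names(mean_ab),
                    mean_abundance = as.numeric(mean_ab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abundance, out$protein), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Exclusive intersection counts over condition protein sets
#'
#' For every non-empty combination of conditions, counts the elements
#' belonging to exactly that combination (the quantities behind an UpSet
#' plot). Counts over all signatures sum to the size of the union.
#'
#' @param protein_sets Named list (>= 2 elements) of character vectors.
#' @return Named integer vector; names are condition names joined by
#'   `"&"`, in the order given, including zero-count combinations.
#' @examples
#' exclusive_intersections(list(X = c("a", "b"), Y = c("b", "c")))
#' @export
exclusive_intersections <- function(protein_sets) {
  if (!is.list(protein_sets) || length(protein_sets) < 2L ||
      is.null(names(protein_sets)) || any(!nzchar(names(protein_sets)))) {
    stop("protein_sets must be a named list of at least 2 sets",
         call. = FALSE)
  }
  sets <- lapply(protein_sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  sig <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(nm), function(k) {
    apply(utils::combn(nm, k), 2L, paste, collapse = "&")
  }))
  counts <- table(factor(sig, levels = combos))
  out <- as.integer(counts)
  names(out) <- combos
  out
}

#' Kolmogorov–Smirnov test of rank uniformity
#'
#' Tests whether a set of ranks (for example the ranks of proteins unique
#' to one condition, within that condition's full rank-abundance table)
#' is uniformly spread over `1..n_total`. Ranks are mapped to mid-rank
#' fractions `(rank - 0.5) / n_total` and compared with Uniform(0, 1) by
#' a one-sample KS test; the p-value uses the exact small-sample
#' computation when `n <= 10` (default) and the asymptotic Kolmogorov
#' distribution otherwise.
#'
#' @param unique_ranks Integer ranks in `[1, n_total]`.
#' @param n_total Size of the full rank table.
#' @param exact Logical; force exact/asymptotic p. Default `NULL` means
#'   exact when `length(unique_ranks) <= 10`.
#' @return An object of class `htest` with the D statistic and p-value.
#' @export
ks_rank_uniformity <- function(unique_ranks, n_total, exact = NULL) {
  r <- as.numeric(unique_ranks)
  if (length(r) == 0L) stop("empty rank list", call. = FALSE)
  if (n_total < 1 || any(r < 1 | r > n_total)) {
    stop("ranks must lie in [1, n_total]", call. = FALSE)
  }
  if (is.null(exact)) exact <- length(r) <= 10L
  u <- (r - 0.5) / n_total
  res <- suppressWarnings(stats::ks.test(u, "punif", exact = exact))
  res$method <- "One-sample KS test of rank uniformity (mid-rank fractions vs U(0,1))"
  res$data.name <- deparse(substitute(unique_ranks))
  res
}

#' Two-sample Kolmogorov–Smirnov test
#'
#' Classical two-sample KS test (asymptotic p unless `exact` is set),
#' e.g. for comparing abundances of proteins unique to a condition with
#' the full abundance distribution.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact Passed to [stats::ks.test()].
#' @return An `htest` with the D statistic and p-value.
#' @export
two_sample_ks <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input", call. = FALSE)
  suppressWarnings(stats::ks.test(a, b, exact = exact))
}

#' Wilcoxon rank-sum (Mann–Whitney) test
#'
#' Two-sided rank-sum test with average ranks on ties. By default the
#' p-value is computed by exact enumeration when both samples have at
#' most 10 observations and there are no ties; otherwise the normal
#' approximation with continuity and tie correction is used (this is
#' also the path taken for tied data, including identical multisets,
#' where the test returns p = 1 by symmetry).
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact Logical; default `NULL` means exact when both `n <= 10`.
#' @return An `htest`; `statistic` is the Mann–Whitney U for sample `a`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1 exactly
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input", call. = FALSE)
  if (is.null(exact)) exact <- length(a) <= 10L && length(b) <= 10L
  suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
}

#' Welch two-sample t test
#'
#' Two-sided unequal-variance t test with Welch–Satterthwaite degrees of
#' freedom.
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @return An `htest` with the t statistic and p-value.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      stop("both samples are constant and equal; t is undefined (0/0)",
           call. = FALSE)
    }
    stop("zero variance in both samples", call. = FALSE)
  }
  stats::t.test(a, b, var.equal = FALSE)
}
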
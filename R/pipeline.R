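#' Digest a FASTA file to a peptide table (pipeline command)
#'
#' Reads a protein FASTA, digests every record, and writes the peptide
#' occurrence table as TSV with a parameter-echo comment block.
#'
#' @param fasta Path to a protein FASTA file.
#' @param enzyme Preset name or rule grammar string (see
#'   [compile_rule()]).
#' @param max_missed,min_len,max_len Digestion criteria (see
#'   [digest_config()]).
#' @param out Output TSV path.
#' @return Invisibly, the peptide data frame; totals are reported via a
#'   message.
#' @export
cmd_digest <- function(fasta, enzyme = "trypsin", max_missed = 2,
                       min_len = 6, max_len = 60, out) {
  proteome <- read_fasta(fasta)
  rule <- compile_rule(enzyme)
  config <- digest_config(max_missed, min_len, max_len)
  peps <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    digest(proteome$sequence[i], rule, config,
           accession = proteome$accession[i])
  }))
  write_peptides(peps, out,
                 comments = echo_params(command = "digest", fasta = fasta,
                                        enzyme = rule$name,
                                        max_missed = config$max_missed,
                                        min_len = config$min_len,
                                        max_len = config$max_len))
  message("cmd_digest: ", nrow(peps), " peptides from ", nrow(proteome),
          " proteins -> ", out)
  invisible(peps)
}

#' Proteome complexity profile across enzymes (pipeline command)
#'
#' Digests a proteome with each requested enzyme (optionally also the
#' full single-residue scan) and writes a summary table of totals,
#' coverage and ratios relative to the reference, plus a JSON report
#' echoing the configuration.
#'
#' @inheritParams cmd_digest
#' @param enzymes Character vector of presets/grammar strings.
#' @param scan_residues Also run the 20-residue x \{C,N\} scan.
#' @param reference Rule everything is normalized to.
#' @param out_prefix Output prefix; writes `<prefix>_summary.tsv` and
#'   `<prefix>_report.json`.
#' @return Invisibly, the summary data frame.
#' @export
cmd_profile <- function(fasta, enzymes = c("trypsin", "lysc", "argc",
                                           "gluc"),
                        scan_residues = FALSE, reference = "trypsin",
                        max_missed = 2, min_len = 6, max_len = 60,
                        out_prefix) {
  proteome <- read_fasta(fasta)
  config <- digest_config(max_missed, min_len, max_len)
  ref_rule <- compile_rule(reference)
  ref_sum <- digest_proteome(proteome, ref_rule, config)

  rows <- lapply(enzymes, function(e) {
    r <- compile_rule(e)
    s <- if (identical(r$name, ref_rule$name)) ref_sum
         else digest_proteome(proteome, r, config)
    relative_complexity(s, ref_sum)
  })
  summary_df <- do.call(rbind, rows)
  if (scan_residues) {
    scan <- residue_scan(proteome, config, reference = ref_rule)
    summary_df <- unique(rbind(summary_df, scan))
  }
  rownames(summary_df) <- NULL

  tsv <- paste0(out_prefix, "_summary.tsv")
  write_tsv_commented(summary_df, tsv,
                      comments = echo_params(command = "profile",
                                             fasta = fasta,
                                             reference = ref_rule$name,
                                             max_missed = config$max_missed,
                                             min_len = config$min_len,
                                             max_len = config$max_len))
  report <- list(command = "profile", fasta = fasta,
                 n_proteins = nrow(proteome),
                 reference = ref_rule$name,
                 config = unclass(config),
                 summary = summary_df)
  jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary_df)
}

#' Generate a synthetic proteome and identification table (pipeline command)
#'
#' Runs the synthetic-data generator end to end: proteome FASTA, protein
#' abundances, a simulated identification table, and a manifest JSON
#' capturing every model parameter and seed so the run can be reproduced
#' exactly.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param enzyme Digestion rule for the simulated experiment.
#' @param conditions Condition labels.
#' @param max_missed,min_len,max_len Digestion criteria.
#' @param n_replicates,replicate_cv,q_above_fraction Observation-model
#'   parameters (see [observation_model()]).
#' @param dynamic_range_orders Abundance dynamic range (orders of
#'   magnitude).
#' @param seed Master seed; sub-seeds for the proteome, abundance and
#'   observation models are derived from it.
#' @param out_dir Output directory (created if needed).
#' @param config_file Optional YAML/JSON file whose entries provide any
#'   of the above parameters; explicit arguments override the file.
#' @return Invisibly, a list with the proteome, abundances, table and
#'   the manifest.
#' @export
cmd_simulate <- function(n_proteins = 500, enzyme = "trypsin",
                         conditions = "cond1", max_missed = 2,
                         min_len = 6, max_len = 60, n_replicates = 3,
                         replicate_cv = 0.15, q_above_fraction = 0.05,
                         dynamic_range_orders = 6, seed = 1,
                         out_dir, config_file = NULL) {
  if (!is.null(config_file)) {
    cfg <- read_run_config(config_file)
    call_args <- as.list(match.call())[-1]
    for (nm in names(cfg)) {
      if (!nm %in% names(call_args) && nm != "out_dir") {
        assign(nm, cfg[[nm]])
      }
    }
  }
  if (n_proteins < 1) stop("n_proteins must be positive", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  pm <- proteome_model(n_proteins, seed = seed)
  am <- abundance_model(dynamic_range_orders = dynamic_range_orders,
                        seed = seed + 1L)
  om <- observation_model(n_replicates = n_replicates,
                          replicate_cv = replicate_cv,
                          q_above_fraction = q_above_fraction,
                          seed = seed + 2L)
  proteome <- generate_proteome(pm)
  ab <- assign_abundances(proteome, am)
  tab <- simulate_identifications(proteome, ab, compile_rule(enzyme),
                                  digest_config(max_missed, min_len,
                                                max_len),
                                  om, conditions = conditions)

  fasta_path <- file.path(out_dir, "proteome_synthetic.fasta")
  ids_path <- file.path(out_dir, "identifications_synthetic.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_fasta(proteome, fasta_path)
  write_identifications(tab, ids_path,
                        comments = c("synthetic identification table",
                                     paste0("seed=", seed)))
  manifest <- list(command = "simulate",
                   note = "synthetic data; DDA detection curve is a logistic stand-in",
                   proteome_model = unclass(pm),
                   abundance_model = unclass(am),
                   observation_model = unclass(om),
                   enzyme = compile_rule(enzyme)$name,
                   digest_config = unclass(digest_config(max_missed,
                                                         min_len, max_len)),
                   conditions = conditions,
                   master_seed = seed,
                   files = list(fasta = basename(fasta_path),
                                identifications = basename(ids_path)),
                   n_rows = nrow(tab))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  message("cmd_simulate: ", nrow(tab), " rows -> ", out_dir)
  invisible(list(proteome = proteome, abundances = ab, table = tab,
                 manifest = manifest))
}

#' Compare identification results across conditions (pipeline command)
#'
#' Filters an identification table at a q-value threshold and writes the
#' comparison report: per-condition counts, CV distributions,
#' rank-abundance tables, exclusive protein-set intersections, and the
#' requested hypothesis tests (pairwise Wilcoxon on protein mean
#' abundances, rank-uniformity KS for proteins unique to each condition,
#' pairwise Welch t on per-replicate protein counts).
#'
#' @param ids Path to a TSV/CSV identification table, or an
#'   [identification_table()].
#' @param q_threshold Confidence threshold for [filter_confident()].
#' @param tests Subset of `c("wilcoxon", "ks_uniformity", "welch_t")`.
#' @param out_prefix Output prefix for the report files.
#' @return Invisibly, a list with all report components.
#' @export
cmd_compare <- function(ids, q_threshold = 0.01,
                        tests = c("wilcoxon", "ks_uniformity", "welch_t"),
                        out_prefix) {
  tests <- match.arg(tests, several.ok = TRUE)
  tab <- if (is.character(ids)) read_identifications(ids)
         else identification_table(ids)
  tab <- filter_confident(tab, q_threshold)
  if (nrow(tab) == 0L) stop("no rows pass the q-value filter",
                            call. = FALSE)
  conds <- sort(unique(tab$condition))
  if (length(conds) < 2L && length(tests)) {
    stop("hypothesis tests need at least 2 conditions", call. = FALSE)
  }

  counts <- summarize_counts(tab)
  cvs <- lapply(conds, function(cn) cv_per_protein(tab, cn))
  names(cvs) <- conds
  ranks <- lapply(conds, function(cn) rank_abundance(tab, cn))
  names(ranks) <- conds
  prop_q <- vapply(conds, function(cn) proportion_quantified(tab, cn),
                   numeric(1))
  sets <- lapply(conds, function(cn) unique(tab$protein[tab$condition == cn]))
  names(sets) <- conds
  inter <- exclusive_intersections(sets)

  test_rows <- list()
  if ("wilcoxon" %in% tests) {
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i < j) {
        w <- wilcoxon_rank_sum(ranks[[i]]$mean_abundance,
                               ranks[[j]]$mean_abundance)
        test_rows[[length(test_rows) + 1L]] <-
          data.frame(test = "wilcoxon_rank_sum",
                     comparison = paste(conds[i], "vs", conds[j]),
                     statistic = unname(w$statistic),
                     p_value = w$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  if ("ks_uniformity" %in% tests) {
    for (cn in conds) {
      others <- unlist(sets[setdiff(conds, cn)])
      uniq <- setdiff(sets[[cn]], others)
      rk <- ranks[[cn]]
      ur <- rk$rank[rk$protein %in% uniq]
      if (length(ur) > 0L) {
        k <- ks_rank_uniformity(ur, nrow(rk))
        test_rows[[length(test_rows) + 1L]] <-
          data.frame(test = "ks_rank_uniformity",
                     comparison = paste0("unique to ", cn),
                     statistic = unname(k$statistic),
                     p_value = k$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  if ("welch_t" %in% tests) {
    pr <- counts$per_replicate
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i < j) {
        a <- pr$n_proteins[pr$condition == conds[i]]
        b <- pr$n_proteins[pr$condition == conds[j]]
        if (length(a) >= 2L && length(b) >= 2L &&
            (stats::var(a) > 0 || stats::var(b) > 0)) {
          tt <- two_sample_t(a, b)
          test_rows[[length(test_rows) + 1L]] <-
            data.frame(test = "welch_t_protein_counts",
                       comparison = paste(conds[i], "vs", conds[j]),
                       statistic = unname(tt$statistic),
                       p_value = tt$p.value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  test_df <- if (length(test_rows)) do.call(rbind, test_rows)
             else data.frame(test = character(0), comparison = character(0),
                             statistic = numeric(0), p_value = numeric(0))

  cmt <- echo_params(command = "compare", q_threshold = q_threshold)
  write_tsv_commented(counts$per_condition,
                      paste0(out_prefix, "_counts.tsv"), cmt)
  cv_df <- do.call(rbind, lapply(conds, function(cn) {
    d <- cvs[[cn]]
    if (nrow(d)) cbind(condition = cn, d) else NULL
  }))
  if (!is.null(cv_df)) {
    write_tsv_commented(cv_df, paste0(out_prefix, "_cv.tsv"), cmt)
  }
  rank_df <- do.call(rbind, lapply(conds, function(cn) {
    cbind(condition = cn, ranks[[cn]])
  }))
  write_tsv_commented(rank_df, paste0(out_prefix, "_ranks.tsv"), cmt)
  inter_df <- data.frame(signature = names(inter),
                         count = as.integer(inter),
                         stringsAsFactors = FALSE)
  write_tsv_commented(inter_df, paste0(out_prefix, "_intersections.tsv"),
                      cmt)
  write_tsv_commented(test_df, paste0(out_prefix, "_tests.tsv"), cmt)
  jsonlite::write_json(
    list(command = "compare", q_threshold = q_threshold,
         conditions = conds,
         per_condition = counts$per_condition,
         proportion_quantified = as.list(prop_q),
         intersections = as.list(inter),
         tests = test_df),
    paste0(out_prefix, "_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(counts = counts, cvs = cvs, ranks = ranks,
                 proportion_quantified = prop_q, intersections = inter,
                 tests = test_df))
}

# Read a YAML or JSON run-configuration file into a named list.
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Command-line entry point
#'
#' Dispatches the `digest`, `profile`, `simulate` and `compare`
#' subcommands; intended to be called from the thin launcher script
#' shipped in `inst/cli/proteasim.R` (`Rscript .../proteasim.R <command>
#' [options]`). Exit status 0 on success, 2 on usage/input errors, 1 on
#' internal errors.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (the launcher passes it to `quit()`).
#' @export
proteasim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: proteasim <digest|profile|simulate|compare> [options]"
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
      digest = cli_digest(rest),
      profile = cli_profile(rest),
      simulate = cli_simulate(rest),
      compare = cli_compare(rest),
      {
        message("unknown command: ", cmd, "\n", usage)
        return(invisible(2L))
      })
    0L
  }, usage_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  }, error = function(e) {
    msg <- conditionMessage(e)
    # input problems (missing files/columns, bad parameters) are usage errors
    if (grepl("not found|missing|unknown|must|empty|invalid|need|require",
              msg)) {
      message("error: ", msg)
      2L
    } else {
      message("internal error: ", msg)
      1L
    }
  })
  invisible(status)
}

cli_digest <- function(args) {
  parser <- optparse::OptionParser(
    usage = "proteasim digest --fasta FILE --out FILE [options]",
    option_list = list(
      optparse::make_option("--fasta", type = "character"),
      optparse::make_option("--enzyme", type = "character",
                            default = "trypsin"),
      optparse::make_option("--max-missed", type = "integer", default = 2L,
                            dest = "max_missed"),
      optparse::make_option("--min-len", type = "integer", default = 6L,
                            dest = "min_len"),
      optparse::make_option("--max-len", type = "integer", default = 60L,
                            dest = "max_len"),
      optparse::make_option("--out", type = "character")))
  o <- optparse::parse_args(parser, args = args)
  if (is.null(o$fasta) || is.null(o$out)) {
    stop("--fasta and --out are required", call. = FALSE)
  }
  cmd_digest(o$fasta, o$enzyme, o$max_missed, o$min_len, o$max_len, o$out)
}

cli_profile <- function(args) {
  parser <- optparse::OptionParser(
    usage = "proteasim profile --fasta FILE --out-prefix PFX [options]",
    option_list = list(
      optparse::make_option("--fasta", type = "character"),
      optparse::make_option("--enzymes", type = "character",
                            default = "trypsin,lysc,argc,gluc"),
      optparse::make_option("--scan-residues", action = "store_true",
                            default = FALSE, dest = "scan_residues"),
      optparse::make_option("--reference", type = "character",
                            default = "trypsin"),
      optparse::make_option("--max-missed", type = "integer", default = 2L,
                            dest = "max_missed"),
      optparse::make_option("--min-len", type = "integer", default = 6L,
                            dest = "min_len"),
      optparse::make_option("--max-len", type = "integer", default = 60L,
                            dest = "max_len"),
      optparse::make_option("--out-prefix", type = "character",
                            dest = "out_prefix")))
  o <- optparse::parse_args(parser, args = args)
  if (is.null(o$fasta) || is.null(o$out_prefix)) {
    stop("--fasta and --out-prefix are required", call. = FALSE)
  }
  cmd_profile(o$fasta, strsplit(o$enzymes, ",")[[1]], o$scan_residues,
              o$reference, o$max_missed, o$min_len, o$max_len,
              o$out_prefix)
}

cli_simulate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "proteasim simulate --out-dir DIR [options]",
    option_list = list(
      optparse::make_option("--config", type = "character",
                            default = NULL),
      optparse::make_option("--n-proteins", type = "integer",
                            default = 500L, dest = "n_proteins"),
      optparse::make_option("--enzyme", type = "character",
                            default = "trypsin"),
      optparse::make_option("--conditions", type = "character",
                            default = "cond1"),
      optparse::make_option("--n-replicates", type = "integer",
                            default = 3L, dest = "n_replicates"),
      optparse::make_option("--replicate-cv", type = "double",
                            default = 0.15, dest = "replicate_cv"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out-dir", type = "character",
                            dest = "out_dir")))
  o <- optparse::parse_args(parser, args = args)
  if (is.null(o$out_dir)) stop("--out-dir is required", call. = FALSE)
  cmd_simulate(n_proteins = o$n_proteins, enzyme = o$enzyme,
               conditions = strsplit(o$conditions, ",")[[1]],
               n_replicates = o$n_replicates,
               replicate_cv = o$replicate_cv, seed = o$seed,
               out_dir = o$out_dir, config_file = o$config)
}

cli_compare <- function(args) {
  parser <- optparse::OptionParser(
    usage = "proteasim compare --ids FILE --out-prefix PFX [options]",
    option_list = list(
      optparse::make_option("--ids", type = "character"),
      optparse::make_option("--q-threshold", type = "double",
                            default = 0.01, dest = "q_threshold"),
      optparse::make_option("--tests", type = "character",
                            default = "wilcoxon,ks_uniformity,welch_t"),
      optparse::make_option("--out-prefix", type = "character",
                            dest = "out_prefix")))
  o <- optparse::parse_args(parser, args = args)
  if (is.null(o$ids) || is.null(o$out_prefix)) {
    stop("--ids and --out-prefix are required", call. = FALSE)
  }
  cmd_compare(o$ids, o$q_threshold, strsplit(o$tests, ",")[[1]],
              o$out_prefix)
}
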
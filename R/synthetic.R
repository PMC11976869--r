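#' Average human proteome amino-acid composition
#'
#' Relative frequencies of the 20 standard residues approximating the
#' composition of the reviewed human proteome (lysine ~5.7%, arginine
#' ~5.6%, leucine ~10%). Used as the default residue model for synthetic
#' proteomes.
#'
#' @return Named numeric vector summing to 1.
#' @export
human_residue_frequencies <- function() {
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
         P = 6.3, S = 8.3, T = 5.4, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
}

#' Synthetic proteome model
#'
#' Describes a random proteome: protein count, a log-normal length
#' distribution (median 375 residues by default, the human scale), and
#' per-residue sampling frequencies.
#'
#' @param n_proteins Number of proteins (> 0).
#' @param median_length Median protein length in residues.
#' @param sdlog_length Log-scale dispersion of the length distribution.
#' @param residue_frequencies Named probabilities over residue letters;
#'   must sum to 1 (within 1e-9).
#' @param seed Integer seed used by [generate_proteome()].
#' @return A `ProteomeModel` list.
#' @export
proteome_model <- function(n_proteins, median_length = 375,
                           sdlog_length = 0.65,
                           residue_frequencies = human_residue_frequencies(),
                           seed = 1L) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    stop("n_proteins must be a positive integer", call. = FALSE)
  }
  if (is.null(names(residue_frequencies)) ||
      any(residue_frequencies < 0) ||
      abs(sum(residue_frequencies) - 1) > 1e-9) {
    stop("residue_frequencies must be named, non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 median_length = median_length,
                 sdlog_length = sdlog_length,
                 residue_frequencies = residue_frequencies,
                 seed = as.integer(seed)),
            class = "ProteomeModel")
}

#' Generate a synthetic proteome
#'
#' Draws protein lengths from the model's log-normal distribution and
#' residues i.i.d. from its frequency table. Accessions are
#' `SYN000001 ...`; output is fully determined by the model (including
#' its seed).
#'
#' @param model A [proteome_model()].
#' @return A [proteome()].
#' @export
generate_proteome <- function(model) {
  stopifnot(inherits(model, "ProteomeModel"))
  set.seed(model$seed)
  n <- model$n_proteins
  lens <- pmax(1L, as.integer(round(stats::rlnorm(
    n, meanlog = log(model$median_length), sdlog = model$sdlog_length))))
  letters_pool <- sample(names(model$residue_frequencies), sum(lens),
                         replace = TRUE, prob = model$residue_frequencies)
  idx <- rep.int(seq_len(n), lens)
  seqs <- vapply(split(letters_pool, idx), paste, character(1),
                 collapse = "")
  proteome(accession = sprintf("SYN%06d", seq_len(n)),
           sequence = unname(seqs),
           description = "synthetic protein",
           source_path = "synthetic")
}

#' Protein abundance model
#'
#' Log10 abundances are normal with a scale calibrated so that the
#' expected log10 range (max/min) of a sample of the proteome's size
#' spans the requested number of orders of magnitude (default 6, the
#' within-cell dynamic range scale).
#'
#' @param dynamic_range_orders Target orders of magnitude between the
#'   most and least abundant proteins.
#' @param location Mean log10 abundance (arbitrary intensity units).
#' @param seed Integer seed used by [assign_abundances()].
#' @return An `AbundanceModel` list.
#' @export
abundance_model <- function(dynamic_range_orders = 6, location = 6,
                            seed = 1L) {
  if (dynamic_range_orders <= 0) {
    stop("dynamic_range_orders must be positive", call. = FALSE)
  }
  structure(list(dynamic_range_orders = dynamic_range_orders,
                 location = location, seed = as.integer(seed)),
            class = "AbundanceModel")
}

#' Assign protein abundances
#'
#' Draws one positive abundance per protein, log10-normal, with the
#' normal scale set from the Blom approximation to the expected range of
#' `n` standard-normal draws so that `log10(max / min)` is close to the
#' model's target dynamic range. The achieved range is attached as the
#' `achieved_orders` attribute.
#'
#' @param proteome A [proteome()].
#' @param model An [abundance_model()].
#' @return Named numeric vector of abundances (names = accessions).
#' @export
assign_abundances <- function(proteome, model) {
  stopifnot(is_proteome(proteome), inherits(model, "AbundanceModel"))
  set.seed(model$seed)
  n <- nrow(proteome)
  # expected standardized range of n normal draws (Blom)
  d <- 2 * stats::qnorm((n - 0.375) / (n + 0.25))
  sigma <- if (is.finite(d) && d > 0) model$dynamic_range_orders / d
           else model$dynamic_range_orders / 4
  lg <- stats::rnorm(n, mean = model$location, sd = sigma)
  ab <- 10^lg
  names(ab) <- proteome$accession
  attr(ab, "achieved_orders") <- if (n > 1) log10(max(ab) / min(ab)) else 0
  ab
}

#' Observation model for simulated identifications
#'
#' Describes how digested peptides are observed across replicates:
#' multiplicative log-normal replicate noise at a target CV,
#' abundance-dependent stochastic detection (a logistic curve in log10
#' parent abundance, mimicking data-dependent acquisition), and a
#' two-component q-value mixture placing a configurable fraction of rows
#' above the confidence threshold.
#'
#' @param n_replicates Replicates per condition.
#' @param replicate_cv Target coefficient of variation of the
#'   multiplicative noise (fraction, e.g. 0.15 for 15%).
#' @param detection_midpoint Log10 parent abundance at which detection
#'   probability is 0.5; `NULL` (default) uses the median log10 abundance
#'   of the simulated proteome.
#' @param detection_slope Slope of the logistic detection curve (per
#'   log10 unit); larger is sharper.
#' @param detection_constant If non-`NULL`, overrides the logistic curve
#'   with a fixed detection probability (e.g. `1` for complete,
#'   noise-only observation).
#' @param q_above_fraction Fraction of rows drawn with q-values above
#'   `q_threshold` (uniform on `(q_threshold, 1]`); the rest are uniform
#'   on `[0, q_threshold)`.
#' @param q_threshold Confidence threshold used by the q mixture.
#' @param missed_penalty Multiplicative down-weight applied per missed
#'   cleavage when sharing parent abundance among peptides.
#' @param seed Integer seed used by [simulate_identifications()].
#' @return An `ObservationModel` list.
#' @export
observation_model <- function(n_replicates = 3L, replicate_cv = 0.15,
                              detection_midpoint = NULL,
                              detection_slope = 1,
                              detection_constant = NULL,
                              q_above_fraction = 0.05,
                              q_threshold = 0.01,
                              missed_penalty = 0.5,
                              seed = 1L) {
  if (replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  if (!is.null(detection_constant) &&
      (detection_constant < 0 || detection_constant > 1)) {
    stop("detection_constant must lie in [0, 1]", call. = FALSE)
  }
  if (q_above_fraction < 0 || q_above_fraction > 1) {
    stop("q_above_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 replicate_cv = replicate_cv,
                 detection_midpoint = detection_midpoint,
                 detection_slope = detection_slope,
                 detection_constant = detection_constant,
                 q_above_fraction = q_above_fraction,
                 q_threshold = q_threshold,
                 missed_penalty = missed_penalty,
                 seed = as.integer(seed)),
            class = "ObservationModel")
}

#' Simulate an identification table
#'
#' Digests every protein with the given rule and criteria, assigns each
#' distinct peptide sequence a share of its parent's abundance (parent
#' abundance divided equally among zero-missed peptides; missed-cleavage
#' products additionally down-weighted by `missed_penalty` per missed
#' site), then observes each (peptide, condition, replicate)
#' independently with the model's detection probability. Observed rows
#' receive multiplicative log-normal noise at the target replicate CV
#' and a q-value from the mixture model. Fully reproducible from the
#' model seeds.
#'
#' @param proteome A [proteome()].
#' @param abundances Named abundance vector from [assign_abundances()].
#' @param rule A [cleavage_rule()] or spec.
#' @param config A [digest_config()].
#' @param obs An [observation_model()].
#' @param conditions Character vector of condition labels; the
#'   observation process is drawn independently per condition.
#' @return An [identification_table()].
#' @export
simulate_identifications <- function(proteome, abundances, rule,
                                     config = digest_config(),
                                     obs = observation_model(),
                                     conditions = "cond1") {
  stopifnot(is_proteome(proteome), inherits(obs, "ObservationModel"))
  rule <- compile_rule(rule)
  if (is.null(names(abundances)) ||
      !all(proteome$accession %in% names(abundances))) {
    stop("abundances must be named for every accession", call. = FALSE)
  }
  set.seed(obs$seed)

  base <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    pep <- digest(proteome$sequence[i], rule, config,
                  accession = proteome$accession[i])
    if (nrow(pep) == 0L) next
    parent <- abundances[[proteome$accession[i]]]
    n_zero <- sum(pep$missed == 0L)
    denom <- if (n_zero > 0L) n_zero else nrow(pep)
    share <- (parent / denom) * obs$missed_penalty^pep$missed
    # collapse positional duplicates of the same sequence
    agg <- tapply(share, pep$sequence, sum)
    base[[i]] <- data.frame(protein = proteome$accession[i],
                            peptide = names(agg),
                            base_abundance = as.numeric(agg),
                            parent_abundance = parent,
                            stringsAsFactors = FALSE)
  }
  base <- do.call(rbind, base)
  if (is.null(base) || nrow(base) == 0L) {
    stop("digestion produced no peptides under this configuration",
         call. = FALSE)
  }

  midpoint <- obs$detection_midpoint
  if (is.null(midpoint)) {
    midpoint <- stats::median(log10(abundances[proteome$accession]))
  }
  p_det <- if (!is.null(obs$detection_constant)) {
    rep(obs$detection_constant, nrow(base))
  } else {
    stats::plogis(obs$detection_slope *
                    (log10(base$parent_abundance) - midpoint))
  }
  sdlog <- sqrt(log(1 + obs$replicate_cv^2))

  out <- vector("list", length(conditions) * obs$n_replicates)
  k <- 0L
  for (cond in conditions) {
    for (r in seq_len(obs$n_replicates)) {
      hit <- stats::runif(nrow(base)) < p_det
      if (!any(hit)) next
      b <- base[hit, , drop = FALSE]
      noise <- if (sdlog > 0) exp(stats::rnorm(nrow(b), 0, sdlog)) else 1
      above <- stats::runif(nrow(b)) < obs$q_above_fraction
      q <- ifelse(above,
                  stats::runif(nrow(b), obs$q_threshold, 1),
                  stats::runif(nrow(b), 0, obs$q_threshold))
      k <- k + 1L
      out[[k]] <- data.frame(protein = b$protein,
                             peptide = b$peptide,
                             condition = cond,
                             replicate = r,
                             abundance = b$base_abundance * noise,
                             q_value = q,
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[seq_len(k)]
  if (k == 0L) {
    warning("no peptides detected under this observation model")
    empty <- data.frame(protein = character(0), peptide = character(0),
                        condition = character(0), replicate = integer(0),
                        abundance = numeric(0), q_value = numeric(0))
    return(identification_table(empty))
  }
  identification_table(do.call(rbind, out))
}
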
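# Brute-force oracles, independent of the package's enumeration path.

# All fully specific peptides by exhaustive substring scan: every (i, j)
# whose boundaries sit on cleavage sites or protein termini, with the
# internal site count and length filter applied afterwards.
oracle_digest <- function(sequence, rule, config) {
  n <- nchar(sequence)
  sites <- proteasim::find_sites(sequence, rule)
  starts_ok <- c(0L, sites)   # left boundary offsets
  ends_ok <- c(sites, n)      # right boundary offsets
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!((i - 1L) %in% starts_ok) || !(j %in% ends_ok)) next
      missed <- sum(sites > (i - 1L) & sites < j)
      len <- j - i + 1L
      if (missed <= config$max_missed &&
          len >= config$min_len && len <= config$max_len) {
        rows[[length(rows) + 1L]] <- data.frame(start = i, end = j,
                                                missed = missed)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      missed = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

random_sequence <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_rule <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  proteasim::cleavage_rule(sample(aa, sample(1:3, 1)),
                           sample(c("C", "N"), 1))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of labelings.
wilcoxon_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Permutation p for the two-sample KS statistic by full enumeration.
ks_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_stat <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(g) - ecdf(y)(g)))
  }
  d_obs <- d_stat(a, b)
  combos <- utils::combn(length(pooled), n)
  d_all <- apply(combos, 2, function(idx) {
    d_stat(pooled[idx], pooled[-idx])
  })
  mean(d_all >= d_obs - 1e-12)
}

make_toy_table <- function() {
  proteasim::identification_table(data.frame(
    protein = c("A", "A", "A", "B", "B", "B", "C", "C"),
    peptide = c("p1", "p1", "p1", "p2", "p2", "p2", "p3", "p3"),
    condition = "c1",
    replicate = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L),
    abundance = c(90, 100, 110, 9, 10, 11, 5, NA),
    q_value = 0))
}
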
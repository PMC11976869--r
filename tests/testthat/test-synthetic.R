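test_that("proteome generation is seed-deterministic and respects composition", {
  m <- proteome_model(10, seed = 42)
  p1 <- generate_proteome(m)
  p2 <- generate_proteome(m)
  expect_identical(p1, p2)
  expect_equal(p1$accession[1], "SYN000001")

  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p1, fa1); write_fasta(p2, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  # degenerate composition
  onlyk <- proteome_model(5, residue_frequencies = c(K = 1), seed = 1)
  pk <- generate_proteome(onlyk)
  expect_true(all(grepl("^K+$", pk$sequence)))

  expect_error(proteome_model(5, residue_frequencies = c(K = 0.5)),
               "sum to 1")
  expect_error(proteome_model(0), "positive")
})

test_that("empirical residue frequencies approach the configured values", {
  p <- generate_proteome(proteome_model(2000, seed = 7))
  all_res <- strsplit(paste(p$sequence, collapse = ""), "")[[1]]
  k_freq <- mean(all_res == "K")
  target <- human_residue_frequencies()[["K"]]
  expect_lt(abs(k_freq - target), 0.005)
})

test_that("abundances are positive, seeded, and span the target dynamic range", {
  p1 <- generate_proteome(proteome_model(1, seed = 2))
  a1 <- assign_abundances(p1, abundance_model(seed = 2))
  expect_length(a1, 1)
  expect_gt(a1[[1]], 0)

  p <- generate_proteome(proteome_model(200, seed = 3))
  am <- abundance_model(seed = 9)
  expect_identical(assign_abundances(p, am), assign_abundances(p, am))

  big <- generate_proteome(proteome_model(5000, median_length = 30,
                                          seed = 4))
  ab <- assign_abundances(big, abundance_model(dynamic_range_orders = 6,
                                               seed = 5))
  span <- log10(max(ab) / min(ab))
  expect_gt(span, 5)
  expect_lt(span, 7)
  expect_equal(attr(ab, "achieved_orders"), span)
})

test_that("noiseless complete observation reproduces parent-proportional abundances", {
  p <- generate_proteome(proteome_model(20, median_length = 50, seed = 6))
  ab <- assign_abundances(p, abundance_model(seed = 6))
  obs <- observation_model(n_replicates = 2, replicate_cv = 0,
                           detection_constant = 1, q_above_fraction = 0,
                           seed = 6)
  cfg <- digest_config(2, 6, 60)
  tab <- simulate_identifications(p, ab, "trypsin", cfg, obs)

  # every digestible peptide sequence present in every replicate
  pep_per_prot <- vapply(seq_len(nrow(p)), function(i) {
    length(unique(digest(p$sequence[i], "trypsin", cfg)$sequence))
  }, numeric(1))
  expect_equal(nrow(tab), 2 * sum(pep_per_prot))
  expect_true(all(tab$q_value < 0.01))

  # zero-missed shares: parent abundance split equally
  i <- which(pep_per_prot > 0)[1]
  d <- digest(p$sequence[i], "trypsin", cfg)
  zero <- d$sequence[d$missed == 0][1]
  got <- tab$abundance[tab$protein == p$accession[i] &
                         tab$peptide == zero & tab$replicate == 1]
  expect_equal(got, ab[[p$accession[i]]] / sum(d$missed == 0))

  # replicates identical in the noiseless limit
  r1 <- tab[tab$replicate == 1, c("protein", "peptide", "abundance")]
  r2 <- tab[tab$replicate == 2, c("protein", "peptide", "abundance")]
  expect_equal(r1[order(r1$protein, r1$peptide), "abundance"],
               r2[order(r2$protein, r2$peptide), "abundance"])
})

test_that("zero detection yields an empty table with a warning", {
  p <- generate_proteome(proteome_model(5, seed = 8))
  ab <- assign_abundances(p, abundance_model(seed = 8))
  expect_warning(
    tab <- simulate_identifications(p, ab, "trypsin", digest_config(),
                                    observation_model(detection_constant = 0,
                                                      seed = 8)),
    "no peptides detected")
  expect_equal(nrow(tab), 0L)
})

test_that("abundance-dependent detection enriches for abundant proteins", {
  p <- generate_proteome(proteome_model(1000, median_length = 100,
                                        seed = 10))
  ab <- assign_abundances(p, abundance_model(seed = 10))
  obs <- observation_model(n_replicates = 1, detection_slope = 2,
                           seed = 10)
  tab <- simulate_identifications(p, ab, "trypsin", digest_config(), obs)
  truth_rank <- rank(-ab[p$accession])
  names(truth_rank) <- p$accession
  detected <- unique(tab$protein)
  expect_lt(median(truth_rank[detected]), median(truth_rank))
})

test_that("simulation is byte-identical for a fixed seed and recovers structure", {
  p <- generate_proteome(proteome_model(50, median_length = 80, seed = 12))
  ab <- assign_abundances(p, abundance_model(seed = 12))
  obs <- observation_model(seed = 12)
  t1 <- simulate_identifications(p, ab, "lysc", digest_config(), obs)
  t2 <- simulate_identifications(p, ab, "lysc", digest_config(), obs)
  expect_identical(t1, t2)

  # truth vs simulated: protein mean abundance rank correlation > 0.9
  # under complete detection and mild noise
  obs2 <- observation_model(n_replicates = 3, replicate_cv = 0.2,
                            detection_constant = 1, seed = 13)
  p2 <- generate_proteome(proteome_model(150, median_length = 100,
                                         seed = 13))
  ab2 <- assign_abundances(p2, abundance_model(seed = 13))
  tab <- simulate_identifications(p2, ab2, "trypsin", digest_config(),
                                  obs2)
  r <- rank_abundance(tab, "cond1")
  truth <- ab2[r$protein]
  expect_gt(cor(r$mean_abundance, truth, method = "spearman"), 0.9)
})

test_that("subset-specificity rules yield no more peptides per protein", {
  # LysC sites are a subset of trypsin sites: at max_missed 0 and an
  # unbounded window, each protein has <= as many LysC peptides
  p <- generate_proteome(proteome_model(40, seed = 15))
  cfg <- digest_config(0, 1, 100000)
  st <- digest_proteome(p, "trypsin", cfg)
  sl <- digest_proteome(p, "lysc", cfg)
  expect_true(all(sl$per_protein <= st$per_protein))
})
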
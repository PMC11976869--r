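test_that("confidence filtering keeps rows strictly below the q threshold", {
  tab <- identification_table(data.frame(
    protein = c("A", "B"), peptide = c("p1", "p2"), condition = "c1",
    replicate = 1L, abundance = c(10, 20), q_value = c(0.001, 0.02)))
  suppressMessages({
    expect_equal(nrow(filter_confident(tab, 0.01)), 1L)
    expect_equal(nrow(filter_confident(tab, 1)), 2L)
  })
  expect_error(filter_confident(tab, 0), "threshold")
  expect_error(filter_confident(tab, 1.5), "threshold")

  # random mixture: retained count equals a direct recount
  set.seed(14)
  q <- runif(300)
  big <- identification_table(data.frame(
    protein = sprintf("P%03d", 1:300), peptide = "pep", condition = "c1",
    replicate = 1L, abundance = 1, q_value = q))
  suppressMessages(f <- filter_confident(big, 0.3))
  expect_equal(nrow(f), sum(q < 0.3))
})

test_that("count summaries give distinct proteins/peptides per replicate and condition means", {
  tab <- identification_table(data.frame(
    protein = c("A", "A", "B", "A", "B", "C", "D"),
    peptide = c("p1", "p2", "p3", "p1", "p3", "p4", "p5"),
    condition = "c1",
    replicate = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
    abundance = 1, q_value = 0))
  s <- summarize_counts(tab)
  expect_equal(s$per_replicate$n_proteins, c(2L, 4L))
  expect_equal(s$per_replicate$n_peptides, c(3L, 4L))
  expect_equal(s$per_condition$mean_proteins, 3)
  expect_equal(s$per_condition$sd_proteins, sd(c(2, 4)))
  expect_error(summarize_counts(tab[0, ]), "empty")
})

test_that("CVs match hand computation and are scale invariant", {
  tab <- make_toy_table()
  suppressMessages(cv <- cv_per_protein(tab, "c1"))
  expect_equal(cv$cv_pct[cv$protein == "A"], 10)     # (90,100,110)
  expect_equal(cv$cv_pct[cv$protein == "B"], 10)     # (9,10,11)
  expect_false("C" %in% cv$protein)                  # 1 replicate < 2

  tab2 <- tab
  tab2$abundance <- tab2$abundance * 7.3
  suppressMessages(cv2 <- cv_per_protein(tab2, "c1"))
  expect_equal(cv2$cv_pct, cv$cv_pct)

  # peptide level exposes the same values here (1 peptide per protein)
  suppressMessages(cvp <- cv_per_protein(tab, "c1", level = "peptide"))
  expect_equal(sort(cvp$cv_pct), sort(cv$cv_pct))
})

test_that("CV recovery from the generator at peptide level", {
  # 500 single-peptide proteins, 6 replicates, 15% generative CV: the
  # median sample CV recovers the target within 2 absolute points
  set.seed(31)
  n <- 500
  s <- sqrt(log(1 + 0.15^2))
  rows <- expand.grid(protein = sprintf("P%03d", 1:n), replicate = 1:6)
  rows$peptide <- "pep"
  rows$condition <- "c1"
  rows$abundance <- 1e5 * exp(rnorm(nrow(rows), 0, s))
  rows$q_value <- 0
  tab <- identification_table(rows)
  suppressMessages(cv <- cv_per_protein(tab, "c1"))
  expect_equal(nrow(cv), n)
  expect_lt(abs(median(cv$cv_pct) - 15), 2)
})

test_that("proportion quantified counts complete entities", {
  tab <- make_toy_table()  # p1, p2 complete in reps 1:3; p3 absent in rep 3
  expect_equal(proportion_quantified(tab, "c1"), 2 / 3)
  full <- tab[tab$protein != "C", ]
  expect_equal(proportion_quantified(identification_table(full), "c1"), 1)
  expect_error(proportion_quantified(tab, "nope"), "no rows")
})

test_that("rank-abundance orders by mean abundance with deterministic ties", {
  tab <- make_toy_table()
  r <- rank_abundance(tab, "c1")
  expect_equal(r$protein, c("A", "B", "C"))
  expect_equal(r$rank, 1:3)
  expect_equal(r$mean_abundance[1], 100)

  tie <- identification_table(data.frame(
    protein = c("Z", "A"), peptide = "p", condition = "c1",
    replicate = 1L, abundance = 5, q_value = 0))
  rt <- rank_abundance(tie, "c1")
  expect_equal(rt$protein, c("A", "Z"))  # lexicographic tie-break

  # random log-normal table: rank order equals a direct sort
  set.seed(4)
  ab <- rlnorm(50, 10, 1)
  rnd <- identification_table(data.frame(
    protein = sprintf("P%02d", 1:50), peptide = "p", condition = "c1",
    replicate = 1L, abundance = ab, q_value = 0))
  rr <- rank_abundance(rnd, "c1")
  expect_equal(rr$protein, sprintf("P%02d", 1:50)[order(-ab)])
})

test_that("exclusive intersections partition the union", {
  x <- exclusive_intersections(list(X = c("a", "b"), Y = c("b", "c")))
  expect_equal(x[["X"]], 1L)
  expect_equal(x[["Y"]], 1L)
  expect_equal(x[["X&Y"]], 1L)

  d <- exclusive_intersections(list(X = "a", Y = "b"))
  expect_equal(d[["X&Y"]], 0L)
  expect_equal(sum(d), 2L)

  expect_error(exclusive_intersections(list(X = "a")), "at least 2")

  # random three-way sets: counts equal brute-force classification and
  # sum to the union size
  set.seed(12)
  universe <- sprintf("g%03d", 1:400)
  sets <- list(A = sample(universe, 100), B = sample(universe, 100),
               C = sample(universe, 100))
  got <- exclusive_intersections(sets)
  expect_equal(sum(got), length(unique(unlist(sets))))
  brute <- table(vapply(unique(unlist(sets)), function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1)))
  for (sig in names(brute)) {
    expect_equal(got[[sig]], as.integer(brute[[sig]]))
  }
})

test_that("rank-uniformity KS behaves on degenerate and extreme inputs", {
  # single exactly-central rank (u = 0.5): D = 0.5 but p = 1, since a
  # single observation always attains D >= 0.5
  k1 <- ks_rank_uniformity(500, 999)
  expect_equal(unname(k1$statistic), 0.5)
  expect_equal(k1$p.value, 1)

  # ranks packed into the top decile: huge D, tiny p
  k2 <- ks_rank_uniformity(1:50, 10000, exact = FALSE)
  expect_gte(unname(k2$statistic), 0.9 - 50 / 10000)
  expect_lt(k2$p.value, 1e-10)

  expect_error(ks_rank_uniformity(integer(0), 10), "empty")
  expect_error(ks_rank_uniformity(11, 10), "in \\[1, n_total\\]")
  # p-values in [0,1] across random draws
  set.seed(2)
  ps <- replicate(50, {
    ks_rank_uniformity(sample(1000, 8), 1000)$p.value
  })
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("two-sample KS matches trivial cases and a permutation oracle", {
  same <- two_sample_ks(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  far <- two_sample_ks(c(1, 2, 3), c(101, 102, 103))
  expect_equal(unname(far$statistic), 1)

  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(sample(4:7, 1))
    b <- rnorm(sample(4:7, 1), mean = sample(0:2, 1))
    got <- two_sample_ks(a, b, exact = TRUE)$p.value
    want <- ks_perm_oracle(a, b)
    expect_lt(abs(got - want) / max(want, 1e-12), 0.10)
  }
})

test_that("Wilcoxon rank-sum matches exact enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(w$statistic), 0)
  expect_equal(w$p.value, 0.1)
  expect_equal(wilcoxon_perm_oracle(c(1, 2, 3), c(4, 5, 6)), 0.1)

  ident <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p.value, 1)

  set.seed(16)
  for (i in 1:10) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1), mean = 1)
    expect_equal(wilcoxon_rank_sum(a, b)$p.value,
                 wilcoxon_perm_oracle(a, b), tolerance = 1e-10)
  }

  # strongly shifted samples are decisively rejected
  set.seed(17)
  big <- wilcoxon_rank_sum(rlnorm(60, 0, 0.3), rlnorm(60, 2, 0.3))
  expect_lt(big$p.value, 1e-3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("Welch t handles degenerate input and grows with the shift", {
  t0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  expect_error(two_sample_t(c(2, 2), c(2, 2)), "constant|variance")

  set.seed(19)
  base <- rnorm(20)
  stats <- vapply(c(0.5, 1, 2, 4), function(shift) {
    abs(unname(two_sample_t(base, base + shift)$statistic))
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
})
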
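test_that("majority vote follows the strict-majority / tie-exclusion rule", {
  mk <- function(...) {
    states <- list(...)
    lapply(seq_along(states), function(i)
      make_decoding(states[[i]], pair_id = paste0("p", i), patient_id = "A"))
  }
  expect_equal(unname(majority_vote(mk(c("+"), c("+"), c("-")))), "+")
  expect_equal(unname(majority_vote(mk(c("+"), c("-")))), "excluded")
  expect_equal(unname(majority_vote(mk(c("="), c("="), c("=")))), "=")
  expect_equal(unname(majority_vote(mk(c("-"), c("="), c("=")))), "-")
  # single pair: identity on states
  st <- c("-", "=", "+", "=")
  expect_equal(unname(majority_vote(mk(st))), st)
  # mismatched gene universes are rejected
  bad <- list(make_decoding(c("+", "-")),
              make_decoding(c("+", "-"), gene_ids = c("x", "y")))
  expect_error(majority_vote(bad), "universes")
})

test_that("consensus tallies, tie fraction and rankings are consistent", {
  g <- c("ccl19", "gap43", "itih2", "zzz1")
  dec <- list(
    make_decoding(c("-", "+", "+", "="), "pA1", "A", g),
    make_decoding(c("-", "+", "-", "="), "pA2", "A", g),  # itih2 tied in A
    make_decoding(c("-", "+", "+", "="), "pB1", "B", g),
    make_decoding(c("-", "+", "+", "+"), "pC1", "C", g))
  cons <- patient_consensus(dec)
  expect_equal(unname(cons$n_down[["ccl19"]]), 3)
  expect_equal(unname(cons$n_up[["gap43"]]), 3)
  expect_equal(cons$states["itih2", "A"], "excluded")
  # one tie among 4 genes in the single multi-pair patient
  expect_equal(cons$tie_fraction, 1 / 4)
  rk <- rank_genes(cons)
  # tied gene is dropped from both rankings
  expect_false("itih2" %in% rk$down$gene_id)
  expect_false("itih2" %in% rk$up$gene_id)
  expect_equal(rk$down$gene_id[1], "ccl19")
  expect_equal(rk$up$gene_id[1], "gap43")
  # count ties break alphabetically
  expect_equal(rk$down$gene_id, c("ccl19", "gap43", "zzz1"))
  cs <- candidate_set(rk, 3)
  expect_equal(cs$down, "ccl19")
  expect_equal(cs$up, "gap43")
  # monotone in min_patients
  for (k in 1:3) {
    a <- candidate_set(rk, k); b <- candidate_set(rk, k + 1)
    expect_true(all(b$down %in% a$down))
    expect_true(all(b$up %in% a$up))
  }
  expect_equal(lengths(candidate_set(rk, 99)), c(down = 0L, up = 0L))
})

test_that("all-unchanged consensus ranks alphabetically with zero counts", {
  g <- c("b", "a", "c")
  dec <- list(make_decoding(c("=", "=", "="), "p1", "A", g))
  rk <- rank_genes(patient_consensus(dec))
  expect_equal(rk$down$gene_id, c("a", "b", "c"))
  expect_true(all(rk$down$n_patients == 0))
})

test_that("Mann-Whitney exact and normal paths match wilcox.test", {
  set.seed(77)
  for (rep in 1:20) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    x <- rnorm(m); y <- rnorm(n)
    ours <- mann_whitney_u(x, y, "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    # the doubling-rule exact p of wilcox.test and the symmetric-tail
    # enumeration agree for these continuous samples
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    big <- mann_whitney_u(rnorm(30), rnorm(25), "normal")
    ref2 <- wilcox.test(rnorm(30), rnorm(25), exact = FALSE)
    expect_true(big$p >= 0 && big$p <= 1)
  }
  # normal approximation with ties reproduces wilcox.test's corrected z
  x <- c(1, 2, 2, 3, 5, 5, 5); y <- c(2, 3, 3, 4, 5, 6)
  ours <- mann_whitney_u(x, y, "normal")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("pairwise overlap counts matches and groups comparisons", {
  g <- sprintf("g%d", 1:4)
  d <- list(
    make_decoding(c("-", "=", "+", "="), "a1", "A", g),
    make_decoding(c("-", "=", "-", "+"), "a2", "A", g),   # 2/4 match with a1
    make_decoding(c("-", "=", "+", "="), "b1", "B", g),   # identical to a1
    make_decoding(c("+", "-", "=", "-"), "c1", "C", g))
  expect_warning(ov <- pairwise_overlap(d, method = "normal"),
                 "fewer than 2")
  cmp <- ov$comparisons
  expect_equal(cmp$overlap[cmp$pair_a == "a1" & cmp$pair_b == "a2"], 50)
  expect_equal(cmp$overlap[cmp$pair_a == "a1" & cmp$pair_b == "b1"], 100)
  expect_equal(cmp$group[cmp$pair_a == "a1" & cmp$pair_b == "a2"],
               "same_patient")
  expect_equal(sum(cmp$group == "same_patient"), 1)
  expect_equal(nrow(cmp), choose(4, 2))
  expect_true(all(cmp$overlap >= 0 & cmp$overlap <= 100))
})

test_that("candidate-set comparison equals the hypergeometric oracle", {
  universe <- sprintf("u%03d", 1:100)
  own <- universe[1:10]
  external <- universe[c(1:5, 30:44)]   # overlap 5, external 20
  res <- compare_candidate_sets(own, external, universe)
  expect_equal(res$n_overlap, 5)
  expect_equal(res$overlap_fraction, 0.5)
  expect_equal(res$p, hyper_fisher_oracle(5, 10, 20, 100), tolerance = 1e-10)
  # identity and disjoint extremes
  expect_equal(compare_candidate_sets(own, own, universe)$overlap_fraction, 1)
  expect_equal(compare_candidate_sets(universe[1:50], universe[51:100],
                                      universe)$overlap_fraction, 0)
  expect_error(compare_candidate_sets(own, external, character(0)), "empty")
})
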
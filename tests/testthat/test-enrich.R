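test_that("contingency tables count correctly and keep marginals", {
  bg <- sprintf("G%d", 1:10)
  tb <- build_contingency(c("G1", "G2"), c("G1", "G3"), bg)
  expect_equal(unname(tb), c(1, 1, 1, 7))
  # term disjoint from background
  tb2 <- build_contingency(c("G1", "G2"), c("X1", "X2"), bg)
  expect_equal(unname(tb2[c("a", "c")]), c(0, 0))
  expect_error(build_contingency(c("G1", "NOPE"), "G1", bg),
               "NOPE", class = "cikmir_contract_error")
  expect_error(build_contingency("G1", "G1", character(0)),
               class = "cikmir_contract_error")
  # marginal identities on random instances
  set.seed(14)
  for (i in 1:10) {
    sel <- sample(bg, sample(0:10, 1))
    term <- sample(sprintf("G%d", 1:15), 5)
    tb <- build_contingency(sel, term, bg)
    expect_equal(tb[["a"]] + tb[["b"]], length(sel))
    expect_equal(tb[["a"]] + tb[["c"]],
                 length(intersect(normalize_symbols(term), bg)))
    expect_equal(sum(tb), length(bg))
  }
})

test_that("Fisher p equals frozen closed-form tails", {
  expect_equal(fisher_exact_enrichment(c(5, 0, 0, 5)), 1 / 252)
  expect_equal(fisher_exact_enrichment(c(3, 1, 1, 3)), 17 / 70)
  expect_equal(fisher_exact_enrichment(c(0, 5, 5, 10)), 1)
})

test_that("Fisher matches stats::fisher.test one-sided on random tables", {
  set.seed(6)
  for (i in 1:20) {
    tb <- c(sample(0:8, 2, TRUE), sample(0:20, 2, TRUE))
    ft <- fisher.test(matrix(tb[c(1, 3, 2, 4)], 2), alternative = "greater")
    expect_equal(fisher_exact_enrichment(tb), ft$p.value, tolerance = 1e-9)
  }
})

test_that("chi-squared statistic, Yates direction, degenerate tables", {
  p0 <- chi_square_enrichment(c(25, 25, 25, 25))
  expect_equal(attr(p0, "statistic"), 0)
  expect_equal(as.numeric(p0), 1)
  p1 <- chi_square_enrichment(c(30, 20, 20, 30), yates = FALSE)
  expect_equal(attr(p1, "statistic"), 4)
  expect_equal(as.numeric(p1), pchisq(4, 1, lower.tail = FALSE))
  p2 <- chi_square_enrichment(c(30, 20, 20, 30), yates = TRUE)
  expect_gt(as.numeric(p2), as.numeric(p1))
  pz <- chi_square_enrichment(c(0, 0, 5, 5))
  expect_equal(as.numeric(pz), 1)
  expect_true(attr(pz, "degenerate"))
})

test_that("BH q-values match the step-up recursion and p.adjust", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(33)
  for (i in 1:8) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_equal(q, p.adjust(p, method = "BH"))
    # monotone along sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    # thresholding q equals the classic step-up rejection set
    for (alpha in c(0.05, 0.2)) {
      expect_equal(which(q <= alpha), bh_reject_oracle(p, alpha))
    }
  }
})

test_that("dual significance rule is strict on both thresholds", {
  res <- data.frame(term_id = c("t1", "t2", "t3", "t4"),
                    p_fisher = c(0.01, 0.01, 0.05, 0.049),
                    q_bh = c(0.03, 0.06, 0.01, 0.05))
  kept <- significant_terms(res)
  expect_equal(kept$term_id, "t1")
})

test_that("enrich_terms wires tables, q-values and significance", {
  sets <- list(S1 = sprintf("G%d", 1:5), S2 = sprintf("G%d", 6:10))
  gs <- gene_set_collection(sets)
  enr <- enrich_terms(sprintf("G%d", 1:4), gs,
                      background = sprintf("G%d", 1:10))
  expect_equal(enr$a[enr$term_id == "S1"], 4)
  expect_equal(enr$q_bh, bh_fdr(enr$p_fisher))
  expect_true(all(enr$q_bh >= 0 & enr$q_bh <= 1))
})

test_that("membership matrix is ordered by marginals, counts intersections", {
  sets <- list(T1 = c("A", "B", "C"), T2 = c("B"), T3 = c("X"))
  m <- membership_matrix(sets, c("T1", "T2", "T3"), c("A", "B", "C"))
  expect_equal(rownames(m), c("T1", "T2", "T3"))
  expect_equal(unname(rowSums(m)), c(3, 1, 0))
  expect_equal(membership_matrix(list(T = "A"), "T", "A"),
               matrix(1L, 1, 1, dimnames = list("T", "A")))
  expect_true(all(membership_matrix(list(T = "A"), "T", "B") == 0))
  set.seed(3)
  univ <- sprintf("g%02d", 1:30)
  sets <- lapply(1:4, function(i) sample(univ, 8))
  names(sets) <- paste0("T", 1:4)
  genes <- sample(univ, 10)
  m <- membership_matrix(sets, names(sets), genes)
  for (t in names(sets))
    expect_equal(sum(m[t, ]),
                 length(intersect(toupper(sets[[t]]), toupper(genes))))
})
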
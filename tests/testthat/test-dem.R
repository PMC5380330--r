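make_flag_dataset <- function(fa, fb) {
  m <- matrix(100, 1, 6,
              dimnames = list("mir1", c(paste0("a", 1:3), paste0("b", 1:3))))
  fl <- matrix(c(fa, fb), 1, 6, dimnames = dimnames(m))
  expression_dataset(m, fl, setNames(rep(c("A", "B"), each = 3),
                                     colnames(m)))
}

test_that("flag consistency requires all-same per group, one Present", {
  pass <- make_flag_dataset(rep("Present", 3), rep("Present", 3))
  expect_true(flag_consistency_filter(pass, c("A", "B"))[["mir1"]])
  mixed <- make_flag_dataset(c("Present", "Present", "Absent"),
                             rep("Present", 3))
  expect_false(flag_consistency_filter(mixed, c("A", "B"))[["mir1"]])
  # consistently Absent in one group still passes (other group Present)
  onesided <- make_flag_dataset(rep("Absent", 3), rep("Present", 3))
  expect_true(flag_consistency_filter(onesided, c("A", "B"))[["mir1"]])
  # Absent everywhere = unmeasured
  dark <- make_flag_dataset(rep("Absent", 3), rep("Absent", 3))
  expect_false(flag_consistency_filter(dark, c("A", "B"))[["mir1"]])
  expect_error(flag_consistency_filter(pass, c("A", "C")),
               class = "cikmir_contract_error")
})

test_that("pooled-variance t test matches frozen and oracle values", {
  m <- rbind(flat = c(1, 2, 3, 3, 2, 1),
             sep  = c(10, 11, 12, 13, 14, 15),
             degen = c(5, 5, 5, 7, 7, 7))
  res <- student_t_test(m, 1:3, 4:6)
  expect_equal(res["flat", "t_stat"], 0)
  expect_equal(res["flat", "p_value"], 1)
  expect_equal(res["sep", "t_stat"], -3.674235, tolerance = 1e-6)
  expect_equal(res["sep", "p_value"], 0.02131164, tolerance = 1e-6)
  expect_false(res["sep", "degenerate"])
  expect_true(res["degen", "degenerate"])
  expect_equal(res["degen", "p_value"], 0)
  # oracle: stats::t.test with var.equal = TRUE on random rows
  set.seed(42)
  r <- matrix(rnorm(50 * 8), 50, 8)
  mine <- student_t_test(r, 1:4, 5:8)
  for (i in c(1, 17, 50)) {
    tt <- t.test(r[i, 1:4], r[i, 5:8], var.equal = TRUE)
    expect_equal(mine$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value[i], tt$p.value, tolerance = 1e-12)
  }
  expect_error(student_t_test(m, 1, 4:6), class = "cikmir_contract_error")
})

test_that("fold change is ratio of linear group means", {
  m <- rbind(x = c(200, 200, 100, 100), y = c(50, 50, 50, 50))
  fc <- fold_change(m, 1:2, 3:4)
  expect_equal(unname(fc), c(2, 1))
  z <- rbind(z = c(1, 1, 0, 0))
  expect_message(fcz <- fold_change(z, 1:2, 3:4), "zero reference mean")
  expect_true(is.na(fcz))
})

test_that("DEM calls use strict thresholds on all three criteria", {
  base <- data.frame(fc_linear = c(2.5, 2.0, 3.0, 0.4, 0.5, 2.5),
                     p_value = c(0.01, 0.001, 0.2, 0.01, 0.01, 0.01),
                     flag_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  called <- call_dems(base)
  expect_equal(as.character(called$call),
               c("up", "none", "none", "down", "none", "none"))
})

test_that("contrast symmetry: swapped groups invert fc and flip calls", {
  gen <- generate_expression_dataset(de_spec(n_probes = 150, seed = 13))
  ds <- gen$dataset
  ab <- run_contrast(ds, c("CIK_IL2", "PBMC"))
  ba <- run_contrast(ds, c("PBMC", "CIK_IL2"))
  expect_equal(ab$fc_linear, 1 / ba$fc_linear)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$call == "up", ba$call == "down")
  # calls partition the probe set
  expect_true(all(table(ab$probe) == 1))
  expect_setequal(as.character(unique(ab$call)),
                  intersect(c("up", "down", "none"), as.character(ab$call)))
})

test_that("cross-contrast comparison equals brute-force set algebra", {
  gen <- generate_expression_dataset(de_spec(n_probes = 400, seed = 21))
  ds <- gen$dataset
  a <- run_contrast(ds, c("CIK_IL2", "PBMC"))
  b <- run_contrast(ds, c("CIK_IL15", "PBMC"))
  cmp <- compare_contrasts(a, b)
  up_a <- a$probe[a$call == "up"]; up_b <- b$probe[b$call == "up"]
  dn_a <- a$probe[a$call == "down"]; dn_b <- b$probe[b$call == "down"]
  expect_setequal(cmp$shared_up, intersect(up_a, up_b))
  expect_setequal(cmp$shared_down, intersect(dn_a, dn_b))
  expect_setequal(cmp$specific_up_a, setdiff(up_a, up_b))
  expect_setequal(cmp$specific_down_b, setdiff(dn_b, dn_a))
  expect_equal(cmp$percentages$pct_a[1],
               floor(10000 * length(intersect(up_a, up_b)) /
                       length(up_a)) / 100)
})

test_that("shared percentages truncate, reproducing the printed values", {
  expect_equal(truncated_percent(c(130, 130, 103, 103),
                                 c(150, 140, 111, 109)),
               c(86.66, 92.85, 92.79, 94.49))
  expect_equal(truncated_percent(1, 2), 50)
  expect_equal(truncated_percent(0, 7), 0)
})

test_that("hierarchical ordering is deterministic and matches hclust", {
  # identical profiles merge first at height zero
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), z = c(4, 2, 7, 1))
  h <- hierarchical_order(m)
  expect_equal(h$height[1], 0)
  expect_setequal(h$labels[-h$merge[1, ]], c("a", "b"))
  # oracle: stats::hclust average linkage on tie-free random data
  set.seed(8)
  r <- matrix(rnorm(72), 12, 6,
              dimnames = list(sprintf("p%02d", 1:12), NULL))
  mine <- hierarchical_order(r)
  ref <- hclust(as.dist(correlation_distance(r)), method = "average")
  expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
  for (k in 2:11) {
    part <- paste(cutree(mine, k), cutree(ref, k))
    expect_equal(length(unique(part)), k)
  }
  # input order does not change the leaf order
  rev_in <- hierarchical_order(r[rev(seq_len(nrow(r))), ])
  expect_identical(mine$labels[mine$order],
                   rev_in$labels[rev_in$order])
  # zero-variance probes sit at distance 1
  d <- correlation_distance(rbind(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(d[1, 2], 1)
})
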
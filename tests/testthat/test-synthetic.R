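test_that("expression generator is seed-deterministic", {
  a <- generate_expression_dataset(de_spec(n_probes = 60, seed = 9))
  b <- generate_expression_dataset(de_spec(n_probes = 60, seed = 9))
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$dataset$flags, b$dataset$flags)
  expect_identical(a$truth, b$truth)
  c <- generate_expression_dataset(de_spec(n_probes = 60, seed = 10))
  expect_false(identical(a$dataset$intensities, c$dataset$intensities))
})

test_that("zero DE fractions give an all-null truth table", {
  gen <- generate_expression_dataset(
    de_spec(n_probes = 50, de_fraction_up = 0, de_fraction_down = 0,
            seed = 2))
  expect_true(all(gen$truth$status == "none"))
})

test_that("planted up-probes show the stated mean linear fold change", {
  # law of large numbers over ~100 planted up-probes: with
  # effect_log2 = 2 the mean observed linear FC is ~4
  gen <- generate_expression_dataset(
    de_spec(n_probes = 2000, effect_log2 = 2, noise_sd_log2 = 0.25,
            flag_dropout = 0, seed = 5))
  ds <- gen$dataset
  up <- gen$truth$probe[gen$truth$contrast == "CIK_IL2" &
                          gen$truth$status == "up"]
  it <- which(ds$groups == "CIK_IL2")
  ir <- which(ds$groups == "PBMC")
  fc <- fold_change(ds$intensities[up, ], it, ir)
  expect_equal(mean(fc), 4, tolerance = 0.1)
})

test_that("spec validation rejects bad replicate counts and fractions", {
  expect_error(de_spec(groups = c(A = 1, B = 3)),
               class = "cikmir_contract_error")
  expect_error(de_spec(de_fraction_up = 1.5),
               class = "cikmir_contract_error")
  expect_error(cluster_spec(intra_gap_bp = 10, min_inter_cluster_gap_bp = 5),
               class = "cikmir_contract_error")
})

test_that("annotation generator plants recoverable clusters", {
  spec <- cluster_spec(n_clusters = 5, sizes = 2, intra_gap_bp = 3000,
                       n_singletons = 4, min_inter_cluster_gap_bp = 1e6,
                       seed = 4)
  ann <- generate_annotation(spec)
  # half-ish of rows use the minus-strand printed dialect
  expect_true(any(ann$start > ann$end) && any(ann$start < ann$end))
  expect_identical(normalize_coordinates(ann$start, ann$end)$low, ann$low)
  cl <- cluster_features(ann, max_gap = 5000, min_size = 2)
  s <- attr(cl, "summary")
  expect_equal(nrow(s), 5)
  got <- split(cl$name, cl$cluster_id)
  want <- split(ann$name[!is.na(ann$truth_cluster)],
                ann$truth_cluster[!is.na(ann$truth_cluster)])
  expect_true(set_equal_groups(got, want))
  # singletons only -> nothing reported
  ann0 <- generate_annotation(cluster_spec(n_clusters = 0,
                                           n_singletons = 10, seed = 4))
  expect_equal(nrow(attr(cluster_features(ann0), "summary")), 0)
  # determinism
  expect_identical(ann, generate_annotation(spec))
})

test_that("target-db generator honours the null and empty cases", {
  db <- generate_target_db(character(0), n_genes = 300, n_sets = 5,
                           set_size = c(20, 30), seed = 1)
  expect_equal(nrow(db$mti), 0)
  db2 <- generate_target_db(c("m1", "m2"), n_genes = 300, n_sets = 5,
                            set_size = c(20, 30), edges_per_mirna = 10,
                            seed = 1)
  expect_equal(nrow(db2$mti), 20)
  expect_identical(db2$mti,
                   generate_target_db(c("m1", "m2"), n_genes = 300,
                                      n_sets = 5, set_size = c(20, 30),
                                      edges_per_mirna = 10, seed = 1)$mti)
})
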
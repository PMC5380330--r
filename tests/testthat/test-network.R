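fixture_net <- function() {
  fx <- cytotox_fixture()
  genes <- c("FASLG", "TNFSF10", "OSM", "GZMB", "PRF1", "TNF", "CD40LG")
  edges <- filter_mti(fx$mti, c(fx$down_mirnas, fx$up_mirnas), genes)
  list(fx = fx, net = build_network(edges))
}

test_that("filtering keeps only requested endpoints, stably ordered", {
  fx <- cytotox_fixture()
  e <- filter_mti(fx$mti, "hsa-let-7c-5p", c("FASLG", "TNFSF10", "OSM"))
  expect_equal(nrow(e), 3)
  expect_equal(sort(e$gene), c("FASLG", "OSM", "TNFSF10"))
  expect_equal(nrow(filter_mti(fx$mti, character(0), "FASLG")), 0)
  set.seed(11)
  mti <- mti_table(sample(letters[1:5], 30, TRUE),
                   sample(c("G1", "G2", "G3"), 30, TRUE))
  keep <- filter_mti(mti, c("a", "b"), c("G1", "G2"))
  expect_true(all(keep$mirna %in% c("a", "b")))
  expect_true(all(keep$gene %in% c("G1", "G2")))
  expect_true(nrow(keep) <= nrow(mti))
})

test_that("networks are bipartite, deduplicated, degree-consistent", {
  e <- data.frame(mirna = c("m1", "m1", "m1"), gene = c("g1", "g1", "g2"))
  net <- build_network(e)
  expect_equal(nrow(net$edges), 2)  # duplicate collapses
  expect_equal(length(net$mirnas), 1)
  expect_error(build_network(data.frame(mirna = "X", gene = "X")),
               class = "cikmir_input_error")
  empty <- build_network(data.frame(mirna = character(0),
                                    gene = character(0)))
  expect_equal(length(empty$mirnas) + length(empty$genes), 0)
  # star graph: degree sum equals edge count
  star <- build_network(data.frame(mirna = "hub",
                                   gene = sprintf("g%d", 1:7)))
  r <- mirna_degree_ranking(star)
  expect_equal(r$degree, 7)
  expect_equal(sum(r$degree), nrow(star$edges))
  expect_equal(attr(r, "n_active"), 1)
  expect_equal(nrow(mirna_degree_ranking(empty)), 0)
})

test_that("fixture: let-7c tops the ranking with out-degree 3", {
  fn <- fixture_net()
  r <- mirna_degree_ranking(fn$net)
  expect_equal(r$mirna[1], "hsa-let-7c-5p")
  expect_equal(r$degree[1], 3)
  expect_equal(sum(r$degree), nrow(fn$net$edges))
})

test_that("regulator classes partition genes as reported", {
  fn <- fixture_net()
  cl <- classify_genes_by_regulators(fn$net, fn$fx$down_mirnas,
                                     fn$fx$up_mirnas)
  expect_equal(sort(names(cl)[cl == "down_only"]),
               c("FASLG", "GZMB", "PRF1", "TNFSF10"))
  expect_equal(sort(names(cl)[cl == "mixed"]),
               c("CD40LG", "OSM", "TNF"))
  # no-edge gene is none; permutation of edges leaves classes unchanged
  net2 <- build_network(fn$net$edges[sample(nrow(fn$net$edges)), ])
  expect_identical(classify_genes_by_regulators(net2, fn$fx$down_mirnas,
                                                fn$fx$up_mirnas), cl)
  iso <- build_network(fn$net$edges, declared_genes = "LONELY",
                       keep_isolates = TRUE)
  cli <- classify_genes_by_regulators(iso, fn$fx$down_mirnas,
                                      fn$fx$up_mirnas)
  expect_equal(unname(cli["LONELY"]), "none")
})

test_that("SIF export writes 'targets' relations and round-trips", {
  fx <- cytotox_fixture()
  net <- build_network(filter_mti(fx$mti, "hsa-let-7c-5p",
                                  c("FASLG", "TNFSF10", "OSM")))
  p <- withr::local_tempfile(fileext = ".sif")
  export_network(net, p, "sif")
  lines <- readLines(p)
  expect_equal(length(lines), 3)
  expect_true(all(grepl("^hsa-let-7c-5p\ttargets\t", lines)))
  back <- import_network(p, "sif")
  expect_setequal(back$nodes, c(net$mirnas, net$genes))
  expect_equal(nrow(back$edges), 3)
})

test_that("GraphML export round-trips nodes, types and edges", {
  fn <- fixture_net()
  p <- withr::local_tempfile(fileext = ".graphml")
  export_network(fn$net, p, "graphml")
  back <- import_network(p, "graphml")
  expect_setequal(back$mirnas, fn$net$mirnas)
  expect_setequal(back$genes, fn$net$genes)
  expect_equal(nrow(back$edges), nrow(fn$net$edges))
  key <- function(e) sort(paste(e$mirna, e$gene))
  expect_equal(key(back$edges), key(fn$net$edges))
  # empty network still writes a valid document
  empty <- build_network(data.frame(mirna = character(0),
                                    gene = character(0)))
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, p2, "graphml")
  expect_equal(nrow(import_network(p2, "graphml")$edges), 0)
  expect_error(export_network(empty, p2, "dot"),
               class = "cikmir_usage_error")
})
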
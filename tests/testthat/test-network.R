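toy_net <- function() {
  edges <- data.frame(gene_a = c("a", "a", "b"),
                      gene_b = c("b", "c", "d"),
                      r = c(0.9, 0.8, 0.7), z = c(3, 2.5, 2.2),
                      stringsAsFactors = FALSE)
  build_network(edges,
                ts_genes = c("a", "b"), de_genes = c("a", "d"),
                tf_genes = "c", snp_genes = "e",
                tissue_of = c(a = "liver", b = "liver", c = "muscle",
                              d = "muscle", e = "liver"))
}

test_that("network assembly keeps non-exclusive class flags", {
  net <- toy_net()
  expect_equal(nrow(net$nodes), 5)
  a <- net$nodes[net$nodes$gene == "a", ]
  expect_true(a$is_ts && a$is_de && !a$is_tf)
  # empty edge list preserves the nodes
  empty <- build_network(toy_net()$edges[0, ], "a", "b", "c", "d",
                         tissue_of = c(a = "x", b = "x", c = "x", d = "x"))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 4)
  # offending endpoints are reported
  bad <- data.frame(gene_a = "a", gene_b = "zz", r = 1, z = 3)
  expect_error(build_network(bad, "a", "b", "c", "d",
                             tissue_of = c(a = "x", b = "x", c = "x",
                                           d = "x")), "zz")
  expect_error(build_network(toy_net()$edges[0, ], "a", "b", "c", "d",
                             tissue_of = c(a = "x")), "missing tissue")
})

test_that("degree table ranks with stable ties and sums correctly", {
  net <- toy_net()
  deg <- degree_table(net)
  expect_equal(sum(deg$degree), 2 * nrow(net$edges))
  expect_equal(deg$degree[deg$gene == "a"], 2)
  expect_equal(deg$degree[deg$gene == "e"], 0)  # isolated node
  # ties broken by gene id
  tied <- deg$gene[deg$degree == 1]
  expect_identical(tied, sort(tied))
  # star: center has degree n - 1
  star <- build_network(
    data.frame(gene_a = "hub", gene_b = paste0("l", 1:4),
               r = 1, z = 3),
    ts_genes = paste0("l", 1:4), de_genes = character(0),
    tf_genes = "hub", snp_genes = character(0),
    tissue_of = setNames(rep("x", 5), c("hub", paste0("l", 1:4))))
  dstar <- degree_table(star)
  expect_equal(dstar$degree[dstar$gene == "hub"], 4)
  expect_true(all(dstar$degree[dstar$gene != "hub"] == 1))
})

test_that("tissue edge summary computes fractions and R^2", {
  net <- toy_net()
  s <- tissue_edge_summary(net)
  # a-b within liver; a-c and b-d cross
  expect_equal(s$within_fraction, 1 / 3)
  expect_equal(sum(s$per_tissue$edges_within), 1)
  # all-within and bipartite extremes
  allw <- build_network(data.frame(gene_a = "a", gene_b = "b", r = 1,
                                   z = 3),
                        "a", "b", character(0), character(0),
                        tissue_of = c(a = "x", b = "x"))
  expect_equal(tissue_edge_summary(allw)$within_fraction, 1)
  bip <- build_network(data.frame(gene_a = c("a", "a"),
                                  gene_b = c("b", "c"), r = 1, z = 3),
                       c("a", "b", "c"), character(0), character(0),
                       character(0),
                       tissue_of = c(a = "x", b = "y", c = "y"))
  expect_equal(tissue_edge_summary(bip)$within_fraction, 0)
  # relabeling nodes does not change the fraction
  net2 <- toy_net()
  map <- c(a = "n1", b = "n2", c = "n3", d = "n4", e = "n5")
  net2$nodes$gene <- unname(map[net2$nodes$gene])
  net2$edges$gene_a <- unname(map[net2$edges$gene_a])
  net2$edges$gene_b <- unname(map[net2$edges$gene_b])
  expect_equal(tissue_edge_summary(net2)$within_fraction,
               s$within_fraction)
})

test_that("TF subnetwork keeps TF-incident structure only", {
  net <- toy_net()
  sub <- extract_tf_subnetwork(net)
  # only edge a-c touches the TF "c"
  expect_equal(nrow(sub$edges), 1)
  expect_setequal(sub$nodes$gene, c("a", "c"))
  expect_lte(nrow(sub$edges),
             2 * sum(degree_table(net)$degree[degree_table(net)$is_tf]))
  # star centred on a TF is returned unchanged
  star <- build_network(
    data.frame(gene_a = "hub", gene_b = paste0("l", 1:3), r = 1, z = 3),
    ts_genes = paste0("l", 1:3), de_genes = character(0),
    tf_genes = "hub", snp_genes = character(0),
    tissue_of = setNames(rep("x", 4), c("hub", paste0("l", 1:3))))
  expect_equal(nrow(extract_tf_subnetwork(star)$edges), 3)
  # no TFs -> empty, with warning
  notf <- build_network(data.frame(gene_a = "a", gene_b = "b", r = 1,
                                   z = 3),
                        c("a", "b"), character(0), character(0),
                        character(0), tissue_of = c(a = "x", b = "x"))
  expect_warning(sub0 <- extract_tf_subnetwork(notf), "no TF")
  expect_equal(nrow(sub0$edges), 0)
})

test_that("enrichment p-values match the hypergeometric closed form", {
  uni <- paste0("g", 1:20)
  terms <- list(T1 = paste0("g", 1:5), T2 = paste0("g", 6:20))
  res <- fisher_enrichment(paste0("g", 1:5), uni, terms)
  expect_equal(res$p[res$term == "T1"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # set = universe gives p = 1 for every term
  res2 <- fisher_enrichment(uni, uni, terms)
  expect_true(all(res2$p == 1))
  # term absent from the set
  res3 <- fisher_enrichment(paste0("g", 1:5), uni,
                            list(T3 = paste0("g", 11:20)))
  expect_equal(res3$k, 0)
  expect_equal(res3$p, 1, tolerance = 1e-12)
  expect_error(fisher_enrichment("g1", character(0), terms), "empty")
  expect_error(fisher_enrichment("zz", uni, terms), "subset")
  # random tables against the summation oracle
  set.seed(4)
  for (i in 1:25) {
    N <- sample(5:50, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    uni <- paste0("g", seq_len(N))
    gs <- sample(uni, n)
    tm <- list(T = sample(uni, K))
    p <- fisher_enrichment(gs, uni, tm)$p
    expect_equal(p, hyper_tail(length(intersect(gs, tm$T)), K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("exports round-trip and count correctly", {
  net <- toy_net()
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 3)
  tsv <- file.path(dir, "net.tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_tsv(tsv)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
  gml <- file.path(dir, "net.graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 3)
  expect_error(export_network(net, file.path(dir, "x"), "xml"))
  # empty network still exports valid files
  empty <- build_network(net$edges[0, ], "a", "b", "c", "d",
                         tissue_of = c(a = "x", b = "x", c = "x",
                                       d = "x"))
  export_network(empty, sif, "sif")
  expect_length(readLines(sif), 0)
})
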
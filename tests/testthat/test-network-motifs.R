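test_that("thresholding is inclusive at the cut and keeps isolated nodes", {
  edges <- data.frame(
    node_a = c("t1", "t1", "m1"), node_b = c("m1", "pp1", "pp1"),
    modality_a = c("T", "T", "M"), modality_b = c("M", "PP", "PP"),
    n_obs = 57L, log10_bf = c(0.499, 0.5, 1.2), rho = c(0.3, -0.4, 0.5),
    stringsAsFactors = FALSE)
  net <- build_network(edges, 0.5)
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$log10_bf >= 0.5))
  expect_equal(nrow(net$nodes), 3L)  # t1 kept although its T-M edge fell
  net_all <- build_network(edges, -Inf)
  expect_equal(nrow(net_all$edges), 3L)
  expect_error(build_network(rbind(edges, edges[1L, ]), 0.5), "duplicate")
})

test_that("the published fatigue edge set yields exactly four motifs", {
  res <- suppressWarnings(run_from_table2())
  m <- res$motifs$WEIMuS
  expect_equal(nrow(m), 4L)
  expect_equal(
    m[, c("taxon", "module")],
    data.frame(
      taxon = c("Anaerotruncus", "Clostridiales_gis", "Eubacterium",
                "Intestinimonas"),
      module = c("pentose_phosphate_pathway", "pentose_phosphate_pathway",
                 "pentose_phosphate_pathway", "methionine_biosynthesis"),
      stringsAsFactors = FALSE))
  # all edges of every motif satisfy the threshold
  expect_true(all(motif_table(m)$log10_bf >= 0.5))
})

test_that("enumeration requires a PP node and handles empty cases", {
  edges <- random_tripartite_edges(5L, 5L, 2L, p_edge = 0.4, seed = 3L)
  net <- build_network(dedup_edges(edges), 0.5)
  expect_error(enumerate_tripartite_triangles(net, "nope"), "not in the")
  expect_error(enumerate_tripartite_triangles(net, "t01"), "modality PP")
  # a network whose PP nodes have no edges has no motifs
  e2 <- edges[edges$modality_b != "PP" & edges$modality_a != "PP", ]
  e2 <- rbind(e2, data.frame(node_a = "t01", node_b = "pp1",
                             modality_a = "T", modality_b = "PP",
                             n_obs = 57L, log10_bf = 0.1, rho = 0.1))
  net2 <- build_network(dedup_edges(e2), 0.5)
  expect_equal(nrow(enumerate_tripartite_triangles(net2, "pp1")), 0L)
})

test_that("enumeration matches brute force on random tripartite graphs", {
  for (seed in 1:50) {
    set.seed(seed)
    n_t <- sample(3:40, 1L); n_m <- sample(3:55, 1L)
    edges <- random_tripartite_edges(n_t, n_m, 2L,
                                     p_edge = runif(1, 0.1, 0.5),
                                     seed = seed)
    net <- build_network(edges, 0.5)
    for (pp in c("pp1", "pp2")) {
      if (!pp %in% net$nodes$id) next
      got <- enumerate_tripartite_triangles(net, pp)
      want <- brute_force_triangles(net, pp)
      expect_identical(got[, c("taxon", "module")],
                       want[, c("taxon", "module")])
    }
  }
})

test_that("raising the threshold never increases the motif count", {
  edges <- random_tripartite_edges(20L, 30L, 2L, p_edge = 0.35, seed = 7L)
  counts <- vapply(c(-Inf, 0, 0.25, 0.5, 0.75, 1.0, 1.4), function(th) {
    net <- build_network(edges, th)
    sum(vapply(c("pp1", "pp2"), function(pp)
      if (pp %in% net$nodes$id)
        nrow(enumerate_tripartite_triangles(net, pp)) else 0L,
      integer(1L)))
  }, integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("motif tables and summaries report the published cardinalities", {
  res <- suppressWarnings(run_from_table2())
  tab_f <- motif_table(res$motifs$WEIMuS)
  expect_equal(nrow(tab_f), 12L)  # three rows per motif
  expect_setequal(unique(tab_f$pair), c("taxon-module", "taxon-pp",
                                        "module-pp"))
  sm <- res$summary
  expect_equal(sm[sm$pp == "WEIMuS", c("n_motifs", "n_taxa", "n_modules")],
               data.frame(n_motifs = 4L, n_taxa = 4L, n_modules = 2L),
               ignore_attr = TRUE)
  expect_equal(sm[sm$pp == "HADS_D", c("n_taxa", "n_modules")],
               data.frame(n_taxa = 3L, n_modules = 3L), ignore_attr = TRUE)
  # direction signs are recorded per motif
  expect_true(all(grepl("^[+-] [+-] [+-]$",
                        res$motifs$HADS_D$direction_pattern)))
  empty <- summarize_motifs(res$motifs$WEIMuS[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(empty$n_motifs), 0)
})

test_that("conflicting duplicate edges keep the maximum with a warning", {
  expect_warning(res <- run_from_table2(), "conflicting duplicate")
  dh <- res$edges[res$edges$node_a == "dermatan_sulfate_degradation" &
                    res$edges$node_b == "HADS_D", ]
  expect_equal(dh$log10_bf, 0.666)
  # identical duplicates collapse silently
  e <- random_tripartite_edges(4L, 4L, 1L, p_edge = 0.5, seed = 9L)
  expect_silent(d <- dedup_edges(rbind(e, e[1L, ])))
  expect_equal(nrow(d), nrow(e))
})

test_that("screened edges yield the same motifs as the full joint matrix", {
  set.seed(31)
  n <- 40L
  ids <- sprintf("s%02d", 1:n)
  z <- rnorm(n)
  taxa <- matrix(rnorm(n * 6), n, 6, dimnames = list(ids, paste0("t", 1:6)))
  mods <- matrix(rnorm(n * 8), n, 8, dimnames = list(ids, paste0("m", 1:8)))
  taxa[, 1] <- taxa[, 1] + 1.2 * z
  mods[, 1] <- mods[, 1] + 1.2 * z
  pp <- cbind(score = 10 + 4 * z + rnorm(n))
  rownames(pp) <- ids
  full <- joint_edge_matrix(list(node_block(taxa, "T"),
                                 node_block(mods, "M"),
                                 node_block(pp, "PP")))
  screened <- screen_motif_edges(node_block(taxa, "T"),
                                 node_block(mods, "M"), pp)
  mot_full <- enumerate_tripartite_triangles(build_network(full, 0.5),
                                             "score")
  mot_scr <- enumerate_tripartite_triangles(build_network(screened, 0.5),
                                            "score")
  expect_identical(mot_full[, c("taxon", "module")],
                   mot_scr[, c("taxon", "module")])
  expect_equal(mot_full$log10_bf_tm, mot_scr$log10_bf_tm, tolerance = 1e-10)
  expect_gt(nrow(mot_full), 0L)
})

test_that("networks export to igraph and GraphML", {
  res <- suppressWarnings(run_from_table2())
  g <- as_igraph(res$network)
  expect_equal(igraph::vcount(g), nrow(res$network$nodes))
  expect_equal(igraph::ecount(g), nrow(res$network$edges))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(res$network, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
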
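test_that("CV ranking equals the hand-computed sd/mean ordering", {
  sheet <- toy_sheet(c("hydrated", "RWC60"), 2)
  expr <- rbind(a = c(1, 1, 1, 1), b = c(1, 5, 9, 13), c = c(10, 10.1, 9.9, 10),
                d = c(2, 6, 2, 6), e = c(100, 101, 99, 100))
  colnames(expr) <- sheet$sample_id
  rk <- rank_by_cv(expr, sheet, "root")
  hand_cv <- apply(expr, 1, function(x) sd(x) / abs(mean(x)))
  expect_equal(rk$cv, unname(sort(hand_cv, decreasing = TRUE)))
  expect_identical(rk$gene, names(sort(hand_cv, decreasing = TRUE)))
  # constant gene: cv = 0, ranked last
  expect_identical(rk$gene[nrow(rk)], "a")
  expect_identical(rk$cv[nrow(rk)], 0)
  expect_identical(rk$rank, seq_len(5L))
})

test_that("CV is invariant to positive scaling of a gene", {
  sheet <- toy_sheet("hydrated", 6)
  expr <- noise_matrix(4, 6, 31) + 10
  colnames(expr) <- sheet$sample_id
  cv1 <- rank_by_cv(expr, sheet, "root")
  expr["g002", ] <- expr["g002", ] * 7.3
  cv2 <- rank_by_cv(expr, sheet, "root")
  expect_equal(cv1$cv[cv1$gene == "g002"], cv2$cv[cv2$gene == "g002"],
               tolerance = 1e-12)
})

test_that("near-zero-mean genes are excluded from CV ranking", {
  sheet <- toy_sheet("hydrated", 4)
  expr <- noise_matrix(3, 4, 5) + 10
  expr["g001", ] <- c(-1, 1, -1, 1) * 1e-10
  colnames(expr) <- sheet$sample_id
  expect_warning(rk <- rank_by_cv(expr, sheet, "root"), "excluded")
  expect_false("g001" %in% rk$gene)
  expect_error(rank_by_cv(expr[, 1:2], sheet[1:2, ], "root"), ">= 3")
})

test_that("top-k selection keeps the k largest CVs deterministically", {
  rk <- data.frame(gene = c("gB", "gC", "gA", "gD"),
                   cv = c(3, 2, 2, 1), rank = 1:4)
  expect_identical(select_top_k(rk, 2), c("gB", "gC"))
  expect_warning(all_genes <- select_top_k(rk, 10), "returning all")
  expect_identical(all_genes, rk$gene)
  # ties resolved lexicographically by the ranking itself
  sheet <- toy_sheet("hydrated", 4)
  expr <- rbind(gZ = c(1, 2, 3, 4), gA = c(1, 2, 3, 4), gM = c(5, 5, 5, 6))
  colnames(expr) <- sheet$sample_id
  rk2 <- rank_by_cv(expr, sheet, "root")
  expect_identical(select_top_k(rk2, 1), "gA")  # gA before gZ at equal cv
})

test_that("all-pairs Pearson matches the raw-sum formula to 1e-12", {
  m <- noise_matrix(20, 12, 77)
  cc <- pearson_all_pairs(m)
  for (i in 1:19) for (j in (i + 1):20)
    expect_equal(cc[i, j], pearson_raw(m[i, ], m[j, ]), tolerance = 1e-12)
  expect_true(all(abs(cc) <= 1 + 1e-12))
})

test_that("exact copies and negations give r of +1 and -1", {
  m <- noise_matrix(1, 10, 3)
  m <- rbind(m, copy = m[1, ], neg = 2 * mean(m[1, ]) - m[1, ])
  cc <- pearson_all_pairs(m)
  expect_equal(cc["g001", "copy"], 1, tolerance = 1e-12)
  expect_equal(cc["g001", "neg"], -1, tolerance = 1e-12)
})

test_that("constant genes are caught before correlation", {
  m <- noise_matrix(3, 5, 4)
  m["g002", ] <- 7
  expect_error(pearson_all_pairs(m), "g002")
  expect_message(kept <- drop_constant_genes(m), "1 constant")
  expect_identical(rownames(kept), c("g001", "g003"))
  expect_error(pearson_all_pairs(m[, 1:2]), ">= 3 samples")
})

test_that("thresholding is strict and produces exactly the passing pairs", {
  m <- noise_matrix(6, 8, 12)
  cc <- pearson_all_pairs(m)
  r12 <- cc[1, 2]
  # a pair sitting exactly at the threshold is NOT an edge
  net <- build_network(cc, threshold = abs(r12))
  expect_false(any(net$edges$gene_a == "g001" & net$edges$gene_b == "g002"))
  # three mutually perfect genes form a triangle
  tri <- rbind(a = 1:6, b = 2 * (1:6) + 3, c = -(1:6))
  net3 <- build_network(pearson_all_pairs(tri), threshold = 0.964)
  expect_identical(nrow(net3$edges), 3L)
  expect_setequal(net3$nodes, c("a", "b", "c"))
  expect_error(build_network(cc, threshold = 1.5), "threshold")
})

test_that("build_network equals the brute-force edge set on random data", {
  set.seed(55)
  for (i in 1:10) {
    n_g <- sample(5:15, 1); n_s <- sample(4:10, 1)
    thr <- runif(1, 0.2, 0.9)
    m <- noise_matrix(n_g, n_s, 300 + i)
    net <- build_network(pearson_all_pairs(m), threshold = thr)
    oracle <- brute_edge_set(m, thr)
    expect_identical(net$edges[, c("gene_a", "gene_b")],
                     oracle[, c("gene_a", "gene_b")])
    expect_equal(net$edges$r, oracle$r, tolerance = 1e-10)
  }
})

test_that("edge sets are nested as the threshold rises", {
  m <- noise_matrix(15, 6, 91)
  cc <- pearson_all_pairs(m)
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  thresholds <- c(0.2, 0.4, 0.6, 0.8, 0.964)
  nets <- lapply(thresholds, function(t) build_network(cc, t))
  for (i in seq_along(nets)[-1])
    expect_true(all(key(nets[[i]]) %in% key(nets[[i - 1]])))
})

test_that("a tissue's network ignores the other tissue's samples", {
  cfg <- sim_config(n_genes = 80, seed = 44,
                    modules = list(module_spec(10, "root", "RWC40", "down")))
  sim <- simulate_expression(cfg)
  net1 <- tissue_network(sim$expression, sim$samples, "root", top_k = 80,
                         threshold = 0.9)
  shoot_ids <- sim$samples$sample_id[sim$samples$tissue == "shoot"]
  perm <- sim$expression
  perm[, shoot_ids] <- perm[, sample(shoot_ids)]
  net2 <- suppressWarnings(
    tissue_network(perm, sim$samples, "root", top_k = 80, threshold = 0.9))
  expect_identical(net1$edges, net2$edges)
  expect_identical(net1$nodes, net2$nodes)
})

test_that("a planted module is recovered as a dense subnetwork", {
  cfg <- sim_config(n_genes = 60, module_corr = 0.99, seed = 7,
                    modules = list(module_spec(10, "root", character(0),
                                               "up")))
  sim <- simulate_expression(cfg)
  net <- tissue_network(sim$expression, sim$samples, "root", top_k = 60)
  mod <- names(sim$truth$module_truth)[!is.na(sim$truth$module_truth)]
  within <- net$edges$gene_a %in% mod & net$edges$gene_b %in% mod
  expect_gte(sum(within) / choose(10, 2), 0.9)
  expect_identical(sum(!within), 0L)  # no noise edges at 0.964
})

test_that("state overlays color nodes by their DEG call", {
  net <- structure(list(tissue = "root", nodes = c("g1", "g2", "g3"),
                        edges = data.frame(gene_a = "g1", gene_b = "g2",
                                           r = 0.99),
                        threshold = 0.964), class = "coex_network")
  degs <- data.frame(
    gene = c("g1", "g2", "g3", "g1"), tissue = "root",
    state = c("RWC40", "RWC40", "RWC40", "RWC60"),
    log2fc = c(-2, 3, 0.1, 0), p_adj = c(0.01, 0.001, 0.9, 0.7))
  degs <- filter_degs(degs)
  ov <- overlay_deg_states(net, degs)
  expect_identical(unname(ov$RWC40[c("g1", "g2", "g3")]),
                   c("down", "up", "unchanged"))
  expect_true(all(ov$RWC60 == "unchanged"))  # nothing passes there
  expect_error(overlay_deg_states(net, transform(degs, tissue = "shoot")),
               "tissue")
})

test_that("state summaries match hand enumeration on a 6-node network", {
  # nodes n1..n6; edges: n1-n2, n2-n3, n4-n5, n5-n6, n1-n6
  net <- structure(list(
    tissue = "root", nodes = sprintf("n%d", 1:6),
    edges = data.frame(gene_a = c("n1", "n2", "n4", "n5", "n1"),
                       gene_b = c("n2", "n3", "n5", "n6", "n6"),
                       r = c(0.99, 0.98, -0.97, 0.99, 0.995)),
    threshold = 0.964), class = "coex_network")
  ov <- structure(list(RWC40 = c(n1 = "up", n2 = "up", n3 = "unchanged",
                                 n4 = "down", n5 = "down", n6 = "down"),
                       RWC10 = setNames(rep("unchanged", 6),
                                        sprintf("n%d", 1:6))),
                  class = "state_overlay", tissue = "root")
  s <- summarize_states(net, ov)
  r40 <- s$per_state[s$per_state$state == "RWC40", ]
  expect_identical(r40$n_up, 2L)
  expect_identical(r40$n_down, 3L)
  # active edges: n1-n2 (up/up), n4-n5, n5-n6 (down/down); n1-n6 mixed
  expect_identical(r40$n_active_edges, 3L)
  # components of active subgraph: {n1,n2}, {n4,n5,n6}
  expect_identical(r40$n_components_active, 2L)
  r10 <- s$per_state[s$per_state$state == "RWC10", ]
  expect_identical(r10$n_up + r10$n_down + r10$n_active_edges, 0L)
  expect_identical(s$jaccard["RWC40", "RWC40"], 1)
  expect_identical(s$jaccard["RWC40", "RWC10"], 0)
  expect_equal(s$jaccard, t(s$jaccard))
})

test_that("identical active sets give Jaccard 1", {
  net <- structure(list(tissue = "root", nodes = c("a", "b"),
                        edges = data.frame(gene_a = "a", gene_b = "b",
                                           r = 0.99),
                        threshold = 0.964), class = "coex_network")
  ov <- structure(list(s1 = c(a = "up", b = "down"),
                       s2 = c(a = "up", b = "down")),
                  class = "state_overlay", tissue = "root")
  s <- summarize_states(net, ov)
  expect_identical(s$jaccard["s1", "s2"], 1)
})

test_that("networks round-trip through GraphML and the edge list", {
  m <- noise_matrix(12, 10, 19)
  net <- build_network(pearson_all_pairs(m), threshold = 0.3,
                       tissue = "shoot")
  expect_gt(nrow(net$edges), 0)
  degs <- data.frame(gene = net$nodes[1], tissue = "shoot", state = "RWC40",
                     log2fc = 2, p_adj = 0.001)
  ov <- overlay_deg_states(net, filter_degs(degs))
  dir <- withr::local_tempdir()
  paths <- export_network(net, ov, file.path(dir, "net"))
  back <- read_network(paths[["graphml"]])
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$tissue, "shoot")
  expect_equal(back$threshold, net$threshold)
  expect_identical(back$edges[, 1:2], net$edges[, 1:2])
  expect_equal(back$edges$r, net$edges$r, tolerance = 1e-9)
  # edge list has one row per edge
  el <- read.delim(paths[["edges"]])
  expect_identical(nrow(el), nrow(net$edges))
})

test_that("an empty network still exports valid GraphML", {
  net <- build_network(matrix(0, 0, 0), threshold = 0.964)
  dir <- withr::local_tempdir()
  paths <- export_network(net, NULL, file.path(dir, "empty"))
  back <- read_network(paths[["graphml"]])
  expect_identical(length(back$nodes), 0L)
  expect_identical(nrow(back$edges), 0L)
})
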
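make_norm <- function(mat) {
  rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  mat
}

test_that("core network edges follow the positive-correlation rule", {
  base <- c(1, 2, 3, 4, 5)
  m <- make_norm(rbind(base, 2 * base, rev(base), c(1, 1, 1, 1, 1)))
  net <- build_core_network(m, rownames(m), colnames(m), min_abs_corr = 0.8)
  pairs <- paste(net$edges$from, net$edges$to)
  expect_true("g01 g02" %in% pairs)       # proportional profiles: r = 1
  expect_false(any(grepl("g03", pairs)))  # anti-correlated: positive-only rule
  expect_false(any(grepl("g04", pairs)))  # constant gene is isolated
  expect_true(net$nodes$constant[net$nodes$gene_id == "g04"])
  expect_error(build_core_network(m, rownames(m), colnames(m)[1:2]),
               "3 samples")
})

test_that("core edges equal a brute-force pairwise correlation oracle", {
  set.seed(15)
  m <- make_norm(matrix(rexp(300), 30, 10))
  thr <- 0.5
  net <- build_core_network(m, rownames(m), colnames(m), min_abs_corr = thr)
  oracle <- character(0)
  for (i in 1:29) for (j in (i + 1):30) {
    r <- cor(m[i, ], m[j, ])
    if (!is.na(r) && r >= thr && r > 0)
      oracle <- c(oracle, paste(rownames(m)[i], rownames(m)[j]))
  }
  expect_setequal(paste(net$edges$from, net$edges$to), oracle)
})

test_that("non-core subnetworks use phi on binary profiles within scope", {
  samples <- sprintf("s%02d", 1:8)
  bin <- rbind(g01 = c(1, 1, 1, 1, 0, 0, 0, 0),
               g02 = c(1, 1, 1, 1, 0, 0, 0, 0),  # identical: phi = 1
               g03 = c(0, 0, 0, 0, 1, 1, 1, 1),  # complement: phi = -1
               g04 = rep(1, 8),                  # all-present: isolated
               g05 = c(1, 0, 1, 0, 1, 0, 1, 0))
  colnames(bin) <- samples
  ann <- data.frame(gene_id = rownames(bin), family = "f", category = "Respiration",
                    pathway_group = "Carbon", stringsAsFactors = FALSE)
  net <- build_noncore_subnetwork(bin, ann, "Carbon", samples, min_abs_corr = 0.8)
  pairs <- paste(net$edges$from, net$edges$to)
  expect_true("g01 g02" %in% pairs)
  expect_false(any(grepl("g03", pairs)))
  expect_false(any(grepl("g04", pairs)))
  expect_error(build_noncore_subnetwork(bin, ann, "Lipids", samples), "unknown")
  ann2 <- ann; ann2$pathway_group <- "AA"
  expect_error(build_noncore_subnetwork(bin, ann2, "Carbon", samples),
               "no non-core genes")
})

test_that("phi scores match the 2x2 contingency-table formula", {
  set.seed(88)
  samples <- sprintf("s%02d", 1:10)
  bin <- matrix(rbinom(200, 1, 0.5), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), samples))
  ann <- data.frame(gene_id = rownames(bin), family = "f",
                    category = "Nitrogen Metabolism", pathway_group = "Nitrogen",
                    stringsAsFactors = FALSE)
  thr <- 0.3
  net <- build_noncore_subnetwork(bin, ann, "Nitrogen", samples, min_abs_corr = thr)
  phi22 <- function(x, y) {
    n11 <- sum(x & y); n10 <- sum(x & !y); n01 <- sum(!x & y); n00 <- sum(!x & !y)
    den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
    if (den == 0) return(NA_real_)
    (n11 * n00 - n10 * n01) / den
  }
  oracle <- character(0)
  for (i in 1:19) for (j in (i + 1):20) {
    p <- phi22(bin[i, ] == 1, bin[j, ] == 1)
    if (!is.na(p) && p >= thr) oracle <- c(oracle, paste(rownames(bin)[i],
                                                         rownames(bin)[j]))
  }
  expect_setequal(paste(net$edges$from, net$edges$to), oracle)
  # scores themselves agree with the contingency formula
  for (k in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$score[k],
                 phi22(bin[net$edges$from[k], ] == 1, bin[net$edges$to[k], ] == 1),
                 tolerance = 1e-12)
  }
})

test_that("modules are connected components with deterministic ids", {
  edges <- data.frame(from = c("a", "b", "c", "x", "y", "z", "p", "q"),
                      to   = c("b", "c", "a", "y", "z", "x", "q", "r"),
                      score = 1, stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = c(letters[1:3], "x", "y", "z", "p", "q", "r", "iso"),
                      kind = "noncore", category = NA_character_,
                      constant = FALSE, stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, modules = NULL,
                        group = "H", pathway_scope = NA, min_abs_corr = 0.8),
                   class = "copresence_network")
  net <- detect_modules(net)
  mods <- net$modules
  expect_length(unique(mods), 3)
  expect_false("iso" %in% names(mods))     # isolated node gets no module
  # two triangles and one path; sizes 3,3,3 -> ties broken by smallest gene id
  expect_equal(unname(mods["a"]), 1L)      # {a,b,c} beats {p,q,r} and {x,y,z}
  expect_equal(unname(mods["p"]), 2L)
  expect_equal(unname(mods["x"]), 3L)
  expect_equal(length(unique(mods[c("a", "b", "c")])), 1)

  s <- summarize_network(net)
  expect_equal(s$n_modules, 3)
  expect_equal(s$largest_module_nodes, 3)
  expect_equal(s$largest_module_edges, 3)  # triangle
})

test_that("components agree with a breadth-first-search oracle", {
  set.seed(19)
  m <- make_norm(matrix(rexp(125), 25, 5))
  net <- detect_modules(build_core_network(m, rownames(m), colnames(m),
                                           min_abs_corr = 0.6))
  linked <- sort(unique(c(net$edges$from, net$edges$to)))
  oracle <- bfs_components(linked, net$edges)
  # same partition: gene pairs share a module iff they share a BFS component
  for (i in seq_along(linked)) for (j in seq_len(i - 1)) {
    expect_equal(net$modules[[linked[i]]] == net$modules[[linked[j]]],
                 oracle[[linked[i]]] == oracle[[linked[j]]])
  }
})

test_that("raising the threshold never increases the edge count", {
  set.seed(7)
  m <- make_norm(matrix(rexp(200), 20, 10))
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
    nrow(build_core_network(m, rownames(m), colnames(m), min_abs_corr = thr)$edges),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summaries are invariant to gene input order", {
  set.seed(25)
  m <- make_norm(matrix(rexp(150), 15, 10))
  s1 <- summarize_network(build_core_network(m, rownames(m), colnames(m), min_abs_corr = 0.5))
  perm <- sample(nrow(m))
  s2 <- summarize_network(build_core_network(m[perm, ], rownames(m)[perm],
                                             colnames(m), min_abs_corr = 0.5))
  expect_equal(s1$n_modules, s2$n_modules)
  expect_equal(s1$n_edges, s2$n_edges)
  expect_equal(sort(s1$module_sizes), sort(s2$module_sizes))
})

test_that("an empty edge set yields zero modules", {
  m <- make_norm(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  net <- detect_modules(build_core_network(m, rownames(m), colnames(m),
                                           min_abs_corr = 0.99))
  s <- summarize_network(net)
  expect_equal(s$n_modules, 0)
  expect_equal(s$largest_module_nodes, 0)
})

test_that("planted co-presence blocks land in a single module at zero noise", {
  cfg <- sim_config(n_samples_per_group = 8, n_genes = 500,
                    copresence_blocks = data.frame(group = "H", pathway = "AA",
                                                   size = 12L),
                    block_on = 1, block_off = 0, seed = 20)
  res <- simulate_dataset(cfg)
  prof <- detection_profile(res$dataset)
  grp <- sample_groups(res$dataset)
  hs <- names(grp)[grp == "H"]
  block <- res$truth$block_genes_by_group$H[[1]]
  net <- detect_modules(build_noncore_subnetwork(
    prof$noncore_binary, res$dataset$annotation, "AA", hs, min_abs_corr = 0.99))
  block_in <- intersect(block, names(net$modules))
  expect_gte(length(block_in), 10)
  expect_length(unique(net$modules[block_in]), 1)
})

test_that("module overlap is reported relative to the smaller module", {
  edges_a <- data.frame(from = c("a", "b"), to = c("b", "c"), score = 1)
  edges_b <- data.frame(from = c("b", "c"), to = c("c", "d"), score = 1)
  mk <- function(e) detect_modules(structure(
    list(nodes = data.frame(gene_id = unique(c(e$from, e$to)), kind = "core",
                            category = NA, constant = FALSE),
         edges = e, modules = NULL, group = "H", pathway_scope = NA,
         min_abs_corr = 0.8), class = "copresence_network"))
  ov <- module_overlap(mk(edges_a), mk(edges_b))
  expect_equal(ov$n_shared, 2)   # {a,b,c} vs {b,c,d}
  expect_equal(ov$percentage_of_smaller, round(100 * 2 / 3, 1))
})
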
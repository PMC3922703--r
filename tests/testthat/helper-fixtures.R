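# Programmatic fixtures shared across test files.

# Detection matrix with named genes/samples from a 0/1 template.
make_detected <- function(mat, genes = NULL, samples = NULL) {
  mat <- as.matrix(mat)
  rownames(mat) <- genes %||% sprintf("g%02d", seq_len(nrow(mat)))
  colnames(mat) <- samples %||% sprintf("s%02d", seq_len(ncol(mat)))
  mat > 0
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Small noise-free simulation config: every non-core presence is 0/1-sharp
# so planted structure is exactly recoverable.
zero_noise_config <- function(...) {
  sim_config(n_samples_per_group = 6, n_genes = 60, core_fraction = 0.5,
             noncore_presence_baseline = 0.5, noncore_presence_conc = 200,
             group_effect = 0, n_exclusive_per_group = 0,
             n_planted_triplets_per_group = 0,
             copresence_blocks = data.frame(group = character(0),
                                            pathway = character(0),
                                            size = integer(0)),
             ...)
}

# Binary non-core profile with one perfectly discriminative triplet per
# group over a 0.5-presence noise background (10 + 10 samples).
make_planted_binary <- function(seed, n_background = 494) {
  set.seed(seed)
  samples <- c(sprintf("H%02d", 1:10), sprintf("C%02d", 1:10))
  groups <- stats::setNames(rep(c("H", "C"), each = 10), samples)
  bg <- matrix(rbinom(n_background * 20, 1, 0.5), n_background, 20,
               dimnames = list(sprintf("bg_%03d", seq_len(n_background)), samples))
  h_mark <- matrix(rep(c(1L, 0L), each = 10), 3, 20, byrow = TRUE,
                   dimnames = list(paste0("h_mark_", 1:3), samples))
  c_mark <- matrix(rep(c(0L, 1L), each = 10), 3, 20, byrow = TRUE,
                   dimnames = list(paste0("c_mark_", 1:3), samples))
  list(binary = rbind(bg, h_mark, c_mark), groups = groups,
       planted = list(H = paste0("h_mark_", 1:3), C = paste0("c_mark_", 1:3)))
}

# Independent connected-components oracle: breadth-first traversal over an
# edge list, no igraph involved.
bfs_components <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), identity)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (n in nodes) {
    if (!is.na(comp[[n]])) next
    cid <- cid + 1L
    queue <- n
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[cur]])) next
      comp[[cur]] <- cid
      queue <- c(queue, adj[[cur]])
    }
  }
  comp
}
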
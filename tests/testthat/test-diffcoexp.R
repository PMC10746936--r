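test_that("pairwise Spearman matches the rank-then-Pearson oracle", {
  m <- rbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 2, 1))
  colnames(m) <- paste0("s", 1:3)
  cc <- pairwise_scc(m, condition = "disease")
  expect_equal(cc$scc["x", "y"], 1)
  expect_equal(cc$scc["x", "z"], -1)
  expect_true(isSymmetric(cc$scc))
  expect_equal(unname(diag(cc$scc)), rep(1, 3))

  # ties: average-rank convention
  mt <- rbind(a = c(1, 1, 2, 3), b = c(1, 2, 3, 4))
  colnames(mt) <- paste0("s", 1:4)
  cct <- pairwise_scc(mt, condition = "control")
  expect_equal(cct$scc["a", "b"], oracle_spearman(mt["a", ], mt["b", ]),
               tolerance = 1e-12)

  expect_error(pairwise_scc(m[, 1:2, drop = FALSE]), ">=3")
  expect_error(pairwise_scc(m, genes = c("x", "nope")), "absent")

  # random small matrices with ties, against the oracle
  set.seed(303)
  for (i in 1:200) {
    n_s <- sample(3:8, 1)
    n_g <- sample(2:6, 1)
    mm <- matrix(sample(1:4, n_g * n_s, replace = TRUE) + rnorm(n_g * n_s, sd = 0.1 * rbinom(1, 1, 0.5)),
                 nrow = n_g,
                 dimnames = list(paste0("g", 1:n_g), paste0("s", 1:n_s)))
    sds <- apply(mm, 1, sd)
    if (any(sds == 0)) next
    got <- pairwise_scc(mm, condition = "disease")$scc
    for (a in 1:(n_g - 1)) for (b in (a + 1):n_g) {
      expect_equal(got[a, b], oracle_spearman(mm[a, ], mm[b, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the critical correlation cutoff is mean + 1.96 sd of the SCCs", {
  scc <- diag(3)
  scc[upper.tri(scc)] <- scc[lower.tri(scc)] <- c(0.1, 0.2, 0.3)
  corr <- structure(list(genes = c("a", "b", "c"), scc = scc,
                         condition = "disease", n_samples = 10),
                    class = "condition_correlation")
  pc <- compute_pcritic(corr)
  expect_equal(pc$value, 0.2 + 1.96 * 0.1, tolerance = 1e-12)
  expect_equal(pc$value, pc$mean_scc + 1.96 * pc$std_scc)

  # degenerate: all pair correlations equal c -> sd 0, cutoff c
  scc[upper.tri(scc)] <- scc[lower.tri(scc)] <- 0.4
  corr$scc <- scc
  expect_equal(compute_pcritic(corr)$value, 0.4)
})

test_that("differential pairs obey the cutoff-and-epsilon rule exactly", {
  mk <- function(vals_d, vals_h, genes = c("A", "B")) {
    sd <- diag(2); sd[1, 2] <- sd[2, 1] <- vals_d
    sh <- diag(2); sh[1, 2] <- sh[2, 1] <- vals_h
    dimnames(sd) <- dimnames(sh) <- list(genes, genes)
    list(d = structure(list(genes = genes, scc = sd, condition = "disease",
                            n_samples = 10), class = "condition_correlation"),
         h = structure(list(genes = genes, scc = sh, condition = "control",
                            n_samples = 10), class = "condition_correlation"))
  }
  c1 <- mk(0.9, 0.2)
  got <- select_differential_pairs(c1$d, c1$h, pcritic_d = 0.5,
                                   pcritic_h = 0.5)
  expect_equal(nrow(got), 1)
  expect_equal(got$epsilon, 0.7)
  expect_true(got$significant_d)
  expect_false(got$significant_h)

  # equal correlations are never differential
  c2 <- mk(0.9, 0.9)
  expect_equal(nrow(select_differential_pairs(c2$d, c2$h, pcritic_d = 0.5,
                                              pcritic_h = 0.5)), 0)

  # truth table over a grid of (scc_d, scc_h, pcritic)
  grid <- expand.grid(d = seq(-1, 1, 0.25), h = seq(-1, 1, 0.25),
                      pc = c(0.2, 0.5, 0.8))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cc <- mk(g$d, g$h)
    kept <- nrow(select_differential_pairs(cc$d, cc$h, pcritic_d = g$pc,
                                           pcritic_h = g$pc)) == 1
    expect_identical(kept, abs(g$d) > g$pc && abs(g$d - g$h) > 0.5)
  }

  # monotonicity in the epsilon threshold
  set.seed(21)
  n_g <- 8
  sd <- matrix(runif(n_g^2, -1, 1), n_g); sd <- (sd + t(sd)) / 2; diag(sd) <- 1
  sh <- matrix(runif(n_g^2, -1, 1), n_g); sh <- (sh + t(sh)) / 2; diag(sh) <- 1
  gn <- paste0("g", 1:n_g)
  dimnames(sd) <- dimnames(sh) <- list(gn, gn)
  cd <- structure(list(genes = gn, scc = sd, condition = "disease",
                       n_samples = 10), class = "condition_correlation")
  ch <- structure(list(genes = gn, scc = sh, condition = "control",
                       n_samples = 10), class = "condition_correlation")
  counts <- vapply(seq(0, 1.5, 0.1), function(eps) {
    nrow(select_differential_pairs(cd, ch, pcritic_d = 0.3,
                                   epsilon_threshold = eps, pcritic_h = 0.3))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(select_differential_pairs(cd, c1$h), "same gene universe")
})

test_that("network construction deduplicates unordered pairs", {
  empty <- build_network(data.frame(gene_a = character(0),
                                    gene_b = character(0)))
  expect_equal(igraph::vcount(empty), 0)
  pairs <- data.frame(gene_a = c("A", "B", "B"), gene_b = c("B", "C", "A"),
                      scc_d = c(0.9, 0.8, 0.9), scc_h = 0, epsilon = 0.8)
  net <- build_network(pairs)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  expect_equal(sort(igraph::E(net)$scc_d), c(0.8, 0.9))
})

test_that("network density follows 2E/(N(N-1)) with range checks", {
  expect_equal(network_density(5, 10), 1)
  expect_equal(network_density(21, 45), 45 / 210)
  expect_equal(network_density(2, 0), 0)
  for (n in 2:10) expect_equal(network_density(n, n * (n - 1) / 2), 1)
  expect_error(network_density(3, 4), "outside")
  expect_error(network_density(1, 0), "at least 2")
})

test_that("module detection keeps dense communities and drops sparse ones", {
  # two cliques joined by a bridge
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("a", 1:6)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("b", 1:5)
  g <- igraph::disjoint_union(k6, k5)
  g <- igraph::add_edges(g, c(which(igraph::V(g)$name == "a1"),
                              which(igraph::V(g)$name == "b1")))
  mods <- detect_modules(g, min_size = 5, density_threshold = 0.9)
  expect_length(mods, 2)
  expect_equal(vapply(mods, `[[`, numeric(1), "density"), c(1, 1))
  expect_equal(mods[[1]]$nodes, paste0("a", 1:6))
  expect_equal(mods[[2]]$nodes, paste0("b", 1:5))

  # star graph: density 2/n fails the bar
  star <- igraph::make_star(10, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:10)
  expect_length(detect_modules(star, min_size = 3,
                               density_threshold = 0.5), 0)

  # empty graph
  expect_length(detect_modules(igraph::make_empty_graph(0, directed = FALSE)),
                0)

  # determinism and invariance under node relabelling (densities unchanged)
  mods2 <- detect_modules(g, min_size = 5, density_threshold = 0.9)
  expect_identical(mods, mods2)
})

test_that("pattern summary counts match an exhaustive pair loop", {
  set.seed(8)
  n_g <- 7
  gn <- paste0("g", 1:n_g)
  mk_corr <- function(cond) {
    s <- matrix(runif(n_g^2, -1, 1), n_g); s <- (s + t(s)) / 2; diag(s) <- 1
    dimnames(s) <- list(gn, gn)
    structure(list(genes = gn, scc = s, condition = cond, n_samples = 10),
              class = "condition_correlation")
  }
  cd <- mk_corr("disease"); ch <- mk_corr("control")
  module <- structure(list(module_id = "M1", nodes = gn[1:5],
                           edges = NULL, density = 1),
                      class = "coexpression_module")
  res <- correlation_pattern_summary(module, cd, ch, 0.3, 0.4)
  # brute-force loop
  pos_d <- neg_d <- 0
  for (a in 1:4) for (b in (a + 1):5) {
    v <- cd$scc[gn[a], gn[b]]
    if (v > 0.3) pos_d <- pos_d + 1
    if (v < -0.3) neg_d <- neg_d + 1
  }
  expect_equal(res$disease$positive, pos_d)
  expect_equal(res$disease$negative, neg_d)
  expect_equal(res$n_pairs, 10)
  expect_equal(unname(res$disease$pct_of_total["positive"]),
               100 * pos_d / 10)
  n_sig <- pos_d + neg_d
  if (n_sig > 0) {
    expect_equal(unname(res$disease$pct_of_significant["positive"]),
                 100 * pos_d / n_sig)
  }

  # all strong positive pairs -> every pair counted positive
  cd$scc[, ] <- 0.9; diag(cd$scc) <- 1
  res2 <- correlation_pattern_summary(module, cd, ch, 0.5, 0.4)
  expect_equal(res2$disease$positive, 10)
  expect_equal(res2$disease$negative, 0)
})

test_that("network exports are readable GraphML and SIF", {
  pairs <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      scc_d = c(0.9, -0.8), scc_h = c(0.1, 0.2),
                      epsilon = c(0.8, 1.0))
  net <- build_network(pairs)
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 2)
  expect_equal(sort(igraph::E(back)$scc_d), sort(c(0.9, -0.8)))
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, 2)
  expect_true(all(grepl("\tcoexp\t", lines)))
})
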
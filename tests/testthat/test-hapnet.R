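test_that("center-star alignment is exact for duplicates and pairs", {
  set.seed(21)
  s <- random_dna(80, 0.5)
  aln <- align_small(c(a = s, b = s, c = s))
  expect_true(all(!grepl("-", aln$rows, fixed = TRUE)))
  expect_equal(aln$length, 80)

  a <- random_dna(60, 0.5)
  b <- paste0(substr(a, 1, 30), substr(a, 36, 60))
  aln2 <- align_small(c(x = a, y = b))
  pa <- align_pair(a, b)
  expect_equal(unname(nchar(aln2$rows[1])), nchar(pa$a))
  expect_identical(gsub("-", "", aln2$rows[["x"]], fixed = TRUE), a)
  expect_identical(gsub("-", "", aln2$rows[["y"]], fixed = TRUE), b)
})

test_that("induced pairwise identities stay close to the pairwise optimum", {
  set.seed(22)
  base <- random_dna(60, 0.5)
  seqs <- c(a = base, b = mutate_snps(base, 3),
            c = paste0(substr(base, 1, 40), substr(base, 44, 60)),
            d = mutate_snps(base, 6))
  aln <- align_small(seqs)
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  ids <- names(seqs)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      keep <- !(mat[i, ] == "-" & mat[j, ] == "-")
      a <- mat[i, keep]
      b <- mat[j, keep]
      induced <- 100 * sum(a == b & a != "-") / length(a)
      optimal <- pairwise_identity(seqs[[i]], seqs[[j]])
      expect_lte(induced, optimal + 1e-9)
      expect_gte(induced, optimal - 5)
    }
  }
})

test_that("alignment statistics match a brute-force recomputation", {
  rows <- c(r1 = strrep("ACGT", 25), r2 = strrep("ACGT", 25))
  st <- alignment_stats(rows)
  expect_equal(st$length, 100)
  expect_equal(st$identical_sites, 100)
  expect_equal(st$mean_pairwise_identity, 100)

  st2 <- alignment_stats(c(a = "AC-T", b = "ACGT"))
  expect_equal(st2$identical_sites, 3)

  set.seed(23)
  mat <- matrix(sample(c("A", "C", "G", "T", "-"), 200, TRUE,
                       prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), nrow = 4)
  rows3 <- setNames(apply(mat, 1, paste, collapse = ""), paste0("r", 1:4))
  st3 <- alignment_stats(rows3)
  ident_brute <- sum(vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col[1] != "-" && length(unique(col)) == 1
  }, logical(1)))
  expect_equal(st3$identical_sites, ident_brute)
  pid <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    keep <- !(mat[i, ] == "-" & mat[j, ] == "-")
    pid <- c(pid, 100 * sum(mat[i, keep] == mat[j, keep] &
                              mat[i, keep] != "-") / sum(keep))
  }
  expect_equal(st3$mean_pairwise_identity, mean(pid))
})

test_that("two haplotypes one step apart give a single weighted edge", {
  net <- mj_network(c(h1 = "AACGT", h2 = "GACGT"))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
})

test_that("a discordant triple is joined through one inferred median", {
  # three haplotypes, pairwise distance 2, differing at disjoint columns
  haps <- c(x = "TACGTACG", y = "ATCGTACG", z = "AACTTACG")
  base <- "AACGTACG"
  expect_equal(sum(seq_chars(haps[[1]]) != seq_chars(base)), 1)
  net <- mj_network(haps)
  inferred <- net$nodes[net$nodes$type == "inferred", ]
  expect_equal(nrow(inferred), 1)
  expect_identical(inferred$seq, base)
  expect_equal(sum(net$edges$weight), 3)
  expect_true(all(net$edges$weight == 1))
})

test_that("identical haplotypes collapse to one observed node", {
  net <- mj_network(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  obs <- net$nodes[net$nodes$type == "observed", ]
  expect_equal(nrow(obs), 2)
  expect_equal(sum(obs$multiplicity), 3)
})

test_that("random instances satisfy the network invariants and cost bounds", {
  set.seed(24)
  for (rep in 1:25) {
    haps <- random_haplotype_set(sample(3:5, 1), sample(6:10, 1))
    if (length(haps) < 2) next
    names(haps) <- paste0("h", seq_along(haps))
    net <- mj_network(haps)
    obs <- net$nodes[net$nodes$type == "observed", ]
    expect_setequal(obs$seq, unname(haps))
    # edge weights equal the recomputed character distance
    seq_of <- setNames(net$nodes$seq, net$nodes$id)
    for (r in seq_len(nrow(net$edges))) {
      d <- sum(utf8ToInt(seq_of[[net$edges$from[r]]]) !=
                 utf8ToInt(seq_of[[net$edges$to[r]]]))
      expect_equal(net$edges$weight[r], d)
    }
    # connectivity
    g <- igraph::graph_from_data_frame(net$edges[c("from", "to")],
                                       directed = FALSE,
                                       vertices = net$nodes["id"])
    expect_true(igraph::is_connected(g))
    # total weight never exceeds the observed-haplotype MST (igraph oracle)
    D <- oracle_hap_dist(haps)
    gful <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                weighted = TRUE)
    mst_w <- sum(igraph::E(igraph::mst(gful))$weight)
    # the network is a spanning structure: connecting everything through
    # it must cost no more than the observed-haplotype MST (its total
    # edge weight may exceed the MST's when co-minimal ties exist)
    gnet <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                          vertices = net$nodes["id"])
    span_w <- sum(igraph::E(igraph::mst(gnet,
      weights = igraph::E(gnet)$weight))$weight)
    expect_lte(span_w, mst_w)
  }
})

test_that("with no useful median the network equals the tolerance-0 MSN", {
  set.seed(25)
  for (rep in 1:10) {
    haps <- random_haplotype_set(4, 8)
    if (length(haps) < 3) next
    names(haps) <- paste0("h", seq_along(haps))
    net <- mj_network(haps)
    if (any(net$nodes$type == "inferred")) next
    # independent MSN oracle: relaxation-based minimax distances
    D <- oracle_hap_dist(haps)
    S <- oracle_minimax(D)
    exp_edges <- 0L
    for (i in seq_len(nrow(D) - 1)) {
      for (j in (i + 1):nrow(D)) {
        if (D[i, j] <= S[i, j]) exp_edges <- exp_edges + 1L
      }
    }
    expect_equal(nrow(net$edges), exp_edges)
  }
})

test_that("input order does not change the network", {
  set.seed(26)
  haps <- random_haplotype_set(5, 10)
  names(haps) <- paste0("h", seq_along(haps))
  net1 <- mj_network(haps)
  net2 <- mj_network(rev(haps))
  canon <- function(net) {
    seq_of <- setNames(net$nodes$seq, net$nodes$id)
    a <- unname(seq_of[net$edges$from])
    b <- unname(seq_of[net$edges$to])
    key <- paste(pmin(a, b), pmax(a, b), net$edges$weight, sep = "|")
    sort(key)
  }
  expect_identical(canon(net1), canon(net2))
  expect_setequal(net1$nodes$seq, net2$nodes$seq)
})

test_that("threshold clustering partitions observed haplotypes", {
  set.seed(27)
  base1 <- random_dna(40, 0.5)
  base2 <- mutate_snps(base1, 12)
  base3 <- mutate_snps(base1, 24)
  haps <- c(a1 = base1, a2 = mutate_snps(base1, 1),
            b1 = base2, b2 = mutate_snps(base2, 1), b3 = mutate_snps(base2, 2),
            c1 = base3)
  net <- mj_network(haps)
  cl <- cluster_by_threshold(net, max_edge = 2)
  # three clusters hold observed haplotypes (inferred medians between the
  # groups may sit in components of their own)
  expect_equal(length(cl$sizes), 3L)
  expect_equal(sort(unname(as.integer(cl$sizes))), c(1L, 2L, 3L))
  obs <- net$nodes$id[net$nodes$type == "observed"]
  expect_equal(sum(cl$sizes), length(obs))

  all_one <- cluster_by_threshold(net, max_edge = max(net$edges$weight))
  expect_equal(all_one$n_clusters, 1)
  singletons <- cluster_by_threshold(net, max_edge = 0)
  expect_equal(unname(singletons$n_clusters), nrow(net$nodes))
})

test_that("network exports write GraphML, DOT and cluster tables", {
  net <- mj_network(c(h1 = "AACGT", h2 = "GACGT", h3 = "GTCGT"))
  dir <- withr::local_tempdir()
  gml <- write_network(net, file.path(dir, "net.graphml"))
  expect_true(file.exists(gml))
  dot <- write_network(net, file.path(dir, "net.dot"))
  expect_true(file.exists(dot))
  cl <- cluster_by_threshold(net)
  tsv <- write_cluster_tsv(net, cl, file.path(dir, "clusters.tsv"))
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(net$nodes))
})
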
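# Hamming distance between gapped rows, gap counted as a fifth state
# (aligned IGS sets carry many indels; the networks display that signal)
hap_dist_matrix <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(mat)
  D <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  D
}

# Prim MST on a distance matrix; returns edge matrix (i, j)
mst_edges <- function(D) {
  n <- nrow(D)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_d <- D[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0L, n - 1, 2)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[order(best_d[cand], cand)][1]
    edges[step, ] <- c(best_from[v], v)
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_d
    best_d[upd] <- D[v, upd]
    best_from[upd] <- v
  }
  edges
}

# minimax path weight between all pairs, from the MST
minimax_matrix <- function(D) {
  n <- nrow(D)
  S <- matrix(0, n, n)
  if (n < 2) return(S)
  edges <- mst_edges(D)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, D[i, j]))
    adj[[j]] <- rbind(adj[[j]], c(i, D[i, j]))
  }
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    queue <- list(c(s, 0))
    while (length(queue)) {
      top <- queue[[1]]
      queue <- queue[-1]
      v <- top[1]; mx <- top[2]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!seen[u]) {
          seen[u] <- TRUE
          S[s, u] <- max(mx, nb[r, 2])
          queue[[length(queue) + 1]] <- c(u, S[s, u])
        }
      }
    }
  }
  S
}

# minimum-spanning network with tolerance eps: edges whose direct distance
# does not exceed the minimax path distance + eps (eps = 0 gives the union
# of all minimum spanning trees)
msn_edges <- function(D, eps = 0) {
  n <- nrow(D)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = numeric(0)))
  S <- minimax_matrix(D)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] <= S[i, j] + eps) {
        out <- rbind(out, c(i, j, D[i, j]))
      }
    }
  }
  data.frame(from = out[, 1], to = out[, 2], weight = out[, 3])
}

# quasi-medians of three rows: columns where two agree take the majority
# state; fully discordant columns expand to all three candidates
quasi_medians <- function(a, b, c, max_expand = 64L) {
  ca <- seq_chars(a); cb <- seq_chars(b); cc <- seq_chars(c)
  fixed <- character(length(ca))
  free <- integer(0)
  for (t in seq_along(ca)) {
    if (ca[t] == cb[t] || ca[t] == cc[t]) fixed[t] <- ca[t]
    else if (cb[t] == cc[t]) fixed[t] <- cb[t]
    else free <- c(free, t)
  }
  if (!length(free)) return(paste(fixed, collapse = ""))
  if (3^length(free) > max_expand) {
    # cap expansion: beyond the first few fully discordant columns the
    # remaining ones take the first row's state
    keep_free <- free[seq_len(floor(log(max_expand, 3)))]
    fixed[setdiff(free, keep_free)] <- ca[setdiff(free, keep_free)]
    free <- keep_free
  }
  grid <- expand.grid(lapply(free, function(t) c(ca[t], cb[t], cc[t])),
                      stringsAsFactors = FALSE)
  apply(grid, 1, function(vals) {
    out <- fixed
    out[free] <- vals
    paste(out, collapse = "")
  })
}

#' Median-joining network over aligned haplotypes
#'
#' Builds the minimum-spanning network (tolerance `epsilon`) over the
#' distinct haplotypes, then iteratively adds quasi-median sequences of
#' linked triplets whenever doing so reduces the total network cost, and
#' finally deletes median nodes that no longer pay for themselves.
#' Distances count differing columns with the gap character as a fifth
#' state. Deterministic: candidate medians are ranked by cost saving, then
#' lexicographically.
#'
#' @param aln an `igs_alignment` or named character vector of equal-length
#'   (gapped) haplotype strings.
#' @param epsilon MSN tolerance (default 0).
#' @param max_iterations safety cap on median-addition rounds.
#' @return an object of class `haplotype_network`: `nodes` (data.frame id,
#'   seq, type observed/inferred, multiplicity, members), `edges`
#'   (data.frame from, to, weight), `epsilon`.
#' @export
mj_network <- function(aln, epsilon = 0, max_iterations = 25L) {
  rows <- as_alignment_rows(aln)
  if (is.null(names(rows))) names(rows) <- sprintf("hap%03d", seq_along(rows))
  groups <- split(names(rows), unname(rows))
  seqs <- names(groups)                   # distinct haplotype strings
  obs_members <- unname(groups)
  obs_labels <- vapply(obs_members, function(m) sort(m)[1], character(1))
  ord <- order(obs_labels)
  seqs <- seqs[ord]
  obs_members <- obs_members[ord]
  obs_labels <- obs_labels[ord]
  n_obs <- length(seqs)

  node_seqs <- seqs
  node_type <- rep("observed", n_obs)

  # cost of a node set: weight of a minimum spanning tree over it (the
  # connection cost medians are meant to reduce; the MSN's total edge
  # weight would double-count co-minimal tie edges)
  network_weight <- function(sq) {
    D <- hap_dist_matrix(sq)
    ed <- mst_edges(D)
    if (!nrow(ed)) return(0)
    sum(D[ed])
  }

  if (n_obs >= 3) {
    for (iter in seq_len(max_iterations)) {
      D <- hap_dist_matrix(node_seqs)
      E <- msn_edges(D, epsilon)
      W <- network_weight(node_seqs)
      link <- matrix(FALSE, length(node_seqs), length(node_seqs))
      if (nrow(E)) {
        link[cbind(E$from, E$to)] <- TRUE
        link[cbind(E$to, E$from)] <- TRUE
      }
      cands <- character(0)
      nn <- length(node_seqs)
      for (u in seq_len(nn - 2)) {
        for (v in (u + 1):(nn - 1)) {
          for (w in (v + 1):nn) {
            nlinks <- link[u, v] + link[u, w] + link[v, w]
            if (nlinks < 2) next
            cands <- c(cands,
                       quasi_medians(node_seqs[u], node_seqs[v], node_seqs[w]))
          }
        }
      }
      cands <- setdiff(unique(cands), node_seqs)
      if (!length(cands)) break
      w_new <- vapply(cands, function(m) network_weight(c(node_seqs, m)),
                      numeric(1))
      best <- order(w_new, cands)[1]
      if (w_new[best] >= W) break
      node_seqs <- c(node_seqs, cands[best])
      node_type <- c(node_type, "inferred")
    }
    # obsolete-median cleanup: drop any inferred node whose removal does
    # not increase the network cost
    repeat {
      W <- network_weight(node_seqs)
      inferred <- which(node_type == "inferred")
      removed <- FALSE
      for (m in inferred) {
        if (network_weight(node_seqs[-m]) <= W) {
          node_seqs <- node_seqs[-m]
          node_type <- node_type[-m]
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
  }

  n_total <- length(node_seqs)
  n_inf <- n_total - n_obs
  ids <- c(obs_labels, if (n_inf) sprintf("median_%02d", seq_len(n_inf)))
  mult <- c(lengths(obs_members), rep(0L, n_inf))
  members <- c(vapply(obs_members, paste, character(1), collapse = ","),
               rep("", n_inf))
  D <- hap_dist_matrix(node_seqs)
  E <- msn_edges(D, epsilon)
  nodes <- data.frame(id = ids, seq = node_seqs, type = node_type,
                      multiplicity = mult, members = members,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[E$from], to = ids[E$to], weight = E$weight,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype_network: %d observed + %d inferred nodes, %d edges (total weight %g)\n",
    sum(x$nodes$type == "observed"), sum(x$nodes$type == "inferred"),
    nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Cluster network nodes by an edge-weight threshold
#'
#' Formalizes the "main clusters" of a haplotype network as the connected
#' components after removing edges heavier than `max_edge`. Cluster labels
#' are deterministic: each cluster is named after its smallest member id.
#'
#' @param net a `haplotype_network`.
#' @param max_edge largest mutation-step weight kept (default 3).
#' @return a list: `membership` (named by node id), `sizes` (observed-node
#'   count per cluster), `n_clusters`.
#' @export
cluster_by_threshold <- function(net, max_edge = 3) {
  keep <- net$edges[net$edges$weight <= max_edge, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[c("from", "to")], directed = FALSE,
    vertices = net$nodes["id"])
  comp <- igraph::components(g)$membership
  labels <- vapply(split(names(comp), comp), function(m) sort(m)[1],
                   character(1))
  membership <- setNames(labels[as.character(comp)], names(comp))
  obs <- net$nodes$id[net$nodes$type == "observed"]
  sizes <- table(membership[obs])
  list(membership = membership,
       sizes = sizes[order(names(sizes))],
       n_clusters = length(unique(membership)))
}

#' Export a haplotype network to GraphML or DOT
#'
#' @param net a `haplotype_network`.
#' @param path output file; format chosen by extension (.graphml or .dot).
#' @export
write_network <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  fmt <- if (grepl("\\.dot$", path)) "dot" else "graphml"
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}

#' Write cluster assignments as TSV
#'
#' Columns: node, cluster, type (observed/inferred), multiplicity.
#'
#' @param net a `haplotype_network`.
#' @param clusters result of [cluster_by_threshold()].
#' @param path output TSV.
#' @export
write_cluster_tsv <- function(net, clusters, path) {
  tab <- data.frame(node = net$nodes$id,
                    cluster = unname(clusters$membership[net$nodes$id]),
                    type = net$nodes$type,
                    multiplicity = net$nodes$multiplicity,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
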
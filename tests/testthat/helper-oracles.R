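# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. These deliberately share no code
# with the implementation paths they verify.

# Naive O(n^3) agglomerative Ward clustering on a raw distance matrix,
# applying the Lance-Williams ward.D update directly at every merge.
# Returns the merge heights (ascending) and, per merge, the sorted leaf
# members of the newly formed cluster.
naive_ward <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  members <- list()
  Dw <- D
  diag(Dw) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- Dw[idx, idx, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(pos)]; j <- idx[max(pos)]
    heights <- c(heights, Dw[i, j])
    new_members <- sort(c(clusters[[i]], clusters[[j]]))
    members[[step]] <- new_members
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      upd <- ((ni + nk) * Dw[i, k] + (nj + nk) * Dw[j, k] -
                nk * Dw[i, j]) / (ni + nj + nk)
      Dw[i, k] <- Dw[k, i] <- upd
    }
    clusters[[i]] <- new_members
    sizes[i] <- ni + nj
    active[j] <- FALSE
  }
  list(heights = heights, members = members)
}

# Extract the same (heights, members) representation from an hclust tree.
hclust_merges <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    kids <- hc$merge[step, ]
    leaves <- integer(0)
    for (kid in kids) {
      leaves <- c(leaves,
                  if (kid < 0) -kid else members[[kid]])
    }
    members[[step]] <- sort(leaves)
  }
  list(heights = hc$height, members = members)
}

# Betweenness by explicit enumeration of every shortest path (BFS depths,
# then recursive path listing), normalized by (n-1)(n-2)/2.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  score <- setNames(numeric(n), rownames(adj))
  bfs_depth <- function(s) {
    depth <- rep(Inf, n)
    depth[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] == 1 & depth == Inf)
        depth[nb] <- d
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    depth
  }
  for (s in seq_len(n - 1)) {
    depth <- bfs_depth(s)
    for (t in seq(s + 1, n)) {
      if (!is.finite(depth[t])) next
      # enumerate all shortest s->t paths by walking predecessors
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1]] <<- acc
          return(invisible())
        }
        preds <- which(adj[v, ] == 1 & depth == depth[v] - 1)
        for (p in preds) walk(p, c(p, acc))
      }
      walk(t, t)
      through <- table(unlist(lapply(paths, function(p) {
        setdiff(p, c(s, t))
      })))
      if (length(through))
        score[as.integer(names(through))] <-
          score[as.integer(names(through))] +
          as.numeric(through) / length(paths)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

# Hypergeometric upper tail by exhaustive enumeration of every possible
# signature draw from a small universe.
exhaustive_hyper_p <- function(signature_size, set_size, overlap,
                               universe_size) {
  draws <- combn(universe_size, signature_size)
  hits <- colSums(draws <= set_size)  # set = first set_size universe genes
  mean(hits >= overlap)
}

# Small deterministic expression fixture.
tiny_matrix <- function(n_genes = 3, n_case = 2, n_control = 2,
                        seed = 99) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * (n_case + n_control)), n_genes,
                n_case + n_control,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("s", seq_len(n_case + n_control))))
    expression_matrix(v, rep(c("case", "control"), c(n_case, n_control)))
  })
}
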
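# Independent oracles used to freeze expected values; these deliberately do
# not share code with the package implementation.

# maximal-match enumeration for the motif grammar: walk left to right, at
# each position try the longest possible match of the class, emit and jump
oracle_scan_motifs <- function(x, cls) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  match_at <- function(i) {
    if (cls == "GPG") {
      if (i + 2 <= n && chars[i] == "G" && chars[i + 1] == "P" &&
          chars[i + 2] == "G") 3L else 0L
    } else if (cls == "GGX") {
      if (i + 2 <= n && chars[i] == "G" && chars[i + 1] == "G") 3L else 0L
    } else if (cls == "POLY_A") {
      len <- 0L
      while (i + len <= n && chars[i + len] == "A") len <- len + 1L
      if (len >= 4L) len else 0L
    } else if (cls == "GA_RUN") {
      len <- 0L
      while (i + len + 1L <= n && chars[i + len] == "G" &&
             chars[i + len + 1L] == "A") len <- len + 2L
      if (len >= 4L) len else 0L
    } else stop("unknown class")
  }
  out <- NULL
  i <- 1L
  while (i <= n) {
    len <- match_at(i)
    if (len > 0L) {
      out <- rbind(out, data.frame(start = i - 1L, end = i - 1L + len))
      i <- i + len
    } else i <- i + 1L
  }
  out
}

# plain linear-gap Needleman-Wunsch score by memoised recursion; valid
# reference for the affine aligner when gap_open == gap_extend
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- gap * (0:n)
  d[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- max(
        d[i, j] + if (a[i] == b[j]) match else mismatch,
        d[i, j + 1] + gap,
        d[i + 1, j] + gap)
    }
  }
  d[n + 1, m + 1]
}

# exhaustive ATG..stop scan over frames; returns longest length (nt) or NA
oracle_longest_orf <- function(x) {
  best <- NA_integer_
  n <- nchar(x)
  for (s in seq_len(max(0L, n - 2L))) {
    if (substr(x, s, s + 2) != "ATG") next
    j <- s + 3L
    while (j + 2L <= n) {
      if (substr(x, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
        len <- j + 3L - s
        if (is.na(best) || len > best) best <- len
        break
      }
      j <- j + 3L
    }
  }
  best
}

# minimum-duplication reconciliation by exhaustive search over valid maps
# (species assignment of each internal gene node ranges over the ancestors
# of the LCA of its descendant species, subject to parent/child consistency)
oracle_min_duplications <- function(gene_tree, species_tree, map_df) {
  sp_map <- stats::setNames(map_df$species, map_df$id)
  n_sp_tips <- length(species_tree$tip.label)
  n_sp <- n_sp_tips + species_tree$Nnode
  parent <- integer(n_sp)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  root_sp <- setdiff(species_tree$edge[, 1], species_tree$edge[, 2])[1]
  anc <- lapply(seq_len(n_sp), function(v) {
    p <- v
    while (v != root_sp) { v <- parent[v]; p <- c(p, v) }
    p
  })
  lca2 <- function(u, v) anc[[u]][match(TRUE, anc[[u]] %in% anc[[v]])]

  ngt <- length(gene_tree$tip.label)
  n_g <- ngt + gene_tree$Nnode
  kids <- vector("list", n_g)
  for (e in seq_len(nrow(gene_tree$edge))) {
    p <- gene_tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], gene_tree$edge[e, 2])
  }
  po <- {
    edges <- ape::reorder.phylo(gene_tree, "postorder")$edge
    c(edges[, 2], setdiff(edges[, 1], edges[, 2])[1])
  }
  lca_map <- integer(n_g)
  for (g in po) {
    lca_map[g] <- if (g <= ngt) {
      match(sp_map[[gene_tree$tip.label[g]]], species_tree$tip.label)
    } else {
      ch <- kids[[g]]
      lca2(lca_map[ch[1]], lca_map[ch[2]])
    }
  }
  internal <- po[po > ngt]
  choices <- lapply(internal, function(g) anc[[lca_map[g]]])
  best <- Inf
  # the species-tree child of s on the path down to descendant node m
  child_towards <- function(s, m) {
    path <- anc[[m]]
    path[match(s, path) - 1L]
  }
  assign_next <- function(idx, m) {
    if (idx > length(internal)) {
      dups <- 0L
      for (g in internal) {
        mcs <- integer(2)
        for (ci in 1:2) {
          c <- kids[[g]][ci]
          mc <- if (c <= ngt) lca_map[c] else m[[as.character(c)]]
          if (!(m[[as.character(g)]] %in% anc[[mc]])) return(invisible(NULL))
          mcs[ci] <- mc
        }
        s <- m[[as.character(g)]]
        # speciation only when the children map into distinct child
        # subtrees of s; anything else is a duplication
        if (s %in% mcs ||
            child_towards(s, mcs[1]) == child_towards(s, mcs[2])) {
          dups <- dups + 1L
        }
      }
      best <<- min(best, dups)
      return(invisible(NULL))
    }
    g <- internal[idx]
    for (s in choices[[idx]]) {
      m[[as.character(g)]] <- s
      assign_next(idx + 1L, m)
    }
  }
  assign_next(1L, list())
  best
}

# exhaustive period scan: best tandem block by trying every period/phase
# with a per-column consensus over full copies
oracle_best_period <- function(x, periods = 5:50, min_identity = 0.75) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  best <- NULL
  for (p in periods) {
    n_cop <- n %/% p
    if (n_cop < 2) next
    for (phase in 0:(min(p - 1, n - 2 * p))) {
      k <- (n - phase) %/% p
      if (k < 2) next
      m <- matrix(chars[phase + seq_len(k * p)], nrow = k, byrow = TRUE)
      cons <- apply(m, 2, function(col) names(which.max(table(col))))
      ids <- rowMeans(m == matrix(cons, k, p, byrow = TRUE))
      if (mean(ids) < min_identity) next
      score <- k * p * mean(ids)
      if (is.null(best) || score > best$score) {
        best <- list(period = p, copies = k, score = score,
                     mean_identity = mean(ids))
      }
    }
  }
  best
}

KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
        G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
        P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

random_protein <- function(n, alphabet = names(KD)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
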
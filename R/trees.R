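#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining (via [ape::nj()]) on a symmetric
#' distance matrix; on additive matrices it recovers the generating tree
#' exactly, topology and branch lengths. Optionally midpoint-rooted for
#' display.
#'
#' @param d A symmetric numeric matrix with zero diagonal (dimnames become
#'   tip labels) or a [stats::dist] object.
#' @param midpoint Midpoint-root the result.
#' @return An [ape] `phylo` tree (unrooted unless `midpoint = TRUE`).
#' @export
neighbor_joining <- function(d, midpoint = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("`d` must be symmetric")
  }
  if (any(diag(d) < 0) || any(abs(diag(d)) > 1e-12)) {
    abort("`d` must have a zero, non-negative diagonal")
  }
  tree <- ape::nj(stats::as.dist(d))
  if (midpoint) tree <- phangorn::midpoint(tree)
  tree
}

#' Gene tree / species tree reconciliation by LCA mapping
#'
#' Maps every gene-tree node to the last common ancestor (in the species
#' tree) of the species its descendant leaves belong to. A gene node whose
#' mapping equals the mapping of one of its children is a duplication.
#' Losses are counted along the induced embedding: each gene-tree edge
#' (g, c) contributes `depth(M(c)) - depth(M(g)) - 1` losses, plus one more
#' when g is a duplication. This LCA reconciliation minimises duplications
#' (and duplications + losses) over all valid reconciliation maps.
#'
#' @param gene_tree,species_tree Rooted binary `phylo` trees.
#' @param leaf_species A tibble mapping gene-tree tip `id` to species-tree
#'   tip `species`.
#' @return A `reconciliation` object: list with `duplication_nodes`
#'   (gene-tree node numbers), `n_duplications`, `n_losses`, and `mapping`
#'   (species-tree node for each gene-tree node).
#' @export
reconcile <- function(gene_tree, species_tree, leaf_species) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  stopifnot(all(c("id", "species") %in% names(leaf_species)))
  check_binary_rooted(gene_tree, "gene tree")
  check_binary_rooted(species_tree, "species tree")
  sp_map <- setNames(leaf_species$species, leaf_species$id)
  missing <- setdiff(gene_tree$tip.label, names(sp_map))
  if (length(missing)) {
    abort(paste0("gene leaf without a species mapping: ", missing[1]))
  }
  bad <- setdiff(unname(sp_map[gene_tree$tip.label]), species_tree$tip.label)
  if (length(bad)) {
    abort(paste0("species not in the species tree: ", bad[1]))
  }

  s_anc <- ancestor_paths(species_tree)        # node -> path to root
  s_depth <- vapply(s_anc, length, integer(1)) - 1L
  sp_tip_idx <- setNames(seq_along(species_tree$tip.label),
                         species_tree$tip.label)
  lca <- function(u, v) {
    pu <- s_anc[[u]]
    pu[match(TRUE, pu %in% s_anc[[v]])]
  }

  ng_tips <- length(gene_tree$tip.label)
  n_nodes <- ng_tips + gene_tree$Nnode
  children <- children_list(gene_tree, n_nodes)
  mapping <- integer(n_nodes)
  is_dup <- logical(n_nodes)
  losses <- 0L
  for (g in postorder_nodes(gene_tree)) {
    if (g <= ng_tips) {
      mapping[g] <- sp_tip_idx[[sp_map[[gene_tree$tip.label[g]]]]]
    } else {
      ch <- children[[g]]
      mapping[g] <- lca(mapping[ch[1]], mapping[ch[2]])
      is_dup[g] <- mapping[g] %in% mapping[ch]
      for (c in ch) {
        losses <- losses + (s_depth[mapping[c]] - s_depth[mapping[g]] -
                              1L + is_dup[g])
      }
    }
  }
  structure(list(duplication_nodes = which(is_dup),
                 n_duplications = sum(is_dup),
                 n_losses = losses,
                 mapping = mapping),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Reconciliation:", x$n_duplications, "duplication(s),",
      x$n_losses, "loss(es)\n")
  invisible(x)
}

check_binary_rooted <- function(tree, what) {
  if (!ape::is.rooted(tree)) abort(paste0(what, " must be rooted"))
  n_tips <- length(tree$tip.label)
  tab <- tabulate(tree$edge[, 1], nbins = n_tips + tree$Nnode)
  poly <- which(tab > 2L)
  if (length(poly)) {
    abort(sprintf("%s has a polytomy at node %d", what, poly[1]))
  }
  if (any(tab[tab > 0L] < 2L)) {
    abort(paste0(what, " has a unary node"))
  }
  invisible(TRUE)
}

children_list <- function(tree, n_nodes) {
  ch <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2])
  }
  ch
}

# node numbers in postorder (children before parents)
postorder_nodes <- function(tree) {
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  root <- setdiff(edges[, 1], edges[, 2])[1]
  c(edges[, 2], root)
}

# node -> vector of nodes from itself up to the root
ancestor_paths <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  lapply(seq_len(n_nodes), function(v) {
    path <- v
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  })
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node the contrast
#' between the two daughter values is standardised by the square root of
#' the summed (adjusted) branch variances, the ancestral value is the
#' variance-weighted mean of the daughters, and the parent branch is
#' lengthened by `v1 * v2 / (v1 + v2)`. Under Brownian motion the
#' standardised contrasts are i.i.d. with variance equal to the evolutionary
#' rate, making cross-species regressions valid (through the origin).
#'
#' @param tree A rooted binary `phylo` tree with branch lengths.
#' @param traits A tibble mapping tip `id` to `value`, or a numeric vector
#'   named by tip label.
#' @return A tibble `node`, `contrast`, `expected_variance`, with attribute
#'   `n_tips`; a binary tree with n tips yields n - 1 contrasts.
#' @export
pic_contrasts <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(traits)) {
    stopifnot(all(c("id", "value") %in% names(traits)))
    traits <- setNames(traits$value, traits$id)
  }
  check_binary_rooted(tree, "tree")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing)) abort(paste0("missing trait for tip: ", missing[1]))
  n_tips <- length(tree$tip.label)
  n_nodes <- n_tips + tree$Nnode
  parent_edge <- integer(n_nodes)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  blen <- numeric(n_nodes)
  blen[tree$edge[, 2]] <- tree$edge.length
  xval <- numeric(n_nodes)
  xval[seq_len(n_tips)] <- unname(traits[tree$tip.label])
  children <- children_list(tree, n_nodes)
  out_node <- integer(0); out_con <- numeric(0); out_var <- numeric(0)
  for (g in postorder_nodes(tree)) {
    if (g <= n_tips) next
    ch <- children[[g]]
    v <- blen[ch]
    if (sum(v) <= 0) {
      abort(sprintf("zero summed branch variance at node %d", g))
    }
    out_node <- c(out_node, g)
    out_con <- c(out_con, (xval[ch[1]] - xval[ch[2]]) / sqrt(sum(v)))
    out_var <- c(out_var, sum(v))
    xval[g] <- weighted.mean(xval[ch], 1 / v)
    blen[g] <- blen[g] + prod(v) / sum(v)
  }
  out <- tibble(node = out_node, contrast = out_con,
                expected_variance = out_var)
  attr(out, "n_tips") <- n_tips
  out
}
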
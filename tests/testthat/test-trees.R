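test_that("neighbor joining validates input and recovers additive trees", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_error(neighbor_joining(matrix(1:6, 2, 3)), "square")
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(neighbor_joining(m), "symmetric")
  md <- d; diag(md) <- c(-1, 0)
  expect_error(neighbor_joining(md), "diagonal")

  # three taxa: branch lengths solve the closed-form equations
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "b"] <- d3["b", "a"] <- 5
  d3["a", "c"] <- d3["c", "a"] <- 7
  d3["b", "c"] <- d3["c", "b"] <- 8
  tr3 <- neighbor_joining(d3)
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(bl["a"]), (5 + 7 - 8) / 2)
  expect_equal(unname(bl["b"]), (5 + 8 - 7) / 2)
  expect_equal(unname(bl["c"]), (7 + 8 - 5) / 2)

  # additive 5-taxon matrices are recovered exactly
  set.seed(37)
  for (i in 1:10) {
    true <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    true <- ape::unroot(true)
    dm <- ape::cophenetic.phylo(true)
    got <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(got, true), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ape::cophenetic.phylo(got))[rownames(dm),
                                                       colnames(dm)],
                 dm, tolerance = 1e-8)
  }
})

test_that("LCA reconciliation counts duplications and losses", {
  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # congruent gene tree: no events
  gt <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  map <- tibble::tibble(id = c("a", "b", "c"), species = c("A", "B", "C"))
  rec <- reconcile(gt, st, map)
  expect_equal(rec$n_duplications, 0L)
  expect_equal(rec$n_losses, 0L)

  # two copies in one species: one duplication
  gt2 <- ape::read.tree(text = "((a1:1,a2:1):1,b:2);")
  rec2 <- reconcile(gt2, st, tibble::tibble(id = c("a1", "a2", "b"),
                                            species = c("A", "A", "B")))
  expect_equal(rec2$n_duplications, 1L)

  # paralogs grouping within two species (the concerted-evolution-like
  # topology) imply independent duplications
  gt3 <- ape::read.tree(text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,c:3);")
  rec3 <- reconcile(gt3, st, tibble::tibble(
    id = c("a1", "a2", "b1", "b2", "c"),
    species = c("A", "A", "B", "B", "C")))
  expect_equal(rec3$n_duplications, 2L)

  # deep duplication with a loss: ((A,B),A') pattern
  gt4 <- ape::read.tree(text = "((a1:1,b1:1):1,a2:2);")
  rec4 <- reconcile(gt4, st, tibble::tibble(id = c("a1", "b1", "a2"),
                                            species = c("A", "B", "A")))
  expect_equal(rec4$n_duplications, 1L)
  expect_equal(rec4$n_losses, 1L)

  expect_error(reconcile(gt, st, map[-1, ]), "without a species")
  # a basal trifurcation is unrooted/polytomous; either way it is refused
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(reconcile(poly, st, map), "polytomy|rooted")
})

test_that("reconciliation equals the brute-force minimum on random trees", {
  set.seed(43)
  for (i in 1:12) {
    st <- ape::rtree(4)
    st$tip.label <- LETTERS[1:4]
    n_genes <- sample(4:7, 1)
    species <- sample(LETTERS[1:4], n_genes, replace = TRUE)
    gt <- ape::rtree(n_genes)
    gt$tip.label <- paste0(tolower(species), seq_len(n_genes))
    map <- tibble::tibble(id = gt$tip.label, species = species)
    rec <- reconcile(gt, st, map)
    expect_equal(rec$n_duplications,
                 oracle_min_duplications(gt, st, map))
  }
})

test_that("duplication count is invariant to within-species leaf swaps", {
  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  gt <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:2):1,c:3);")
  map1 <- tibble::tibble(id = c("a1", "a2", "b1", "c"),
                         species = c("A", "A", "B", "C"))
  swapped <- tibble::tibble(id = c("a2", "a1", "b1", "c"),
                            species = c("A", "A", "B", "C"))
  expect_equal(reconcile(gt, st, map1)$n_duplications,
               reconcile(gt, st, swapped)$n_duplications)
})

test_that("independent contrasts match closed forms and ape", {
  # two tips, equal branches: contrast = (x1 - x2) / sqrt(2v)
  t2 <- ape::read.tree(text = "(a:2,b:2);")
  c2 <- pic_contrasts(t2, c(a = 5, b = 1))
  expect_equal(c2$contrast, (5 - 1) / sqrt(4))
  expect_equal(c2$expected_variance, 4)
  expect_equal(nrow(c2), 1L)

  # three tips, unit branches: pruning order closed form
  t3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  x3 <- c(a = 3, b = 1, c = 7)
  c3 <- pic_contrasts(t3, x3)
  expect_equal(nrow(c3), 2L)
  expect_equal(sort(abs(c3$contrast)),
               sort(abs(c(
                 (3 - 1) / sqrt(2),                       # a vs b
                 (2 - 7) / sqrt(1.5 + 2)))))              # anc(a,b) vs c
  # n - 1 contrasts on larger random trees, matching ape::pic
  set.seed(47)
  for (i in 1:8) {
    tr <- ape::rtree(sample(5:12, 1))
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    expect_equal(nrow(mine), length(tr$tip.label) - 1L)
    theirs <- ape::pic(x, tr)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(theirs))),
                 tolerance = 1e-10)
  }
  expect_error(pic_contrasts(t2, c(a = 1)), "missing trait")
  t0 <- t2; t0$edge.length <- c(0, 0)
  expect_error(pic_contrasts(t0, c(a = 1, b = 2)), "zero summed")
})

test_that("contrast regression recovers the Brownian slope", {
  set.seed(53)
  tree <- ape::rtree(16)
  beta <- 1.7
  est <- se <- numeric(120)
  for (r in 1:120) {
    traits <- simulate_bm_traits(tree, sigma2 = 1, slope = beta,
                                 noise_sigma2 = 0.25, seed = 7000 + r)
    fit <- pic_regress(tree, traits, x, y)
    est[r] <- fit$slope
    se[r] <- fit$slope_se
  }
  expect_lt(abs(mean(est) - beta), 2 * sd(est) / sqrt(length(est)))
  # standardized contrast variance tracks sigma2
  v <- replicate(60, {
    tr <- simulate_bm_traits(tree, sigma2 = 1, seed = sample.int(1e6, 1))
    var(pic_contrasts(tree, tibble::tibble(id = tr$id,
                                           value = tr$x))$contrast)
  })
  expect_lt(abs(mean(v) - 1), 2 * sd(v) / sqrt(length(v)))
})
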
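test_that("generators are bit-reproducible and leave the RNG alone", {
  spec <- spidroin_spec()
  g1 <- generate_spidroin(spec, seed = 11)
  g2 <- generate_spidroin(spec, seed = 11)
  expect_identical(g1, g2)
  g3 <- generate_spidroin(spec, seed = 12)
  expect_false(identical(g1$protein$residues, g3$protein$residues))

  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_spidroin(spec, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero mutation rates give identical repeat copies", {
  spec <- spidroin_spec(repeat_rate = 0, spacer_rate = 0,
                        spacer_positions = integer(0))
  gen <- generate_spidroin(spec, seed = 13)
  blk <- find_tandem_repeats(gen$protein)
  expect_equal(blk$period, spec$repeat_period)
  expect_equal(blk$copies, spec$repeat_copies)
  # seed phase is arbitrary, so the interval may be rotated by part of one
  # period and the first copy may straddle the terminal boundary
  expect_gte(blk$mean_identity, 1 - 2 / spec$repeat_period)
  expect_lt(abs(blk$start - gen$truth$repeats$start), spec$repeat_period)
  expect_lt(abs(blk$end - gen$truth$repeats$end), spec$repeat_period)
})

test_that("motif mix controls repeat-region coverage and composition", {
  pure <- spidroin_spec(motif_mix = c(GPG = 1), repeat_period = 30L,
                        repeat_copies = 10L, repeat_rate = 0,
                        spacer_positions = integer(0))
  gen <- generate_spidroin(pure, seed = 17)
  reg <- gen$truth$regions
  cov <- motif_coverage(gen$protein, "GPG",
                        region_start = reg$start[reg$region == "repeat"],
                        region_end = reg$end[reg$region == "repeat"])
  expect_equal(cov$coverage, 1)

  # with weight w on GPG, coverage lands near w
  mixed <- spidroin_spec(motif_mix = c(GPG = 0.4, GA_RUN = 0.6),
                         repeat_period = 60L, repeat_copies = 12L,
                         repeat_rate = 0, spacer_positions = integer(0))
  gm <- generate_spidroin(mixed, seed = 19)
  regm <- gm$truth$regions
  covm <- motif_coverage(gm$protein, "GPG",
                         region_start = regm$start[regm$region == "repeat"],
                         region_end = regm$end[regm$region == "repeat"])
  expect_gt(covm$coverage, 0.2)
  expect_lt(covm$coverage, 0.6)

  # default grammar makes G, A, S the most abundant residues
  gen_def <- generate_spidroin(spidroin_spec(), seed = 23)
  cmp <- composition(gen_def$protein)
  top3 <- cmp$residue[order(-cmp$fraction)][1:3]
  expect_setequal(top3, c("G", "A", "S"))
})

test_that("family evolution logs events and honours their scopes", {
  spec <- spidroin_spec()
  tree <- ape::read.tree(text = "((Lh:1,Lt:1):1,(Lg:1.5,Sg:1.5):0.5);")

  # slippage only: repeat length changes, spacer count constant
  fam <- evolve_family(spec, tree, duplications = "root",
                       conversion_rate = 0, slippage_rate = 2,
                       branch_rate = 0, seed = 29)
  expect_true(all(c("duplication", "slippage") %in% fam$events$event))
  expect_false("conversion" %in% fam$events$event)
  prot <- translate_cds(seq_tbl(fam$sequences$id,
                                vapply(fam$sequences$residues, function(x)
                                  substr(x, 1, nchar(x) - 3), character(1),
                                  USE.NAMES = FALSE)))
  n_spacers <- detect_spacers(prot) |>
    dplyr::count(id) |>
    dplyr::pull(n)
  expect_true(all(n_spacers == length(spec$spacer_positions)))
  slipped <- unique(fam$events$branch[fam$events$event == "slippage"])
  expect_gt(length(slipped), 0)

  # conversion off: terminal distance grows with branch length and NJ on
  # termini groups orthologous loci
  fam0 <- evolve_family(spec, tree, duplications = "root",
                        conversion_rate = 0, slippage_rate = 0,
                        branch_rate = 0.03, seed = 31)
  term <- extract_region(fam0$sequences, "terminal")
  d <- p_distance_matrix(term)
  # sister species (Lh, Lt) termini are closer than distant pairs
  expect_lt(d["Lh_v1", "Lt_v1"], d["Lh_v1", "Sg_v1"])
  # with the duplication at the root, ortholog sister pairs group while
  # within-species paralog pairs do not
  nj <- neighbor_joining(d, midpoint = TRUE)
  expect_true(ape::is.monophyletic(nj, c("Lh_v1", "Lt_v1")))
  expect_true(ape::is.monophyletic(nj, c("Lg_v2", "Sg_v2")))
  expect_false(ape::is.monophyletic(nj, c("Lh_v1", "Lh_v2")))

  # high terminal-only conversion: paralogs group within species while
  # repeat regions stay divergent
  fam1 <- evolve_family(spec, tree, duplications = "root",
                        conversion_rate = 8, conversion_tract_len = 300,
                        terminal_only = TRUE, slippage_rate = 0,
                        branch_rate = 0.03, seed = 31)
  term1 <- extract_region(fam1$sequences, "terminal")
  d1 <- p_distance_matrix(term1)
  nj1 <- neighbor_joining(d1, midpoint = TRUE)
  expect_true(ape::is.monophyletic(nj1, c("Lh_v1", "Lh_v2")))
  rep1 <- p_distance_matrix(extract_region(fam1$sequences, "repeat"))
  expect_gt(rep1["Lh_v1", "Lh_v2"], 3 * d1["Lh_v1", "Lh_v2"])
})

test_that("read simulation honours ratio, bias and error settings", {
  spec <- spidroin_spec(repeat_copies = 8L)
  refs <- dplyr::bind_rows(
    generate_spidroin(spec, seed = 37, id = "v2")$cds,
    generate_spidroin(spec, seed = 38, id = "v1")$cds)

  rr <- generate_reads(refs, depth = 3000, true_ratio = c(v2 = 4, v1 = 1),
                       read_len = 60, three_prime_decay = 0,
                       error_rate = 0, seed = 41)
  tab <- table(rr$truth$reference_id)
  p <- unname(tab["v2"] / 3000)
  expect_lt(abs(p - 0.8), 3 * sqrt(0.8 * 0.2 / 3000))
  # error-free reads are exact substrings at their recorded start
  idx <- sample(nrow(rr$truth), 20)
  for (i in idx) {
    ref <- refs$residues[refs$id == rr$truth$reference_id[i]]
    expect_equal(substr(ref, rr$truth$start[i] + 1,
                        rr$truth$start[i] + 60),
                 rr$reads$residues[rr$reads$id == rr$truth$read_id[i]])
  }
  # uniform start positions under decay 0
  L <- nchar(refs$residues[1]) - 60
  expect_lt(abs(mean(rr$truth$start[rr$truth$reference_id == "v2"]) - L / 2),
            3 * L / sqrt(12 * sum(rr$truth$reference_id == "v2")))

  # strong decay concentrates starts near the 3' end
  rr3 <- generate_reads(refs, depth = 2000, true_ratio = c(v2 = 1),
                        read_len = 60, three_prime_decay = 10, seed = 43)
  frac_last_quarter <- mean(rr3$truth$start > 0.75 * L)
  expect_gt(frac_last_quarter, 0.9)
})

test_that("Brownian traits degenerate correctly and scale with sigma2", {
  tree <- ape::rtree(12)
  flat <- simulate_bm_traits(tree, sigma2 = 0, root_value = 3, seed = 47)
  expect_equal(flat$x, rep(3, 12))
  tr <- simulate_bm_traits(tree, sigma2 = 2, slope = 0.5, seed = 49)
  expect_named(tr, c("id", "x", "y"))
  expect_equal(nrow(tr), 12L)
})
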
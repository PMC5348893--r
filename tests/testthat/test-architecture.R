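ga_rich <- function(n, seed_offset = 0) {
  paste(rep(c("G", "A"), length.out = n), collapse = "")
}
stv_block <- function(n) {
  paste(rep(c("S", "T", "V"), length.out = n), collapse = "")
}

test_that("spacer detection recovers a planted Ser/Thr/Val block", {
  x <- paste0(ga_rich(160), stv_block(30), ga_rich(160), ga_rich(110))
  sp <- detect_spacers(seq_tbl("p", x, "protein"))
  expect_equal(nrow(sp), 1L)
  # recovered interval covers the planted block within half a window
  expect_lte(abs(sp$start - 160), 13)
  expect_lte(abs(sp$end - 190), 13)
  expect_lt(sp$gly_ala_fraction, 0.25)
  expect_gt(sp$stv_fraction, 0.8)
  # pure repetitive core has no spacers
  expect_equal(nrow(detect_spacers(seq_tbl("p", ga_rich(600), "protein"))), 0L)
  expect_error(detect_spacers(seq_tbl("p", ga_rich(100), "protein")), "shorter")
})

test_that("nearby planted blocks merge and margins are respected", {
  x <- paste0(ga_rich(170), stv_block(25), "GAGA", stv_block(25),
              ga_rich(170), ga_rich(110))
  sp <- detect_spacers(seq_tbl("p", x, "protein"), merge_gap = 5)
  expect_equal(nrow(sp), 1L)
  expect_gt(sp$end - sp$start, 40)

  set.seed(5)
  for (i in 1:20) {
    pos <- sample(160:400, 1)
    x <- paste0(ga_rich(pos), stv_block(30), ga_rich(700 - pos - 30))
    sp <- detect_spacers(seq_tbl("p", x, "protein"))
    expect_true(all(sp$start >= 150))
    expect_true(all(sp$end <= 700 - 100))
  }
})

test_that("spacer homogeneity is mean pairwise alignment identity", {
  sp <- tibble::tibble(id = "p", sequence = rep(stv_block(30), 3))
  expect_equal(spacer_homogeneity(sp)$mean_identity, 1)

  one_sub <- sub("^S", "A", stv_block(30))
  sp2 <- tibble::tibble(id = "p", sequence = c(stv_block(30), one_sub))
  expect_equal(spacer_homogeneity(sp2)$mean_identity, 29 / 30)

  single <- tibble::tibble(id = "p", sequence = stv_block(30))
  expect_true(is.na(spacer_homogeneity(single)$mean_identity))
})

test_that("tandem repeat detector handles exact and degenerate arrays", {
  s <- seq_tbl("r", strrep("GASTQ", 5))
  blk <- find_tandem_repeats(s, min_period = 5)
  expect_equal(nrow(blk), 1L)
  expect_equal(blk$period, 5L)
  expect_equal(blk$copies, 5)
  expect_equal(blk$mean_identity, 1)
  expect_equal(blk$consensus, "GASTQ")

  # planted period-28 x 12 with 10% per-copy substitutions, checked against
  # the exhaustive period-scan oracle
  set.seed(17)
  ok <- 0L
  for (i in 1:25) {
    unit <- random_protein(28, c("G", "A", "S", "T", "Q", "V", "L"))
    copies <- replicate(12, {
      ch <- strsplit(unit, "")[[1]]
      hit <- which(runif(28) < 0.10)
      ch[hit] <- sample(c("G", "A", "S", "T", "Q", "V", "L", "Y", "P"),
                        length(hit), replace = TRUE)
      paste(ch, collapse = "")
    })
    x <- paste(copies, collapse = "")
    blk <- find_tandem_repeats(seq_tbl("r", x), min_period = 5,
                               max_period = 60)
    blk <- blk[which.max(blk$copies * blk$period * blk$mean_identity), ]
    oracle <- oracle_best_period(x)
    expect_equal(oracle$period, 28)
    if (nrow(blk) && abs(blk$period - 28) <= 1 && blk$copies >= 10 &&
        blk$mean_identity >= 0.8) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 24L)
})

test_that("random sequences rarely yield repeat blocks (null control)", {
  set.seed(23)
  hits <- 0L
  for (i in 1:60) {
    x <- random_protein(500)
    blk <- find_tandem_repeats(seq_tbl("r", x), min_period = 5)
    if (nrow(blk)) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.05)
})

test_that("modularity classification uses the strict period bounds", {
  blk <- function(period, copies) {
    tibble::tibble(id = "s", start = 0L, end = period * copies,
                   period = period, copies = copies, consensus = "X",
                   mean_identity = 0.9)
  }
  expect_equal(classify_modularity(blk(200, 2))$modularity, "higher_order")
  expect_equal(classify_modularity(blk(28, 12))$modularity, "short_unit")
  expect_equal(classify_modularity(blk(160, 2))$modularity, "none")
  expect_equal(classify_modularity(blk(28, 10))$modularity, "none")
  both <- dplyr::bind_rows(blk(200, 2), blk(28, 12))
  expect_equal(classify_modularity(both)$modularity, "higher_order")
})

test_that("generator output shows the homogenized-spacer signature", {
  # spacer mutation rate below repeat rate implies spacer homogeneity above
  # repeat-copy identity
  set.seed(31)
  for (seed in 1:5) {
    gen <- generate_spidroin(spidroin_spec(repeat_rate = 0.08,
                                           spacer_rate = 0.005),
                             seed = seed)
    sp <- detect_spacers(gen$protein)
    hom <- spacer_homogeneity(sp)$mean_identity
    blk <- find_tandem_repeats(gen$protein)
    main <- blk[which.max(blk$copies * blk$period * blk$mean_identity), ]
    expect_gt(hom, main$mean_identity)
  }
})
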
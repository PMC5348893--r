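#' Detect Ser/Thr/Val-rich spacer regions
#'
#' Spacers interrupt the glycine/alanine-rich repetitive region of minor
#' ampullate spidroins: they are low in Gly+Ala, rich in Ser/Thr/Val, lie
#' outside the conserved N/C-terminal domains, and are nearly identical in
#' sequence within one protein. The detector slides a window over the
#' non-terminal span, flags windows whose Gly+Ala fraction is at most
#' `ga_ceiling`, merges flagged window starts separated by at most
#' `merge_gap`, trims region edges by a centered-window refinement, and
#' drops regions shorter than `min_len`.
#'
#' @param seqs A protein sequence table.
#' @param n_margin,c_margin N-/C-terminal margins (aa) excluded from the
#'   scan; spidroin terminal domains are roughly this long.
#' @param window Sliding window size (aa).
#' @param ga_ceiling Maximum Gly+Ala fraction of a flagged window.
#' @param min_len Minimum spacer length (aa).
#' @param merge_gap Merge flagged windows separated by at most this many
#'   positions.
#' @return A tibble `id`, `start`, `end` (0-based half-open), `sequence`,
#'   `gly_ala_fraction`, `stv_fraction`.
#' @export
detect_spacers <- function(seqs, n_margin = 150L, c_margin = 100L,
                           window = 25L, ga_ceiling = 0.25, min_len = 15L,
                           merge_gap = 5L) {
  if (!all(seqs$alphabet == "protein")) {
    abort("detect_spacers() requires protein sequences")
  }
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    chars <- strsplit(seqs$residues[i], "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n <= n_margin + c_margin + window) {
      abort(paste0("sequence '", seqs$id[i],
                   "' is shorter than the terminal margins plus one window"))
    }
    is_ga <- chars %in% c("G", "A")
    cs <- cumsum(c(0L, is_ga))
    # window starts (1-based) restricted to the non-terminal span
    w_starts <- seq.int(n_margin + 1L, n - c_margin - window + 1L)
    ga_frac <- (cs[w_starts + window] - cs[w_starts]) / window
    flagged <- w_starts[ga_frac <= ga_ceiling]
    if (!length(flagged)) return(NULL)
    runs <- split(flagged, cumsum(c(1L, diff(flagged) > merge_gap + 1L)))
    purrr::map_dfr(runs, function(fs) {
      lo <- min(fs)
      hi <- max(fs) + window - 1L            # 1-based inclusive residue span
      # edge refinement: shrink while the centered window around an edge
      # residue still exceeds the ceiling
      half <- window %/% 2L
      centered <- function(pos) {
        a <- max(1L, pos - half); b <- min(n, pos + half)
        (cs[b + 1L] - cs[a]) / (b - a + 1L)
      }
      while (lo < hi && centered(lo) > ga_ceiling) lo <- lo + 1L
      while (hi > lo && centered(hi) > ga_ceiling) hi <- hi - 1L
      lo <- max(lo, n_margin + 1L)
      hi <- min(hi, n - c_margin)
      # sharpen edges: spacers are Gly/Ala-poor, their repeat flanks
      # Gly/Ala-rich, so snap boundaries to the contiguous non-G/A run
      while (lo <= hi && chars[lo] %in% c("G", "A")) lo <- lo + 1L
      while (hi >= lo && chars[hi] %in% c("G", "A")) hi <- hi - 1L
      while (lo - 1L > n_margin && !chars[lo - 1L] %in% c("G", "A")) {
        lo <- lo - 1L
      }
      while (hi + 1L <= n - c_margin && !chars[hi + 1L] %in% c("G", "A")) {
        hi <- hi + 1L
      }
      if (hi - lo + 1L < min_len) return(NULL)
      region <- chars[lo:hi]
      tibble(id = seqs$id[i], start = lo - 1L, end = hi,
             sequence = paste(region, collapse = ""),
             gly_ala_fraction = mean(region %in% c("G", "A")),
             stv_fraction = mean(region %in% c("S", "T", "V")))
    })
  })
}

#' Spacer homogeneity
#'
#' Mean pairwise global-alignment identity among the spacers of each
#' sequence. Near-perfect values are the within-protein homogenization
#' signature of intragenic concerted evolution. Sequences with fewer than
#' two spacers get `NA` (a single spacer has no pairs).
#'
#' @param spacers Output of [detect_spacers()] (columns `id`, `sequence`).
#' @param ... Passed to [global_align()].
#' @return A tibble `id`, `n_spacers`, `mean_identity`.
#' @export
spacer_homogeneity <- function(spacers, ...) {
  spacers |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_spacers = dplyr::n(),
      mean_identity = {
        ss <- .data$sequence
        if (length(ss) < 2L) NA_real_ else {
          pairs <- utils::combn(length(ss), 2L)
          mean(apply(pairs, 2L, function(p) {
            alignment_identity(global_align(ss[p[1]], ss[p[2]], ...))
          }))
        }
      },
      .groups = "drop")
}

#' Detect tandem repeats by seeded consensus extension
#'
#' A seed-and-extend detector for the tandem/ensemble repeats of spidroin
#' repetitive regions. Candidate periods are seeded by the spacings between
#' recurring k-mers (k = 4); each candidate is extended copy-by-copy in both
#' directions, accepting a new period-length window while its identity to
#' the running per-column majority consensus stays at or above
#' `min_identity`. A trailing partial copy is counted fractionally.
#' Overlapping blocks are resolved by keeping the higher
#' `copies * period * identity` score.
#'
#' @param seqs A protein sequence table.
#' @param min_period,max_period Period bounds (aa).
#' @param min_copies Minimum copy number (fractional final copies count).
#' @param min_identity Minimum mean per-copy identity to the consensus.
#' @return A tibble `id`, `start`, `end`, `period`, `copies`, `consensus`,
#'   `mean_identity`, one row per retained block.
#' @export
find_tandem_repeats <- function(seqs, min_period = 5L, max_period = 600L,
                                min_copies = 2, min_identity = 0.70) {
  if (!all(seqs$alphabet == "protein")) {
    abort("find_tandem_repeats() requires protein sequences")
  }
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    chars <- strsplit(seqs$residues[i], "", fixed = TRUE)[[1]]
    blocks <- scan_tandem_one(chars, min_period, max_period,
                              min_copies, min_identity)
    if (is.null(blocks)) return(NULL)
    dplyr::bind_cols(tibble(id = seqs$id[i]), blocks)
  })
}

scan_tandem_one <- function(chars, min_period, max_period,
                            min_copies, min_identity, k = 4L) {
  n <- length(chars)
  if (n < 2L * min_period) return(NULL)
  x <- paste(chars, collapse = "")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(x, starts, starts + k - 1L)
  pos_by_kmer <- split(starts, kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= 2L]
  if (!length(pos_by_kmer)) return(NULL)
  cand <- purrr::map_dfr(pos_by_kmer, function(p) {
    d <- diff(p)
    keep <- d >= min_period & d <= min(max_period, n %/% 2L)
    if (!any(keep)) return(NULL)
    tibble(start = p[-length(p)][keep], period = d[keep])
  })
  if (!nrow(cand)) return(NULL)
  cand <- dplyr::distinct(cand)
  # one attempt per (period, phase): extensions from the same phase land on
  # the same block
  cand <- cand |>
    dplyr::mutate(phase = .data$start %% .data$period) |>
    dplyr::distinct(.data$period, .data$phase, .keep_all = TRUE) |>
    dplyr::arrange(.data$period, .data$start)
  blocks <- purrr::map_dfr(seq_len(nrow(cand)), function(j) {
    extend_tandem(chars, cand$start[j], cand$period[j], min_identity,
                  min_period)
  })
  if (!nrow(blocks)) return(NULL)
  blocks <- blocks |>
    dplyr::filter(.data$copies >= min_copies,
                  .data$mean_identity >= min_identity) |>
    dplyr::mutate(score = .data$copies * .data$period * .data$mean_identity) |>
    dplyr::arrange(dplyr::desc(.data$score))
  if (!nrow(blocks)) return(NULL)
  kept <- integer(0)
  for (j in seq_len(nrow(blocks))) {
    if (!length(kept) ||
        all(blocks$start[j] >= blocks$end[kept] |
            blocks$end[j] <= blocks$start[kept])) {
      kept <- c(kept, j)
    }
  }
  blocks[kept, c("start", "end", "period", "copies", "consensus",
                 "mean_identity")] |>
    dplyr::arrange(.data$start)
}

# grow a block around seed `s` (1-based) with period `p`; returns a one-row
# tibble with 0-based half-open coordinates, or NULL
extend_tandem <- function(chars, s, p, min_identity, min_period = 1L) {
  n <- length(chars)
  if (s + p - 1L > n) return(NULL)
  copies <- list(chars[s:(s + p - 1L)])
  consensus <- copies[[1]]
  first <- s
  # right extension
  nxt <- s + p
  while (nxt + p - 1L <= n) {
    w <- chars[nxt:(nxt + p - 1L)]
    if (mean(w == consensus) < min_identity) break
    copies <- c(copies, list(w))
    consensus <- column_majority(copies)
    nxt <- nxt + p
  }
  # left extension
  prv <- first - p
  while (prv >= 1L) {
    w <- chars[prv:(prv + p - 1L)]
    if (mean(w == consensus) < min_identity) break
    copies <- c(list(w), copies)
    consensus <- column_majority(copies)
    first <- prv
    prv <- prv - p
  }
  if (length(copies) < 2L) return(NULL)
  last_end <- first + p * length(copies) - 1L   # 1-based inclusive
  # fractional trailing copy
  frac <- 0
  tail_len <- min(n - last_end, p - 1L)
  if (tail_len >= max(3L, ceiling(p / 4))) {
    w <- chars[(last_end + 1L):(last_end + tail_len)]
    if (mean(w == consensus[seq_len(tail_len)]) >= min_identity) {
      frac <- tail_len / p
      last_end <- last_end + tail_len
    }
  }
  ids <- vapply(copies, function(w) mean(w == consensus), numeric(1))
  # period-multiple degeneracy: if the consensus is itself periodic at a
  # divisor -- at least as strongly as the copies match the consensus --
  # the divisor is the fundamental period
  divisors <- setdiff(seq_len(p %/% 2L), 0L)
  divisors <- divisors[p %% divisors == 0L & divisors >= min_period]
  for (d in divisors) {
    m <- matrix(consensus, nrow = p %/% d, ncol = d, byrow = TRUE)
    cons_d <- apply(m, 2L, function(col) names(which.max(table(col))))
    fold_id <- mean(m == matrix(cons_d, nrow(m), d, byrow = TRUE))
    if (fold_id >= mean(ids)) {
      return(extend_tandem(chars, s, d, min_identity, min_period))
    }
  }
  tibble(start = first - 1L, end = last_end,
         period = p, copies = length(copies) + frac,
         consensus = paste(consensus, collapse = ""),
         mean_identity = mean(ids))
}

column_majority <- function(copies) {
  m <- do.call(rbind, copies)
  apply(m, 2L, function(col) names(which.max(table(col))))
}

#' Classify repeat modularity
#'
#' Spidroin repetitive regions fall into two organizational modes: a higher
#' order ensemble unit (period > 160 aa, repeated at least once more, i.e.
#' at least 2 copies) or an array of short units only (period <= 30 aa
#' repeated more than 10 times). The boundaries are strict: a 160-aa period
#' is not higher-order.
#'
#' @param blocks Output of [find_tandem_repeats()].
#' @return A tibble `id`, `modularity` in
#'   `c("higher_order", "short_unit", "none")`.
#' @export
classify_modularity <- function(blocks) {
  blocks |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      modularity = {
        higher <- any(.data$period > 160 & .data$copies >= 2)
        short <- any(.data$period <= 30 & .data$copies > 10)
        if (higher) "higher_order" else if (short) "short_unit" else "none"
      },
      .groups = "drop")
}
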
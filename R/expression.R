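#' Assign reads to paralog references by best ungapped match
#'
#' Places each read at the forward-orientation, ungapped position with the
#' fewest mismatches across all references, mimicking a best-single-hit
#' aligner contract: every candidate placement is considered, only the best
#' is reported. Ties across references are broken by reference input order
#' and ties within a reference by the leftmost position, so assignment is
#' deterministic. Reads exceeding `max_mismatch` everywhere (or longer than
#' every reference) are reported as `"unassigned"`.
#'
#' @param reads A nucleotide sequence table of reads.
#' @param references A nucleotide sequence table of reference loci; order
#'   defines tie-breaking priority.
#' @param max_mismatch Maximum mismatches for a valid placement.
#' @param reverse_complement Also search the reverse complement of each
#'   read (off by default; library orientation is assumed forward).
#' @return A tibble `read_id`, `reference_id` (or `"unassigned"`), `start`
#'   (0-based on the reference, `NA` if unassigned), `mismatches`,
#'   `read_length`.
#' @export
assign_reads <- function(reads, references, max_mismatch = 3L,
                         reverse_complement = FALSE) {
  stopifnot(nrow(references) >= 1L)
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(0), reference_id = character(0),
                  start = integer(0), mismatches = integer(0),
                  read_length = integer(0)))
  }
  refs <- lapply(references$residues, Biostrings::DNAString)
  ref_len <- vapply(refs, length, integer(1))
  too_long <- nchar(reads$residues) > max(ref_len)
  if (any(too_long)) {
    warn(paste0(sum(too_long), " read(s) longer than every reference; ",
                "left unassigned"))
  }
  purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    rl <- nchar(reads$residues[i])
    best_ref <- NA_integer_; best_start <- NA_integer_; best_mm <- NA_integer_
    if (rl <= max(ref_len)) {
      variants <- list(Biostrings::DNAString(reads$residues[i]))
      if (reverse_complement) {
        variants <- c(variants,
                      list(Biostrings::reverseComplement(variants[[1]])))
      }
      for (mm in 0:max_mismatch) {
        for (r in seq_along(refs)) {
          if (rl > ref_len[r]) next
          for (v in variants) {
            hits <- Biostrings::matchPattern(v, refs[[r]], max.mismatch = mm)
            if (length(hits)) {
              best_ref <- r
              best_start <- Biostrings::start(hits)[1] - 1L
              best_mm <- mm
              break
            }
          }
          if (!is.na(best_ref)) break
        }
        if (!is.na(best_ref)) break
      }
    }
    tibble(read_id = reads$id[i],
           reference_id = if (is.na(best_ref)) "unassigned" else
             references$id[best_ref],
           start = best_start,
           mismatches = best_mm,
           read_length = rl)
  })
}

#' Count assigned reads, whole-gene and 3'-window
#'
#' Whole-gene counts are assigned reads per reference. The 3'-window count
#' restricts to reads whose placement overlaps the 3'-most `window` bases
#' of the reference by at least half the read length; comparing paralog
#' ratios within that window guards against gene-length and 3'-bias
#' artefacts.
#'
#' @param assignments Output of [assign_reads()].
#' @param references The reference sequence table used for assignment.
#' @param window 3'-window width in bases.
#' @return A tibble `reference_id`, `n_total`, `n_window`, plus attribute
#'   `total_reads`.
#' @export
count_reads <- function(assignments, references, window = 500L) {
  ref_len <- setNames(nchar(references$residues), references$id)
  counts <- purrr::map_dfr(references$id, function(ref) {
    a <- dplyr::filter(assignments, .data$reference_id == ref)
    win_lo <- ref_len[[ref]] - window          # 0-based window start
    overlap <- pmin(a$start + a$read_length, ref_len[[ref]]) -
      pmax(a$start, win_lo)
    tibble(reference_id = ref,
           n_total = nrow(a),
           n_window = sum(overlap >= a$read_length / 2))
  })
  attr(counts, "total_reads") <- nrow(assignments)
  counts
}

#' Paralog abundance ratio
#'
#' Ratio of read counts between two references, either over whole genes or
#' over the 3'-most window (see [count_reads()]). A zero denominator yields
#' `NA` (an undefined ratio), not an error.
#'
#' @param counts Output of [count_reads()].
#' @param numerator,denominator Reference ids.
#' @param mode `"whole"` or `"window"`.
#' @return A single numeric ratio (`NA` if undefined).
#' @export
abundance_ratio <- function(counts, numerator, denominator,
                            mode = c("whole", "window")) {
  mode <- match.arg(mode)
  col <- if (mode == "whole") "n_total" else "n_window"
  num <- counts[[col]][match(numerator, counts$reference_id)]
  den <- counts[[col]][match(denominator, counts$reference_id)]
  if (is.na(num) || is.na(den)) abort("reference id not found in counts")
  if (den == 0) {
    inform("undefined ratio: zero denominator count")
    return(NA_real_)
  }
  num / den
}
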
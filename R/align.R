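#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under affine gap costs: the first
#' residue of a gap costs `gap_open` and each further residue `gap_extend`
#' (both negative). The optimisation is delegated to
#' [Biostrings::pairwiseAlignment()] with the gap parameters remapped to
#' that convention; the result is deterministic for fixed inputs.
#'
#' @param a,b Sequences (character strings, or one-row sequence tables).
#' @param match,mismatch Substitution scores.
#' @param gap_open Score for the first residue of a gap (negative).
#' @param gap_extend Score for each subsequent gap residue (negative).
#' @return A `pairwise_alignment` object: list with `gapped_a`, `gapped_b`,
#'   `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  a <- as_residue_string(a)
  b <- as_residue_string(b)
  go <- abs(gap_open)
  ge <- abs(gap_extend)
  if (go < ge) abort("`gap_open` must be at least as costly as `gap_extend`")
  letters <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  sm <- matrix(mismatch, length(letters), length(letters),
               dimnames = list(letters, letters))
  diag(sm) <- match
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = sm,
    gapOpening = go - ge, gapExtension = ge)
  structure(
    list(gapped_a = as.character(Biostrings::alignedPattern(aln)),
         gapped_b = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln)),
    class = "pairwise_alignment")
}

as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "residues" %in% names(x))
    x <- x$residues
  }
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  toupper(x)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", sep = "")
  cat(" a: ", x$gapped_a, "\n b: ", x$gapped_b, "\n", sep = "")
  invisible(x)
}

#' Alignment identity and p-distance
#'
#' `alignment_identity()` is the fraction of alignment columns with
#' identical residues (gap columns count against identity).
#' `p_distance()` is the proportion of differing sites among compared
#' sites, where columns containing a gap in either sequence are excluded
#' (pairwise deletion) -- the uncorrected distance behind printed
#' "pairwise difference" percentages.
#'
#' @param alignment A `pairwise_alignment` object.
#' @return A fraction in `[0, 1]`.
#' @export
alignment_identity <- function(alignment) {
  a <- strsplit(alignment$gapped_a, "")[[1]]
  b <- strsplit(alignment$gapped_b, "")[[1]]
  mean(a == b & a != "-")
}

#' @rdname alignment_identity
#' @export
p_distance <- function(alignment) {
  a <- strsplit(alignment$gapped_a, "")[[1]]
  b <- strsplit(alignment$gapped_b, "")[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) abort("no gap-free columns to compare")
  mean(a[keep] != b[keep])
}

#' All-pairs p-distance matrix
#'
#' Aligns every pair of sequences globally and collects p-distances into a
#' symmetric matrix, ready for [neighbor_joining()].
#'
#' @param seqs A sequence table.
#' @param ... Passed to [global_align()].
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance_matrix <- function(seqs, ...) {
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pd <- p_distance(global_align(seqs$residues[i], seqs$residues[j], ...))
      d[i, j] <- d[j, i] <- pd
    }
  }
  d
}

#' Within- and between-cluster divergence
#'
#' Mean pairwise p-distance over all within-cluster pairs (per cluster) and
#' over all cross-cluster pairs. Distinct paralogous loci show much higher
#' between- than within-cluster divergence. Clusters with a single member
#' have no within pairs and get `NA`.
#'
#' @param seqs A sequence table.
#' @param labels A tibble mapping `id` to `cluster`.
#' @param ... Passed to [global_align()].
#' @return A list with `within` (tibble `cluster`, `mean_p_distance`,
#'   `n_pairs`) and `between` (scalar mean over cross-cluster pairs, `NA`
#'   if there are none).
#' @export
cluster_divergence <- function(seqs, labels, ...) {
  stopifnot(all(c("id", "cluster") %in% names(labels)))
  missing <- setdiff(seqs$id, labels$id)
  if (length(missing)) abort(paste0("no cluster for sequence: ", missing[1]))
  cl <- setNames(labels$cluster, labels$id)[seqs$id]
  d <- p_distance_matrix(seqs, ...)
  n <- nrow(seqs)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  same <- cl[pairs[, 1]] == cl[pairs[, 2]]
  within <- tibble(cluster = as.character(cl[pairs[same, 1]]),
                   p = d[pairs[same, , drop = FALSE]]) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean_p_distance = mean(.data$p),
                     n_pairs = dplyr::n(), .groups = "drop")
  singletons <- setdiff(unique(as.character(cl)), within$cluster)
  if (length(singletons)) {
    within <- dplyr::bind_rows(
      within,
      tibble(cluster = singletons, mean_p_distance = NA_real_, n_pairs = 0L))
  }
  between <- if (any(!same)) mean(d[pairs[!same, , drop = FALSE]]) else NA_real_
  list(within = dplyr::arrange(within, .data$cluster), between = between)
}
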
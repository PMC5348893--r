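#' Motif grammar of spidroin repetitive regions
#'
#' The repetitive regions of minor ampullate spidroins are dominated by four
#' short amino-acid "words": `GGX` (3-1 helix forming, X any residue),
#' poly-alanine runs `POLY_A` (A_n, n >= 4, beta-sheet), glycine-alanine
#' couplets `GA_RUN` ((GA)_n, n >= 2, beta-sheet), and `GPG` (beta-spiral,
#' elasticity-conferring). `scan_motifs()` annotates a protein with a greedy
#' left-to-right, maximally extended, non-overlapping scan per class:
#' `AAAAA` is one poly-A of length 5 and `GAGAGA` one (GA)-run of length 6.
#' Classes are scanned independently, so annotations of different classes
#' may overlap; annotations of the same class never do.
#'
#' @param seqs A protein sequence table (see [seq_tbl()]).
#' @param classes Motif classes to scan.
#' @return A tibble with columns `id`, `motif_class`, `start`, `end`
#'   (0-based half-open) and `matched`.
#' @export
scan_motifs <- function(seqs,
                        classes = c("GGX", "POLY_A", "GA_RUN", "GPG")) {
  if (!all(seqs$alphabet == "protein")) {
    abort("scan_motifs() requires protein sequences")
  }
  classes <- match.arg(classes, several.ok = TRUE)
  patterns <- c(GGX = "GG[A-Z]", POLY_A = "A{4,}",
                GA_RUN = "(?:GA){2,}", GPG = "GPG")
  empty <- tibble(id = character(0), motif_class = character(0),
                  start = integer(0), end = integer(0),
                  matched = character(0))
  out <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    x <- seqs$residues[i]
    purrr::map_dfr(classes, function(cl) {
      m <- gregexpr(patterns[[cl]], x, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      start <- as.integer(m) - 1L
      len <- attr(m, "match.length")
      tibble(id = seqs$id[i], motif_class = cl,
             start = start, end = start + len,
             matched = substring(x, start + 1L, start + len))
    })
  })
  if (nrow(out)) out else empty
}

#' Motif coverage of a sequence or region
#'
#' Fraction of residues inside annotations of one motif class, relative to
#' the whole sequence or to a supplied region (0-based half-open
#' `region_start`/`region_end`, applied to every sequence). Annotations are
#' clipped to the region. Use [format_percent()] for the conventional
#' two-decimal percent rendering.
#'
#' @inheritParams scan_motifs
#' @param motif_class One motif class.
#' @param region_start,region_end Optional region bounds.
#' @return A tibble `id`, `motif_class`, `coverage` (fraction in `[0, 1]`).
#' @export
motif_coverage <- function(seqs, motif_class,
                           region_start = NULL, region_end = NULL) {
  motif_class <- match.arg(motif_class, c("GGX", "POLY_A", "GA_RUN", "GPG"))
  ann <- scan_motifs(seqs, motif_class)
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    n <- nchar(seqs$residues[i])
    lo <- region_start %||% 0L
    hi <- region_end %||% n
    if (hi <= lo) abort("empty region")
    a <- dplyr::filter(ann, .data$id == seqs$id[i])
    covered <- if (nrow(a)) {
      sum(pmax(0L, pmin(a$end, hi) - pmax(a$start, lo)))
    } else 0L
    tibble(id = seqs$id[i], motif_class = motif_class,
           coverage = covered / (hi - lo))
  })
}

#' Species-level motif coverage averages
#'
#' Unweighted mean of per-sequence motif coverages within each species, the
#' convention used when a species is described by more than one spidroin
#' variant.
#'
#' @inheritParams motif_coverage
#' @param species_map A tibble mapping `id` to `species`.
#' @return A tibble `species`, `motif_class`, `mean_coverage`, `n_sequences`.
#' @export
species_motif_average <- function(seqs, species_map, motif_class) {
  stopifnot(all(c("id", "species") %in% names(species_map)))
  missing <- setdiff(seqs$id, species_map$id)
  if (length(missing)) {
    abort(paste0("no species assigned for sequence: ", missing[1]))
  }
  motif_coverage(seqs, motif_class) |>
    dplyr::left_join(species_map, by = "id") |>
    dplyr::group_by(.data$species, .data$motif_class) |>
    dplyr::summarise(mean_coverage = mean(.data$coverage),
                     n_sequences = dplyr::n(), .groups = "drop")
}

#' Round-half-away-from-zero percent formatting
#'
#' @param x Fractions in `[0, 1]`.
#' @param digits Decimal places.
#' @return Character vector of percents, e.g. `"12.79"`.
#' @export
format_percent <- function(x, digits = 2) {
  p <- x * 100
  scale <- 10^digits
  sprintf(paste0("%.", digits, "f"),
          sign(p) * floor(abs(p) * scale + 0.5 + 1e-9) / scale)
}

#' Amino-acid composition
#'
#' @inheritParams scan_motifs
#' @return A long tibble `id`, `residue`, `count`, `fraction`; fractions sum
#'   to one within each sequence.
#' @export
composition <- function(seqs) {
  if (!all(seqs$alphabet == "protein")) {
    abort("composition() requires protein sequences")
  }
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    chars <- strsplit(seqs$residues[i], "", fixed = TRUE)[[1]]
    tab <- table(chars)
    tibble(id = seqs$id[i], residue = names(tab),
           count = as.integer(tab), fraction = as.integer(tab) / length(chars))
  })
}

#' Codon usage and third-position A/T bias
#'
#' `codon_usage()` counts codons of in-frame coding sequences (trailing
#' partial codons dropped, codons containing ambiguity codes skipped).
#' `third_position_at()` summarises, per encoded amino acid, the fraction of
#' its codons whose third base is A or T -- the bias reported for spidroin
#' alanine and glycine codons.
#'
#' @param seqs A nucleotide sequence table of coding sequences.
#' @return `codon_usage()`: tibble `id`, `codon`, `aa`, `count`.
#' @export
codon_usage <- function(seqs) {
  if (!all(seqs$alphabet == "nucleotide")) {
    abort("codon_usage() requires nucleotide sequences")
  }
  code <- Biostrings::GENETIC_CODE
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    x <- chartr("U", "T", seqs$residues[i])
    n_codons <- nchar(x) %/% 3L
    if (n_codons == 0L) return(NULL)
    starts <- 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(x, starts, starts + 2L)
    codons <- codons[codons %in% names(code)]
    tab <- table(codons)
    tibble(id = seqs$id[i], codon = names(tab),
           aa = unname(code[names(tab)]), count = as.integer(tab))
  })
}

#' @rdname codon_usage
#' @param usage Output of `codon_usage()`.
#' @return `third_position_at()`: tibble `id`, `aa`, `n_codons`,
#'   `third_position_at` (fraction in `[0, 1]`).
#' @export
third_position_at <- function(usage) {
  usage |>
    dplyr::mutate(third_at = substr(.data$codon, 3, 3) %in% c("A", "T")) |>
    dplyr::group_by(.data$id, .data$aa) |>
    dplyr::summarise(
      n_codons = sum(.data$count),
      third_position_at = sum(.data$count[.data$third_at]) / sum(.data$count),
      .groups = "drop")
}

# Kyte-Doolittle residue hydropathy values
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy profile
#'
#' Centered moving average of Kyte-Doolittle residue hydropathy values;
#' positions whose window would run off either end are omitted. Positive
#' scores are hydrophobic. Spacer regions of most minor ampullate spidroins
#' show up as hydrophilic troughs against the repetitive region.
#'
#' @inheritParams scan_motifs
#' @param window Odd window size (default 7).
#' @return A tibble `id`, `position` (0-based window center), `score`.
#' @export
hydropathy_profile <- function(seqs, window = 7L) {
  if (window %% 2L != 1L || window < 1L) abort("`window` must be odd")
  if (!all(seqs$alphabet == "protein")) {
    abort("hydropathy_profile() requires protein sequences")
  }
  half <- window %/% 2L
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    chars <- strsplit(seqs$residues[i], "", fixed = TRUE)[[1]]
    vals <- unname(KYTE_DOOLITTLE[chars])
    if (anyNA(vals)) {
      abort(paste0("residue without hydropathy value in '", seqs$id[i], "'"))
    }
    n <- length(vals)
    if (n < window) return(NULL)
    cs <- cumsum(c(0, vals))
    centers <- seq.int(half + 1L, n - half)
    score <- (cs[centers + half + 1L] - cs[centers - half]) / window
    tibble(id = seqs$id[i], position = centers - 1L, score = score)
  })
}
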
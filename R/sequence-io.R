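IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")
IUPAC_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "J",
              "U", "O", "*", "-")

#' Build a sequence table
#'
#' Sequence sets are plain tibbles with columns `id`, `alphabet`
#' (`"nucleotide"` or `"protein"`) and `residues` (uppercase IUPAC).
#' `seq_tbl()` validates residues, uppercases them, and infers the alphabet
#' when it is not supplied: sequences whose residues all belong to the
#' nucleotide IUPAC set are called nucleotide, anything else protein.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of sequences.
#' @param alphabet Optional `"nucleotide"`/`"protein"`, recycled.
#' @return A tibble with columns `id`, `alphabet`, `residues`.
#' @export
seq_tbl <- function(id, residues, alphabet = NULL) {
  if (length(id) != length(residues)) {
    abort("`id` and `residues` must have the same length.")
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id: ", id[duplicated(id)][1]))
  }
  id <- unname(id)
  residues <- unname(toupper(gsub("[[:space:]]", "", residues)))
  if (any(!nzchar(residues))) {
    abort(paste0("empty sequence: ", id[!nzchar(residues)][1]))
  }
  if (is.null(alphabet)) {
    alphabet <- vapply(residues, infer_alphabet, character(1), USE.NAMES = FALSE)
  } else {
    alphabet <- rep_len(match.arg(alphabet, c("nucleotide", "protein")),
                        length(id))
  }
  for (i in seq_along(residues)) {
    check_alphabet(residues[i], alphabet[i], id[i])
  }
  tibble(id = as.character(id), alphabet = alphabet, residues = residues)
}

# inference is deliberately conservative: only unambiguous nucleotide
# residues count, since most IUPAC ambiguity codes are also amino acids
infer_alphabet <- function(x) {
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  if (all(chars %in% c("A", "C", "G", "T", "U", "N", "-")))
    "nucleotide" else "protein"
}

check_alphabet <- function(x, alphabet, id) {
  valid <- if (alphabet == "nucleotide") IUPAC_NT else IUPAC_AA
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% valid)
  if (length(bad)) {
    abort(sprintf("non-IUPAC character '%s' at position %d in '%s'",
                  chars[bad[1]], bad[1], id))
  }
  invisible(TRUE)
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns a sequence table (see [seq_tbl()]); the id is the
#' first whitespace-delimited token of each header, residues are uppercased
#' and whitespace-stripped, and record order is preserved. `write_fasta()`
#' writes one, wrapped at `width` columns. Reading back a written table
#' recovers it exactly.
#'
#' @param path File path.
#' @param seqs A sequence table.
#' @param width Line-wrap width for writing.
#' @return `read_fasta()`: a sequence tibble. `write_fasta()`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("cannot parse FASTA: ",
                                                   conditionMessage(e))))
  if (length(set) == 0L) abort(paste0("no records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]))
  }
  seq_tbl(ids, as.character(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate coding sequences
#'
#' Standard genetic code; the trailing partial codon is dropped, stop codons
#' render as `*`, and any ambiguous codon (e.g. one containing N) renders as
#' `X`. RNA input (U) is accepted.
#'
#' @param seqs A nucleotide sequence table.
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return A protein sequence table with the same ids.
#' @export
translate_cds <- function(seqs, frame = 0L) {
  if (!all(seqs$alphabet == "nucleotide")) {
    abort("translate_cds() requires nucleotide sequences")
  }
  stopifnot(frame %in% 0:2)
  prot <- vapply(seqs$residues, function(x) {
    x <- chartr("U", "T", x)
    n <- nchar(x) - frame
    n <- (n %/% 3L) * 3L
    if (n <= 0L) return("")
    cds <- substr(x, frame + 1L, frame + n)
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       if.fuzzy.codon = "X"))
  }, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(prot))) {
    abort(paste0("sequence too short to translate: ",
                 seqs$id[!nzchar(prot)][1]))
  }
  tibble(id = seqs$id, alphabet = "protein", residues = prot)
}

#' Locate the longest open reading frame
#'
#' Scans reading frames 0-2 of the given strand (and of the reverse
#' complement when `both_strands = TRUE`) for ATG-to-stop open reading
#' frames; the stop codon is included in the interval. Coordinates are
#' 0-based half-open on the input sequence.
#'
#' @param seqs A nucleotide sequence table.
#' @param min_len Minimum ORF length in nucleotides (stop included).
#' @param both_strands Also scan the reverse complement.
#' @return A tibble with one row per sequence: `id`, `start`, `end`,
#'   `length`, `strand`, `frame`.
#' @export
find_longest_orf <- function(seqs, min_len = 300L, both_strands = FALSE) {
  if (!all(seqs$alphabet == "nucleotide")) {
    abort("find_longest_orf() requires nucleotide sequences")
  }
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    x <- chartr("U", "T", seqs$residues[i])
    n <- nchar(x)
    best <- NULL
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      s <- if (strand == "+") x else revcomp_chr(x)
      for (frame in 0:2) {
        hit <- longest_orf_in_frame(s, frame)
        if (is.null(hit)) next
        if (is.null(best) || hit$len > best$len) {
          best <- c(hit, strand = strand, frame = frame)
        }
      }
    }
    if (is.null(best) || best$len < min_len) {
      abort(paste0("no ORF of length >= ", min_len, " in '", seqs$id[i], "'"))
    }
    start <- best$start
    end <- best$start + best$len
    if (best$strand == "-") {   # report on the input strand
      tmp <- n - end
      end <- n - start
      start <- tmp
    }
    tibble(id = seqs$id[i], start = start, end = end, length = best$len,
           strand = best$strand, frame = best$frame)
  })
}

# longest ATG..stop span in one frame; start is a 0-based offset, length in nt
longest_orf_in_frame <- function(x, frame) {
  n <- nchar(x) - frame
  n_codons <- n %/% 3L
  if (n_codons < 2L) return(NULL)
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(x, starts, starts + 2L)
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  is_atg <- codons == "ATG"
  best <- NULL
  open <- NA_integer_
  for (j in seq_len(n_codons)) {
    if (is_stop[j]) {
      if (!is.na(open)) {
        len <- (j - open + 1L) * 3L
        if (is.null(best) || len > best$len) {
          best <- list(start = starts[open] - 1L, len = len)
        }
        open <- NA_integer_
      }
    } else if (is_atg[j] && is.na(open)) {
      open <- j
    }
  }
  best
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Export annotations as BED-like TSV
#'
#' Writes `id`, `start`, `end` and a label column (0-based half-open
#' coordinates) as tab-separated text without a header, the conventional
#' BED-like exchange format for interval annotations.
#'
#' @param annotations A tibble with `id`, `start`, `end` columns.
#' @param path Output path.
#' @param label Name of the column used as the BED label (default: the first
#'   non-coordinate column).
#' @return `path`, invisibly.
#' @export
export_bed <- function(annotations, path, label = NULL) {
  stopifnot(all(c("id", "start", "end") %in% names(annotations)))
  if (is.null(label)) {
    label <- setdiff(names(annotations), c("id", "start", "end"))[1]
  }
  out <- dplyr::select(annotations, "id", "start", "end",
                       dplyr::all_of(label))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
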
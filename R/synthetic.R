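# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# amino-acid pool used for random substitutions and terminal domains
TERMINAL_COMPOSITION <- c(A = 0.12, S = 0.12, L = 0.09, G = 0.08, Q = 0.08,
                          N = 0.06, E = 0.05, R = 0.05, T = 0.05, V = 0.05,
                          I = 0.04, D = 0.04, K = 0.04, F = 0.03, P = 0.03,
                          Y = 0.03, M = 0.02, H = 0.02, W = 0.01, C = 0.01)

#' Specify a synthetic spidroin
#'
#' The generator mirrors the canonical minor ampullate spidroin
#' architecture: a conserved N-terminal domain, a repetitive region of
#' tandem ensemble-repeat copies built from the motif grammar
#' (predominantly (GA)n and GGX, some poly-A, optionally GPG), nearly
#' identical Ser/Thr/Val-rich spacers planted between repeat copies, and a
#' conserved C-terminal domain. Per-site substitution rates let repeat
#' copies diverge while spacers stay homogenized (`spacer_rate` well below
#' `repeat_rate` reproduces the concerted-evolution signature of real
#' spacers).
#'
#' @param n_term_len,c_term_len Terminal domain lengths (aa).
#' @param motif_mix Named weights over `GA_RUN`, `GGX`, `POLY_A`, `GPG`
#'   (normalised to sum to 1).
#' @param repeat_period Ensemble repeat unit length (aa).
#' @param repeat_copies Number of tandem copies.
#' @param spacer_seq Spacer sequence (aa).
#' @param spacer_positions Repeat-copy indices after which a spacer is
#'   inserted (empty for none).
#' @param repeat_rate,spacer_rate,terminal_rate Per-site substitution
#'   probabilities applied to repeat copies, spacer copies, and nothing /
#'   reserved for family evolution respectively; all in `[0, 0.5]`.
#' @param third_at_bias Probability that a back-translated codon carries A
#'   or T at its third position (when the amino acid offers both choices);
#'   spidroin coding sequences are A/T-biased at silent sites.
#' @return A `spidroin_spec` list.
#' @export
spidroin_spec <- function(n_term_len = 150L, c_term_len = 100L,
                          motif_mix = c(GA_RUN = 0.45, GGX = 0.35,
                                        POLY_A = 0.15, GPG = 0.05),
                          repeat_period = 30L, repeat_copies = 12L,
                          spacer_seq = "TTVSTSSSVVSTTVSPSSTSVVSSTTVSST",
                          spacer_positions = c(4L, 8L),
                          repeat_rate = 0.05, spacer_rate = 0.005,
                          terminal_rate = 0.01, third_at_bias = 0.7) {
  stopifnot(all(names(motif_mix) %in% c("GA_RUN", "GGX", "POLY_A", "GPG")),
            all(motif_mix >= 0), sum(motif_mix) > 0)
  rates <- c(repeat_rate, spacer_rate, terminal_rate)
  if (any(rates < 0 | rates > 0.5)) abort("rates must lie in [0, 0.5]")
  if (third_at_bias < 0 || third_at_bias > 1) {
    abort("`third_at_bias` must lie in [0, 1]")
  }
  structure(list(n_term_len = as.integer(n_term_len),
                 c_term_len = as.integer(c_term_len),
                 motif_mix = motif_mix / sum(motif_mix),
                 repeat_period = as.integer(repeat_period),
                 repeat_copies = as.integer(repeat_copies),
                 spacer_seq = toupper(spacer_seq),
                 spacer_positions = as.integer(spacer_positions),
                 repeat_rate = repeat_rate, spacer_rate = spacer_rate,
                 terminal_rate = terminal_rate,
                 third_at_bias = third_at_bias),
            class = "spidroin_spec")
}

sample_motif_instance <- function(cls) {
  x_set <- c("A", "S", "T", "Q", "Y", "L", "R")
  switch(cls,
         GGX = paste0("GG", sample(x_set, 1L)),
         POLY_A = strrep("A", sample(4:7, 1L)),
         GA_RUN = strrep("GA", sample(2:5, 1L)),
         GPG = "GPG")
}

mutate_chars <- function(chars, rate, alphabet = names(TERMINAL_COMPOSITION)) {
  if (rate <= 0 || !length(chars)) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  chars
}

#' Generate one synthetic spidroin with ground truth
#'
#' Assembles N-terminus, mutated tandem repeat copies with planted spacers,
#' and C-terminus from a [spidroin_spec()]; back-translates the protein
#' with the configured third-position A/T bias, prefixing ATG and suffixing
#' a stop codon. Ground-truth annotation tables (planted motifs, spacers,
#' the repeat block, and region boundaries in both aa and nt coordinates)
#' accompany the sequences, so recovery by the annotation modules can be
#' validated against construction rather than against other pipeline
#' output.
#'
#' @param spec A [spidroin_spec()].
#' @param seed Integer seed; fixed (spec, seed) pairs are bit-reproducible.
#' @param id Sequence id.
#' @return A list with `protein` and `cds` (one-row sequence tables) and
#'   `truth` (list of tibbles: `motifs`, `spacers`, `repeats`, `regions`).
#' @export
generate_spidroin <- function(spec, seed = NULL, id = "synthetic_misp") {
  stopifnot(inherits(spec, "spidroin_spec"))
  with_seed(seed, {
    # ensemble repeat unit from the motif grammar; class draws are weighted
    # by mix weight over mean instance length so that the residue share of
    # a class tracks its mix weight
    mean_len <- c(GGX = 3, POLY_A = 5.5, GA_RUN = 7, GPG = 3)
    draw_w <- spec$motif_mix / mean_len[names(spec$motif_mix)]
    unit <- character(0)
    unit_motifs <- tibble(motif_class = character(0), start = integer(0),
                          end = integer(0))
    while (length(unit) < spec$repeat_period) {
      cls <- sample(names(spec$motif_mix), 1L, prob = draw_w)
      inst <- strsplit(sample_motif_instance(cls), "")[[1]]
      s <- length(unit)
      unit <- c(unit, inst)
      unit_motifs <- dplyr::bind_rows(
        unit_motifs,
        tibble(motif_class = cls, start = s,
               end = min(s + length(inst), spec$repeat_period)))
    }
    unit <- unit[seq_len(spec$repeat_period)]
    unit_motifs <- dplyr::filter(unit_motifs,
                                 .data$start < spec$repeat_period)

    n_term <- sample(names(TERMINAL_COMPOSITION), spec$n_term_len,
                     replace = TRUE, prob = TERMINAL_COMPOSITION)
    n_term[1] <- "M"
    c_term <- sample(names(TERMINAL_COMPOSITION), spec$c_term_len,
                     replace = TRUE, prob = TERMINAL_COMPOSITION)

    parts <- list(n_term)
    motifs <- NULL; spacers <- NULL
    offset <- spec$n_term_len
    repeat_start <- offset
    spacer_chars <- strsplit(spec$spacer_seq, "")[[1]]
    for (cp in seq_len(spec$repeat_copies)) {
      copy <- mutate_chars(unit, spec$repeat_rate)
      parts <- c(parts, list(copy))
      motifs <- dplyr::bind_rows(
        motifs, dplyr::mutate(unit_motifs, copy = cp,
                              start = .data$start + offset,
                              end = .data$end + offset))
      offset <- offset + length(copy)
      if (cp %in% spec$spacer_positions) {
        sp <- mutate_chars(spacer_chars, spec$spacer_rate)
        parts <- c(parts, list(sp))
        spacers <- dplyr::bind_rows(
          spacers, tibble(start = offset, end = offset + length(sp)))
        offset <- offset + length(sp)
      }
    }
    repeat_end <- offset
    parts <- c(parts, list(c_term))
    protein_chars <- unlist(parts)
    total <- length(protein_chars)

    truth <- list(
      motifs = dplyr::bind_rows(motifs) %||%
        tibble(motif_class = character(0), start = integer(0),
               end = integer(0), copy = integer(0)),
      spacers = spacers %||% tibble(start = integer(0), end = integer(0)),
      repeats = tibble(start = repeat_start, end = repeat_end,
                       period = spec$repeat_period,
                       copies = spec$repeat_copies),
      regions = tibble(
        region = c("n_term", "repeat", "c_term"),
        start = c(0L, repeat_start, repeat_end),
        end = c(repeat_start, repeat_end, total),
        start_nt = 3L * c(0L, repeat_start, repeat_end),
        end_nt = 3L * c(repeat_start, repeat_end, total) +
          c(0L, 0L, 3L)))   # stop codon belongs to the c_term span

    protein <- paste(protein_chars, collapse = "")
    cds <- back_translate(protein_chars, spec$third_at_bias)
    list(protein = seq_tbl(id, protein, "protein"),
         cds = seq_tbl(id, cds, "nucleotide"),
         truth = truth)
  })
}

# codon choice honouring a third-position A/T bias; assumes an RNG is active
back_translate <- function(chars, third_at_bias) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  codons <- vapply(chars, function(aa) {
    if (aa == "M") return("ATG")
    opts <- by_aa[[aa]]
    if (is.null(opts)) abort(paste0("cannot back-translate residue ", aa))
    at3 <- substr(opts, 3, 3) %in% c("A", "T")
    w <- if (all(at3) || !any(at3)) rep(1, length(opts)) else
      ifelse(at3, third_at_bias / sum(at3), (1 - third_at_bias) / sum(!at3))
    sample(opts, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L,
                       prob = c(third_at_bias / 2, third_at_bias / 2,
                                1 - third_at_bias))
  paste(c(codons, stop_codon), collapse = "")
}

#' Evolve a spidroin paralog family down a species tree
#'
#' Starting from a single root gene (from [generate_spidroin()]), evolves
#' coding sequences along a species tree with per-branch, per-site
#' substitution. Loci duplicate at nominated nodes; on every branch,
#' intergenic gene conversion copies tracts between paralogs (restricted to
#' the terminal-encoding regions when `terminal_only = TRUE`, the regime
#' that homogenizes termini while repeat regions diverge), and
#' slipped-strand mispairing expands or contracts the repeat region in
#' codon-sized units. Every event is logged with its branch, loci and
#' coordinates so downstream inference can be scored against truth.
#'
#' @param root_spec A [spidroin_spec()] for the ancestral gene.
#' @param species_tree A rooted `phylo` tree with branch lengths.
#' @param duplications Species-tree node labels at which every lineage
#'   gains a second copy of locus 1; `"root"` duplicates before descent.
#' @param conversion_rate Expected conversion events per unit branch
#'   length.
#' @param conversion_tract_len Conversion tract length (nt).
#' @param terminal_only Restrict conversion tracts to terminal-encoding
#'   regions.
#' @param slippage_rate Expected slippage events per unit branch length.
#' @param branch_rate Per-site substitution probability per unit branch
#'   length.
#' @param seed Integer seed.
#' @return A list with `sequences` (tibble `species`, `locus`, `id`,
#'   `residues`, region boundaries `n_term_end_nt`, `c_term_start_nt`) and
#'   `events` (ordered tibble of duplication / conversion / slippage
#'   records).
#' @export
evolve_family <- function(root_spec, species_tree, duplications = "root",
                          conversion_rate = 0, conversion_tract_len = 200L,
                          terminal_only = TRUE, slippage_rate = 0,
                          branch_rate = 0.02, seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"))
  if (is.null(species_tree$edge.length)) {
    abort("species tree must have branch lengths")
  }
  with_seed(seed, {
    root_gene <- generate_spidroin(root_spec, seed = NULL, id = "root")
    regions <- root_gene$truth$regions
    nterm_end <- regions$end_nt[regions$region == "n_term"]
    make_locus <- function(chars, cterm_start) {
      list(chars = chars, nterm_end = nterm_end, cterm_start = cterm_start)
    }
    root_chars <- strsplit(root_gene$cds$residues, "")[[1]]
    root_locus <- make_locus(root_chars,
                             regions$start_nt[regions$region == "c_term"])

    n_tips <- length(species_tree$tip.label)
    root_node <- n_tips + 1L
    node_label <- function(v) {
      if (v <= n_tips) species_tree$tip.label[v]
      else if (v == root_node) "root"
      else if (!is.null(species_tree$node.label) &&
               nzchar(species_tree$node.label[v - n_tips] %||% "")) {
        species_tree$node.label[v - n_tips]
      } else paste0("node", v)
    }

    events <- list()
    log_event <- function(...) events[[length(events) + 1L]] <<- tibble(...)
    bases <- c("A", "C", "G", "T")

    duplicate_at <- function(loci, label) {
      if (label %in% duplications) {
        loci <- c(loci, loci[1])
        log_event(event = "duplication", branch = label,
                  locus = length(loci), source_locus = 1L,
                  start = NA_integer_, end = NA_integer_,
                  units = NA_integer_)
      }
      loci
    }

    evolve_branch <- function(loci, t, label) {
      p_sub <- min(0.5, branch_rate * t)
      loci <- lapply(loci, function(lc) {
        lc$chars <- mutate_chars(lc$chars, p_sub, bases)
        lc
      })
      if (length(loci) >= 2L && conversion_rate > 0) {
        for (ev in seq_len(rpois(1L, conversion_rate * t))) {
          pair <- sample(length(loci), 2L)
          src <- loci[[pair[1]]]; tgt <- loci[[pair[2]]]
          if (terminal_only) {
            if (runif(1) < 0.5) {           # N-terminal tract
              len <- min(conversion_tract_len, src$nterm_end)
              s <- sample.int(src$nterm_end - len + 1L, 1L) - 1L
              tgt$chars[(s + 1L):(s + len)] <- src$chars[(s + 1L):(s + len)]
              lo <- s; hi <- s + len
            } else {                        # C-terminal tract, 3'-anchored
              src_len <- length(src$chars) - src$cterm_start
              tgt_len <- length(tgt$chars) - tgt$cterm_start
              len <- min(conversion_tract_len, src_len, tgt_len)
              off <- sample.int(min(src_len, tgt_len) - len + 1L, 1L) - 1L
              si <- src$cterm_start + off; ti <- tgt$cterm_start + off
              tgt$chars[(ti + 1L):(ti + len)] <-
                src$chars[(si + 1L):(si + len)]
              lo <- ti; hi <- ti + len
            }
          } else {
            len <- min(conversion_tract_len, length(tgt$chars),
                       length(src$chars))
            s <- sample.int(min(length(src$chars), length(tgt$chars)) -
                              len + 1L, 1L) - 1L
            tgt$chars[(s + 1L):(s + len)] <- src$chars[(s + 1L):(s + len)]
            lo <- s; hi <- s + len
          }
          loci[[pair[2]]] <- tgt
          log_event(event = "conversion", branch = label,
                    locus = pair[2], source_locus = pair[1],
                    start = lo, end = hi, units = NA_integer_)
        }
      }
      if (slippage_rate > 0) {
        for (ev in seq_len(rpois(1L, slippage_rate * t))) {
          li <- sample(length(loci), 1L)
          lc <- loci[[li]]
          unit_nt <- 6L
          rep_lo <- lc$nterm_end
          rep_hi <- lc$cterm_start
          if (rep_hi - rep_lo < 2L * unit_nt) next
          s <- rep_lo + sample.int(rep_hi - rep_lo - unit_nt, 1L) - 1L
          expand <- runif(1) < 0.5
          if (expand) {
            chunk <- lc$chars[(s + 1L):(s + unit_nt)]
            lc$chars <- append(lc$chars, chunk, after = s + unit_nt)
            lc$cterm_start <- lc$cterm_start + unit_nt
          } else {
            lc$chars <- lc$chars[-((s + 1L):(s + unit_nt))]
            lc$cterm_start <- lc$cterm_start - unit_nt
          }
          loci[[li]] <- lc
          log_event(event = "slippage", branch = label, locus = li,
                    source_locus = NA_integer_, start = s, end = s + unit_nt,
                    units = if (expand) 1L else -1L)
        }
      }
      loci
    }

    tips <- list()
    recurse <- function(node, loci) {
      loci <- duplicate_at(loci, node_label(node))
      if (node <= n_tips) {
        tips[[species_tree$tip.label[node]]] <<- loci
        return(invisible(NULL))
      }
      kids <- which(species_tree$edge[, 1] == node)
      for (e in kids) {
        child <- species_tree$edge[e, 2]
        lab <- paste0(node_label(node), "->", node_label(child))
        recurse(child, evolve_branch(loci, species_tree$edge.length[e], lab))
      }
    }
    recurse(root_node, list(root_locus))

    sequences <- purrr::map_dfr(names(tips), function(sp) {
      purrr::map_dfr(seq_along(tips[[sp]]), function(li) {
        lc <- tips[[sp]][[li]]
        tibble(species = sp, locus = paste0("v", li),
               id = paste0(sp, "_v", li),
               residues = paste(lc$chars, collapse = ""),
               n_term_end_nt = lc$nterm_end,
               c_term_start_nt = lc$cterm_start)
      })
    })
    list(sequences = sequences,
         events = dplyr::bind_rows(events) %||%
           tibble(event = character(0), branch = character(0),
                  locus = integer(0), source_locus = integer(0),
                  start = integer(0), end = integer(0), units = integer(0)))
  })
}

#' Extract terminal or repeat regions from an evolved family
#'
#' @param family_seqs The `sequences` tibble from [evolve_family()].
#' @param region `"terminal"` (N- and C-terminal encoding regions
#'   concatenated) or `"repeat"`.
#' @return A nucleotide sequence table (`id`, `alphabet`, `residues`).
#' @export
extract_region <- function(family_seqs, region = c("terminal", "repeat")) {
  region <- match.arg(region)
  res <- purrr::pmap_chr(
    list(family_seqs$residues, family_seqs$n_term_end_nt,
         family_seqs$c_term_start_nt),
    function(x, ne, cs) {
      if (region == "terminal") {
        paste0(substr(x, 1L, ne), substr(x, cs + 1L, nchar(x)))
      } else {
        substr(x, ne + 1L, cs)
      }
    })
  seq_tbl(family_seqs$id, res, "nucleotide")
}

#' Simulate a 3'-biased read set at a known paralog ratio
#'
#' Reads originate from each reference with probability proportional to
#' `true_ratio`; start positions are drawn with exponential weighting
#' toward the 3' end (`exp(-decay * f)` where f is the fractional distance
#' of the start from its 3'-most possible position; decay 0 is uniform,
#' decay 10 puts >90% of reads in the last quarter); sequencing errors are
#' i.i.d. base substitutions. The truth map records each read's source.
#'
#' @param references A nucleotide sequence table.
#' @param depth Total number of reads.
#' @param true_ratio Named abundance weights (names matching reference
#'   ids), e.g. `c(v2 = 4, v1 = 1)`.
#' @param read_len Read length (nt).
#' @param three_prime_decay Exponential 3'-bias decay parameter.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A list with `reads` (sequence table) and `truth` (tibble
#'   `read_id`, `reference_id`, `start`).
#' @export
generate_reads <- function(references, depth, true_ratio, read_len = 75L,
                           three_prime_decay = 0, error_rate = 0,
                           seed = NULL) {
  stopifnot(all(names(true_ratio) %in% references$id),
            length(true_ratio) >= 1L, all(true_ratio >= 0))
  if (any(nchar(references$residues[references$id %in% names(true_ratio)]) <
          read_len)) {
    abort("every sampled reference must be at least one read long")
  }
  with_seed(seed, {
    origin <- sample(names(true_ratio), depth, replace = TRUE,
                     prob = true_ratio / sum(true_ratio))
    bases <- c("A", "C", "G", "T")
    out <- purrr::map_dfr(names(true_ratio), function(ref) {
      n_reads <- sum(origin == ref)
      if (!n_reads) return(NULL)
      x <- references$residues[references$id == ref]
      max_start <- nchar(x) - read_len          # 0-based start in 0..max
      f_from_3 <- (max_start - (0:max_start)) / max(1L, max_start)
      w <- exp(-three_prime_decay * f_from_3)
      starts <- sample(0:max_start, n_reads, replace = TRUE, prob = w)
      res <- substring(x, starts + 1L, starts + read_len)
      if (error_rate > 0) {
        res <- vapply(res, function(r) {
          ch <- strsplit(r, "")[[1]]
          paste(mutate_chars(ch, error_rate, bases), collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      tibble(reference_id = ref, start = starts, residues = res)
    })
    out <- out[sample.int(nrow(out)), ]         # interleave origins
    out$read_id <- sprintf("read_%06d", seq_len(nrow(out)))
    list(reads = seq_tbl(out$read_id, out$residues, "nucleotide"),
         truth = tibble(read_id = out$read_id,
                        reference_id = out$reference_id,
                        start = out$start))
  })
}

#' Simulate a fiber tensile trace with known properties
#'
#' Builds the force-extension record whose true-stress/true-strain
#' transform is a bilinear rising curve: initial slope `modulus_GPa` up to
#' `yield_strain`, then linear to the breakage point
#' (`extensibility`, `strength_MPa`). Gaussian force noise is added and a
#' post-break force collapse appended. With zero noise,
#' [tensile_properties()] recovers modulus, strength, extensibility and
#' the analytic (piecewise-trapezoid) toughness exactly; the analytic
#' values are attached as attribute `truth`.
#'
#' @param modulus_GPa Young's modulus (GPa).
#' @param strength_MPa True stress at breakage (MPa).
#' @param extensibility True strain at breakage (ln mm/mm).
#' @param yield_strain Strain at the stiffness knee.
#' @param noise_sd Gaussian force noise SD (uN).
#' @param n_samples Samples along the strain grid.
#' @param gage_length_mm,diameter_um Fiber geometry.
#' @param seed Integer seed.
#' @return A `tensile_trace` with attribute `truth` (list `modulus_GPa`,
#'   `strength_MPa`, `extensibility`, `toughness_MJ_m3`).
#' @export
simulate_tensile <- function(modulus_GPa, strength_MPa, extensibility,
                             yield_strain = 0.02, noise_sd = 0,
                             n_samples = 200L, gage_length_mm = 10,
                             diameter_um = 1.1, seed = NULL) {
  e_mpa <- modulus_GPa * 1000
  sigma_y <- e_mpa * yield_strain
  if (yield_strain >= extensibility) {
    abort("`yield_strain` must be below `extensibility`")
  }
  if (sigma_y > strength_MPa) {
    abort("initial slope reaches `strength_MPa` before the yield strain; lower `yield_strain` or `modulus_GPa`")
  }
  with_seed(seed, {
    eps <- sort(unique(c(seq(0, extensibility, length.out = n_samples),
                         yield_strain)))
    sig <- ifelse(eps <= yield_strain, e_mpa * eps,
                  sigma_y + (strength_MPa - sigma_y) *
                    (eps - yield_strain) / (extensibility - yield_strain))
    l0 <- gage_length_mm
    a0 <- pi * (diameter_um / 2)^2
    ext <- l0 * (exp(eps) - 1)
    force <- sig * a0 * exp(-eps)
    if (noise_sd > 0) {
      force <- pmax(0, force + rnorm(length(force), sd = noise_sd))
    }
    # post-break collapse
    ext_post <- ext[length(ext)] + l0 * c(0.002, 0.004, 0.006)
    force_post <- rep(0.02 * force[length(force)], 3L)
    trace <- tensile_trace(
      tibble(extension_mm = c(ext, ext_post),
             force_uN = c(force, force_post)),
      gage_length_mm = l0, diameter_um = diameter_um)
    attr(trace, "truth") <- list(
      modulus_GPa = modulus_GPa, strength_MPa = strength_MPa,
      extensibility = extensibility,
      toughness_MJ_m3 = 0.5 * sigma_y * yield_strain +
        (extensibility - yield_strain) * (sigma_y + strength_MPa) / 2)
    trace
  })
}

#' Simulate Brownian-motion traits on a tree
#'
#' Trait values diffuse along branches with variance `sigma2` per unit
#' branch length. When `slope` is given a second trait is returned,
#' `y = slope * x + BM noise` (noise rate `noise_sigma2`), for regression
#' recovery experiments on independent contrasts.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param sigma2 Brownian rate of the (first) trait.
#' @param root_value Trait value at the root.
#' @param slope Optional true slope linking a response trait to the first.
#' @param noise_sigma2 Brownian rate of the response-trait noise.
#' @param seed Integer seed.
#' @return A tibble `id`, `x` (and `y` when `slope` is given).
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_value = 0,
                               slope = NULL, noise_sigma2 = sigma2,
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  with_seed(seed, {
    bm_once <- function(rate, root) {
      n_nodes <- length(tree$tip.label) + tree$Nnode
      val <- numeric(n_nodes)
      val[length(tree$tip.label) + 1L] <- root
      edges <- ape::reorder.phylo(tree, "cladewise")$edge
      lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
      for (e in seq_len(nrow(edges))) {
        val[edges[e, 2]] <- val[edges[e, 1]] +
          rnorm(1L, sd = sqrt(rate * lens[e]))
      }
      val[seq_along(tree$tip.label)]
    }
    x <- bm_once(sigma2, root_value)
    out <- tibble(id = tree$tip.label, x = x)
    if (!is.null(slope)) {
      out$y <- slope * x + bm_once(noise_sigma2, 0)
    }
    out
  })
}
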
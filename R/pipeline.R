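CONFIG_KEYS <- c("seed", "out_dir", "motif_classes", "spacer", "repeat",
                 "align", "expression", "tensile", "correlate", "simulate")

#' Pipeline configuration
#'
#' A validated key-value configuration shared by the `cmd_*` stage
#' runners. Unknown keys are rejected outright; module parameter groups
#' (`spacer`, `repeat`, `align`, `expression`, `tensile`, `correlate`,
#' `simulate`) are named lists passed through to the corresponding
#' functions. Identical configuration and seed give byte-identical
#' reports.
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param out_dir Directory reports are written to (created if needed).
#' @param ... Module parameter groups, e.g.
#'   `spacer = list(ga_ceiling = 0.3)`.
#' @return A `misilk_config` list.
#' @export
misilk_config <- function(seed = 1L, out_dir = tempdir(), ...) {
  extra <- list(...)
  unknown <- setdiff(names(extra), CONFIG_KEYS)
  if (length(unknown)) {
    abort(paste0("unknown config key: ", unknown[1]))
  }
  cfg <- c(list(seed = as.integer(seed), out_dir = out_dir), extra)
  structure(cfg, class = "misilk_config")
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  config$out_dir
}

# TSV + JSON twin report writers; JSON numbers are written unrounded
write_report <- function(x, out_dir, name) {
  readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
  jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Write a provenance record
#'
#' Machine-readable record of a pipeline run: configuration hash, seed and
#' package/R versions (no timestamp, so identical runs produce identical
#' records).
#'
#' @param config A [misilk_config()].
#' @return Path of the written JSON, invisibly.
#' @export
write_provenance <- function(config) {
  out_dir <- ensure_out_dir(config)
  rec <- list(config_hash = rlang::hash(unclass(config)),
              seed = config$seed,
              misilk_version = as.character(utils::packageVersion("misilk")),
              r_version = paste(R.version$major, R.version$minor, sep = "."))
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

as_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L) read_fasta(x) else x
}

#' Stage runner: sequence architecture profile
#'
#' Profiles every protein in a FASTA file (or sequence table): motif
#' annotations and per-class coverage, spacers, tandem repeats, repeat
#' modularity, and amino-acid composition. Reports are written to the
#' configured output directory as TSV + JSON twins along with a provenance
#' record.
#'
#' @param fasta Path to a protein FASTA, or a sequence table.
#' @param config A [misilk_config()].
#' @return A named list of tibbles (`motifs`, `coverage`, `spacers`,
#'   `repeats`, `modularity`, `composition`), invisibly written as
#'   reports.
#' @export
cmd_profile <- function(fasta, config = misilk_config()) {
  seqs <- as_seqs(fasta)
  out_dir <- ensure_out_dir(config)
  classes <- config$motif_classes %||% c("GGX", "POLY_A", "GA_RUN", "GPG")
  motifs <- scan_motifs(seqs, classes)
  coverage <- purrr::map_dfr(classes, function(cl) motif_coverage(seqs, cl))
  spacers <- rlang::exec(detect_spacers, seqs, !!!(config$spacer %||% list()))
  repeats <- rlang::exec(find_tandem_repeats, seqs,
                         !!!(config$`repeat` %||% list()))
  modularity <- if (nrow(repeats)) classify_modularity(repeats) else
    tibble(id = seqs$id, modularity = "none")
  reports <- list(motifs = motifs, coverage = coverage, spacers = spacers,
                  repeats = repeats, modularity = modularity,
                  composition = composition(seqs))
  for (nm in names(reports)) write_report(reports[[nm]], out_dir, nm)
  write_provenance(config)
  reports
}

#' Stage runner: structure-property correlation
#'
#' Regresses a fiber property on a sequence statistic across species, raw
#' and (when a tree is supplied) on phylogenetic independent contrasts
#' through the origin.
#'
#' @param traits A tibble (or TSV path) with a tip-label column `id` and
#'   trait columns.
#' @param x,y Trait column names (character).
#' @param tree Optional rooted binary `phylo` tree (or newick path) for
#'   the contrasts fit.
#' @param config A [misilk_config()].
#' @return A list with `raw` and (optionally) `contrasts`
#'   `silk_regression` objects.
#' @export
cmd_correlate <- function(traits, x, y, tree = NULL,
                          config = misilk_config()) {
  if (is.character(traits)) {
    traits <- readr::read_tsv(traits, show_col_types = FALSE)
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  out_dir <- ensure_out_dir(config)
  raw <- silk_regress(traits, !!rlang::sym(x), !!rlang::sym(y))
  out <- list(raw = raw)
  if (!is.null(tree)) {
    out$contrasts <- pic_regress(tree, traits, !!rlang::sym(x),
                                 !!rlang::sym(y))
  }
  report <- purrr::map_dfr(names(out), function(nm) {
    dplyr::mutate(glance(out[[nm]]), fit = nm, slope = out[[nm]]$slope,
                  .before = 1)
  })
  write_report(report, out_dir, "correlation")
  write_provenance(config)
  out
}

#' Stage runner: paralog expression ratios
#'
#' Assigns reads to paralog references, counts whole-gene and 3'-window
#' hits, and reports the abundance ratio of the first reference to the
#' second in both modes (the layout of a per-library transcript-abundance
#' table).
#'
#' @param reads Reads (FASTA path or sequence table; FASTQ may be read
#'   with [read_fasta()]-compatible tools upstream).
#' @param references Reference loci (FASTA path or sequence table); input
#'   order breaks assignment ties.
#' @param numerator,denominator Reference ids for the ratio (defaults:
#'   first and second reference).
#' @param config A [misilk_config()]; `expression` group may set
#'   `max_mismatch` and `window`.
#' @return A one-row tibble `total_reads`, per-reference counts, `ratio`,
#'   `ratio_3prime`.
#' @export
cmd_expression <- function(reads, references, numerator = NULL,
                           denominator = NULL, config = misilk_config()) {
  reads <- as_seqs(reads)
  references <- as_seqs(references)
  out_dir <- ensure_out_dir(config)
  pars <- config$expression %||% list()
  assignments <- assign_reads(reads, references,
                              max_mismatch = pars$max_mismatch %||% 3L)
  counts <- count_reads(assignments, references,
                        window = pars$window %||% 500L)
  numerator <- numerator %||% references$id[1]
  denominator <- denominator %||% references$id[2]
  report <- tibble(
    total_reads = nrow(assignments),
    !!paste0("count_", numerator) :=
      counts$n_total[counts$reference_id == numerator],
    !!paste0("count_", denominator) :=
      counts$n_total[counts$reference_id == denominator],
    ratio = abundance_ratio(counts, numerator, denominator, "whole"),
    ratio_3prime = abundance_ratio(counts, numerator, denominator, "window"))
  write_report(report, out_dir, "expression")
  write_provenance(config)
  report
}

#' Stage runner: synthetic dataset bundle
#'
#' Generates a reproducible demonstration dataset under the configured
#' output directory: a synthetic spidroin (protein + CDS FASTA with truth
#' annotation tables), a 3'-biased read set at a 4:1 paralog ratio with
#' its truth map, a noisy tensile trace, and Brownian traits on a supplied
#' or default tree. All files are plain text; every sequence is labelled
#' synthetic.
#'
#' @param config A [misilk_config()]; the `simulate` group may override
#'   `spec` (a [spidroin_spec()]), `depth`, `true_ratio`, `read_len`,
#'   `three_prime_decay`, `error_rate`, and `tree` (a `phylo`).
#' @return Invisible character vector of written file paths.
#' @export
cmd_simulate <- function(config = misilk_config()) {
  out_dir <- ensure_out_dir(config)
  pars <- config$simulate %||% list()
  spec <- pars$spec %||% spidroin_spec()
  seed <- config$seed

  gen <- generate_spidroin(spec, seed = seed, id = "synthetic_misp_v2")
  gen2 <- generate_spidroin(spec, seed = seed + 1L, id = "synthetic_misp_v1")
  write_fasta(dplyr::bind_rows(gen$protein, gen2$protein),
              file.path(out_dir, "synthetic_proteins.fasta"))
  refs <- dplyr::bind_rows(gen$cds, gen2$cds)
  write_fasta(refs, file.path(out_dir, "synthetic_cds.fasta"))
  for (nm in c("motifs", "spacers", "repeats", "regions")) {
    readr::write_tsv(gen$truth[[nm]],
                     file.path(out_dir, paste0("truth_", nm, ".tsv")))
  }

  sim_reads <- generate_reads(
    refs, depth = pars$depth %||% 5000L,
    true_ratio = pars$true_ratio %||%
      setNames(c(4, 1), refs$id),
    read_len = pars$read_len %||% 75L,
    three_prime_decay = pars$three_prime_decay %||% 10,
    error_rate = pars$error_rate %||% 0.002,
    seed = seed + 2L)
  write_fasta(sim_reads$reads, file.path(out_dir, "synthetic_reads.fasta"))
  readr::write_tsv(sim_reads$truth, file.path(out_dir, "truth_reads.tsv"))

  trace <- simulate_tensile(modulus_GPa = 3.9, strength_MPa = 245,
                            extensibility = 0.57, noise_sd = 2,
                            seed = seed + 3L)
  write_tensile_trace(trace, file.path(out_dir, "synthetic_trace.tsv"))

  tree <- pars$tree %||% ape::read.tree(
    text = "((Lh:1,Lt:1):1,(Lg:1.5,Sg:1.5):0.5);")
  traits <- simulate_bm_traits(tree, sigma2 = 1, slope = 0.02,
                               seed = seed + 4L)
  ape::write.tree(tree, file.path(out_dir, "synthetic_tree.nwk"))
  readr::write_tsv(traits, file.path(out_dir, "synthetic_traits.tsv"))

  write_provenance(config)
  invisible(list.files(out_dir, full.names = TRUE))
}
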
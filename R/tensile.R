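#' Tensile traces
#'
#' A tensile trace is a raw fiber test record: gage length (mm), fiber
#' diameter (um), and an ordered table of (extension mm, force uN) samples
#' with non-decreasing extensions starting at zero. Traces are stored as a
#' `tensile_trace` object and serialised as two-column tab-separated text
#' with `# key value` metadata header lines (`gage_length_mm`,
#' `diameter_um`).
#'
#' @param samples A data frame with columns `extension_mm`, `force_uN`.
#' @param gage_length_mm Original gage length in mm.
#' @param diameter_um Fiber diameter in um.
#' @return A `tensile_trace` object.
#' @export
tensile_trace <- function(samples, gage_length_mm, diameter_um) {
  stopifnot(all(c("extension_mm", "force_uN") %in% names(samples)))
  if (gage_length_mm <= 0) abort("gage length must be positive")
  if (diameter_um <= 0) abort("diameter must be positive")
  ext <- samples$extension_mm
  if (length(ext) < 2L) abort("a trace needs at least two samples")
  if (ext[1] < 0 || any(diff(ext) < 0)) {
    abort("extensions must be non-decreasing from 0")
  }
  if (any(!is.finite(samples$force_uN))) abort("forces must be finite")
  structure(list(gage_length_mm = gage_length_mm,
                 diameter_um = diameter_um,
                 samples = tibble::as_tibble(samples)),
            class = "tensile_trace")
}

#' @export
print.tensile_trace <- function(x, ...) {
  cat("Tensile trace:", nrow(x$samples), "samples, gage",
      x$gage_length_mm, "mm, diameter", x$diameter_um, "um\n")
  invisible(x)
}

#' @rdname tensile_trace
#' @param path File path.
#' @export
read_tensile_trace <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", meta_lines), "\\s+")
  meta <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(kv, `[`, character(1), 1))
  for (key in c("gage_length_mm", "diameter_um")) {
    if (!key %in% names(meta)) {
      abort(paste0("trace file missing metadata line: ", key))
    }
  }
  body <- readr::read_tsv(I(grep("^#", lines, invert = TRUE, value = TRUE)),
                          show_col_types = FALSE)
  tensile_trace(body, meta[["gage_length_mm"]], meta[["diameter_um"]])
}

#' @rdname tensile_trace
#' @param trace A `tensile_trace` object.
#' @export
write_tensile_trace <- function(trace, path) {
  hdr <- c(paste("# gage_length_mm", format(trace$gage_length_mm)),
           paste("# diameter_um", format(trace$diameter_um)),
           paste("extension_mm", "force_uN", sep = "\t"))
  body <- paste(format(trace$samples$extension_mm, trim = TRUE),
                format(trace$samples$force_uN, trim = TRUE), sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' True stress / true strain transform
#'
#' Converts a force-extension trace to true stress and true strain assuming
#' constant fiber volume: strain is `ln(L / L0)` with
#' `L = L0 + extension`, and true stress is `F * L / (A0 * L0)` where `A0 =
#' pi * (d / 2)^2` is the original cross-section. With force in uN,
#' extension/gage in mm and diameter in um, stress comes out in MPa.
#'
#' @param trace A `tensile_trace` object.
#' @return A tibble `true_strain` (ln mm/mm), `true_stress_MPa`.
#' @export
true_curve <- function(trace) {
  stopifnot(inherits(trace, "tensile_trace"))
  l0 <- trace$gage_length_mm
  a0 <- pi * (trace$diameter_um / 2)^2          # um^2; uN/um^2 == MPa
  l <- l0 + trace$samples$extension_mm
  tibble(true_strain = log(l / l0),
         true_stress_MPa = trace$samples$force_uN * l / (a0 * l0))
}

#' Derive tensile properties from a true stress-strain curve
#'
#' Breakage is the last sample before stress drops by more than 50% from
#' its running maximum (the final sample when no such drop exists), so the
#' post-break force collapse of a recorded trace is excluded; dips while
#' the running maximum is still below 10% of the peak stress are treated
#' as load-up noise, not failure. Strength is
#' the true stress and extensibility the true strain at breakage; Young's
#' modulus is the least-squares slope of stress on strain over strains up
#' to `modulus_strain_max`; toughness is the trapezoidal area under the
#' curve up to breakage (MPa times dimensionless strain is MJ/m^3,
#' numerically equal to J/cm^3).
#'
#' @param curve Output of [true_curve()] (columns `true_strain`,
#'   `true_stress_MPa`).
#' @param modulus_strain_max Strain ceiling of the initial-slope fit.
#' @return A one-row tibble `strength_MPa`, `extensibility`,
#'   `modulus_GPa`, `toughness_MJ_m3`.
#' @export
tensile_properties <- function(curve, modulus_strain_max = 0.02) {
  eps <- curve$true_strain
  sig <- curve$true_stress_MPa
  if (length(eps) < 2L) abort("curve needs at least two samples")
  run_max <- cummax(sig)
  # noise guard: a >50% dip only counts as failure once the fiber has been
  # loaded appreciably (running max beyond 10% of the curve's peak stress)
  dropped <- which(sig < 0.5 * run_max & run_max > 0.1 * max(sig))
  brk <- if (length(dropped)) dropped[1] - 1L else length(eps)
  eps <- eps[seq_len(brk)]
  sig <- sig[seq_len(brk)]
  init <- eps <= modulus_strain_max
  if (sum(init) < 2L) init <- seq_len(min(2L, length(eps)))
  modulus <- unname(coef(lm(sig[init] ~ eps[init]))[2]) / 1000
  toughness <- sum(diff(eps) * (head(sig, -1) + tail(sig, -1)) / 2)
  tibble(strength_MPa = sig[length(sig)],
         extensibility = eps[length(eps)],
         modulus_GPa = modulus,
         toughness_MJ_m3 = toughness)
}

#' One-way analysis of variance from sums of squares
#'
#' Standard one-way decomposition computed directly from between- and
#' within-group sums of squares. Three groups of fifty fibers give the
#' familiar (2, 147) degrees of freedom.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-select).
#' @return A one-row tibble `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  k <- nlevels(g)
  n <- length(y)
  if (k < 2L) abort("need at least two groups")
  grand <- mean(y)
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  tibble(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Tukey honestly-significant-difference letters
#'
#' Pairwise studentized-range comparisons with a common sample size taken
#' as the harmonic mean of the group sizes (the Tukey-Kramer convention for
#' unbalanced designs reported alongside fiber tests), summarised as a
#' compact letter display: groups sharing a letter are not significantly
#' different at level `alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level.
#' @return A tibble `group`, `n`, `mean`, `letters`, ordered by mean.
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  k <- nlevels(g)
  if (k < 2L) abort("need at least two groups")
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  df2 <- length(y) - k
  mse <- sum((y - means[g])^2) / df2
  n_h <- harmonic_mean(sizes)
  crit <- qtukey(1 - alpha, k, df2)
  se <- sqrt(mse / n_h)
  lev <- levels(g)
  differs <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      q <- abs(means[i] - means[j]) / se
      differs[i, j] <- differs[j, i] <- q > crit
    }
  }
  letters_map <- compact_letters(differs, order(means, decreasing = TRUE))
  tibble(group = lev, n = as.integer(sizes), mean = as.numeric(means),
         letters = letters_map[lev]) |>
    dplyr::arrange(dplyr::desc(.data$mean))
}

harmonic_mean <- function(x) length(x) / sum(1 / x)

# compact letter display: maximal cliques of the "not significantly
# different" graph, lettered in mean order (group counts here are tiny)
compact_letters <- function(differs, order_idx) {
  k <- nrow(differs)
  lev <- rownames(differs)
  same <- !differs
  subsets <- list()
  for (bits in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0L)
    if (all(same[members, members])) subsets <- c(subsets, list(members))
  }
  is_maximal <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, logical(1))
  cliques <- subsets[is_maximal]
  first_rank <- vapply(cliques, function(s) min(match(s, order_idx)), numeric(1))
  cliques <- cliques[order(first_rank)]
  out <- setNames(rep("", k), lev)
  for (ci in seq_along(cliques)) {
    out[cliques[[ci]]] <- paste0(out[cliques[[ci]]], LETTERS[ci])
  }
  out
}
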
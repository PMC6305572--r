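#' Wilson 95% score interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(estimate, lower, upper)`; all `NA` when
#'   `n == 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Species call from expression purity
#'
#' A barcode whose majority-species UMI fraction (purity) falls strictly
#' below `purity_threshold` is called a cross-species multiplet;
#' otherwise the majority species is called. Barcodes with no UMIs get
#' "no-call".
#'
#' @param counts A `species_counts` data.frame (see
#'   [species_counts_from_matrix()]).
#' @param purity_threshold Multiplet threshold (default 0.7; a purity of
#'   exactly 0.7 is a singlet, the threshold is strict).
#' @param min_umis Minimum UMIs for any call (default 1).
#' @return Character vector: species name, "multiplet", or "no-call".
#' @export
call_species_from_expression <- function(counts, purity_threshold = 0.7,
                                         min_umis = 1L) {
  sp <- attr(counts, "species")
  if (is.null(sp)) sp <- c("speciesA", "speciesB")
  out <- ifelse(counts$umis_a >= counts$umis_b, sp[1], sp[2])
  out[counts$purity < purity_threshold] <- "multiplet"
  out[is.na(counts$purity) | counts$total < min_umis] <- "no-call"
  out
}

#' Imaging/expression species concordance
#'
#' Fraction of linked cells whose imaging species label agrees with the
#' expression species call, among cells where both sides made an
#' unambiguous single-species call (mixed/multiplet/none on either side
#' are excluded).
#'
#' @param imaging_label Character vector of imaging labels.
#' @param expression_call Character vector of expression calls (aligned).
#' @param species Names of the two single-species calls.
#' @return List: `value`, `n` (informative pairs), `ci` (Wilson).
#' @export
concordance <- function(imaging_label, expression_call,
                        species = NULL) {
  if (length(imaging_label) == 0L) stop("no linked cells supplied")
  if (is.null(species)) {
    species <- setdiff(unique(c(imaging_label, expression_call)),
                       c("mixed", "multiplet", "none", "no-call", NA))
  }
  ok <- imaging_label %in% species & expression_call %in% species
  n <- sum(ok)
  k <- sum(imaging_label[ok] == expression_call[ok])
  list(value = if (n > 0) k / n else NA_real_, n = n, ci = wilson_ci(k, n))
}

#' Abundance-corrected linking accuracy
#'
#' Observed species concordance C overstates linking accuracy because a
#' randomly wrong link still agrees with probability C0 = sum(p_s^2)
#' (the chance two cells share a species). The chance-corrected accuracy
#' (C - C0) / (1 - C0) -- a Cohen-kappa-style correction -- is 1 for
#' perfect linking and about 0 for random linking. Undefined when only
#' one species is present (C0 = 1).
#'
#' @param concordance_value Observed concordance C.
#' @param species_proportions Species proportions (estimated from the
#'   data), summing to 1.
#' @return List: `value`, `chance` (C0). `value` is `NA` with a warning
#'   when C0 = 1.
#' @export
linking_accuracy <- function(concordance_value, species_proportions) {
  p <- species_proportions / sum(species_proportions)
  c0 <- sum(p^2)
  if (1 - c0 < 1e-12) {
    warning("single-species data: chance agreement is 1, accuracy undefined")
    return(list(value = NA_real_, chance = c0))
  }
  list(value = (concordance_value - c0) / (1 - c0), chance = c0)
}

#' Multiplet-detection metrics
#'
#' Sensitivity and specificity of the monochrome imaging multiplet flag
#' against expression-purity multiplet calls (the experimental ground
#' truth), plus the concordance between one-colour (monochrome) and
#' two-colour (mixed-label) imaging flags. When true simulation labels
#' are supplied, the same metrics against truth are reported as well.
#'
#' @param mono_flag Logical, monochrome imaging multiplet flags.
#' @param expr_multiplet Logical, expression purity multiplet calls.
#' @param two_color_flag Optional logical, two-colour mixed-label flags.
#' @param truth_multiplet Optional logical, true multi-cell status.
#' @return List of class `multiplet_metrics` with elements
#'   `sensitivity`, `specificity` (each `list(value, ci, n)`; value `NA`
#'   when undefined), `one_vs_two_color`, and `vs_truth` when truth is
#'   given.
#' @export
multiplet_metrics <- function(mono_flag, expr_multiplet,
                              two_color_flag = NULL, truth_multiplet = NULL) {
  sens_spec <- function(flag, truth) {
    tp <- sum(flag & truth); fn <- sum(!flag & truth)
    tn <- sum(!flag & !truth); fp <- sum(flag & !truth)
    list(
      sensitivity = list(value = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                         ci = wilson_ci(tp, tp + fn), n = tp + fn),
      specificity = list(value = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                         ci = wilson_ci(tn, tn + fp), n = tn + fp))
  }
  out <- sens_spec(mono_flag, expr_multiplet)
  if (!is.null(two_color_flag)) {
    n <- length(mono_flag)
    k <- sum(mono_flag == two_color_flag)
    out$one_vs_two_color <- list(value = k / n, ci = wilson_ci(k, n), n = n)
  }
  if (!is.null(truth_multiplet)) {
    out$vs_truth <- sens_spec(mono_flag, truth_multiplet)
  }
  class(out) <- "multiplet_metrics"
  out
}

#' Estimate the total multiplet rate from expression purity calls
#'
#' Purity only exposes cross-species multiplets; if a fraction
#' 2 p_a p_b of multiplets is cross-species (two-species mixing, ignoring
#' higher orders), the total multiplet rate is the observed multiplet
#' fraction divided by 2 p_a p_b. Species proportions default to the
#' singlet-call composition of the same data.
#'
#' @param expr_calls Character vector from
#'   [call_species_from_expression()] (no-call entries are excluded).
#' @param species_proportions Optional length-2 proportions.
#' @return List: `rate` (point estimate), `ci` (Wilson interval, scaled),
#'   `observed_fraction`, `n`.
#' @export
estimate_doublet_rate <- function(expr_calls, species_proportions = NULL) {
  calls <- expr_calls[expr_calls != "no-call"]
  n <- length(calls)
  k <- sum(calls == "multiplet")
  if (is.null(species_proportions)) {
    single <- calls[calls != "multiplet"]
    species_proportions <- as.numeric(table(single) / length(single))
  }
  p <- species_proportions / sum(species_proportions)
  cross <- 2 * p[1] * p[2]
  ci <- wilson_ci(k, n)
  list(rate = (k / n) / cross, ci = ci / cross,
       observed_fraction = k / n, n = n)
}

#' Full validation report for a linked experiment
#'
#' Joins linked cells to their imaging records (by well) and expression
#' species counts (by barcode) and computes the mixing-experiment
#' validation statistics: linked fraction, species concordance,
#' abundance-corrected linking accuracy, multiplet sensitivity /
#' specificity (monochrome imaging vs expression purity), one- vs
#' two-colour imaging concordance, and the estimated multiplet rate.
#' All fractions carry Wilson 95% intervals.
#'
#' @param linked A `linked_cells` from [link()].
#' @param imaging An `imaging_records` data.frame.
#' @param counts A `species_counts` data.frame.
#' @param purity_threshold Expression multiplet threshold (default 0.7).
#' @param min_umis Minimum UMIs for an expression profile to count
#'   (default 20).
#' @param truth Optional `wells_truth` data.frame (from the simulator)
#'   for metrics against true labels.
#' @return A list of class `validation_report`.
#' @export
validation_report <- function(linked, imaging, counts,
                              purity_threshold = 0.7, min_umis = 20L,
                              truth = NULL) {
  stopifnot(inherits(linked, "linked_cells"))
  cells <- linked$cells
  profiles <- counts[!is.na(counts$purity) & counts$total >= min_umis, ]
  n_profiles <- nrow(profiles)
  lc <- cells[cells$link_status == "linked", ]
  lc <- lc[lc$sequencing_barcode %in% profiles$sequencing_barcode, ]
  # a profile counts as linked to imaging data only if its well produced
  # an imaging record
  lc <- lc[lc$well %in% imaging$well, ]
  n_linked <- nrow(lc)

  im <- imaging[match(lc$well, imaging$well), ]
  sc <- profiles[match(lc$sequencing_barcode, profiles$sequencing_barcode), ]
  attr(sc, "species") <- attr(counts, "species")
  expr_call <- call_species_from_expression(sc, purity_threshold)
  species <- attr(counts, "species")
  if (is.null(species)) species <- c("speciesA", "speciesB")

  conc <- concordance(im$species_label, expr_call, species = species)
  single <- expr_call[expr_call %in% species]
  props <- as.numeric(table(factor(single, levels = species)))
  acc <- if (sum(props) > 0) {
    linking_accuracy(conc$value, props / sum(props))
  } else list(value = NA_real_, chance = NA_real_)

  truth_flag <- NULL
  if (!is.null(truth)) {
    truth_flag <- truth$n_cells[match(lc$well, truth$well)] >= 2L
  }
  mm <- multiplet_metrics(im$multiplet_mono, expr_call == "multiplet",
                          two_color_flag = im$multiplet_two_color,
                          truth_multiplet = truth_flag)
  dr <- estimate_doublet_rate(expr_call)

  structure(list(
    n_profiles = n_profiles,
    n_linked = n_linked,
    linked_fraction = list(value = if (n_profiles > 0) n_linked / n_profiles
                           else NA_real_,
                           ci = wilson_ci(n_linked, n_profiles)),
    link_yield = linked$summary$yield,
    concordance = conc,
    linking_accuracy = acc,
    multiplet = mm,
    doublet_rate = dr,
    purity_threshold = purity_threshold
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("Mixing-experiment validation\n")
  cat(sprintf("  expression profiles      : %d (%d linked, %s)\n",
              x$n_profiles, x$n_linked, fmt(x$linked_fraction$value)))
  cat(sprintf("  link yield (per call)    : %s\n", fmt(x$link_yield)))
  cat(sprintf("  species concordance      : %s (n=%d)\n",
              fmt(x$concordance$value), x$concordance$n))
  cat(sprintf("  corrected link accuracy  : %s (chance %.3f)\n",
              if (is.na(x$linking_accuracy$value)) NA
              else sprintf("%.1f%%", 100 * x$linking_accuracy$value),
              x$linking_accuracy$chance))
  cat(sprintf("  multiplet sens/spec      : %s / %s (vs purity < %.0f%%)\n",
              fmt(x$multiplet$sensitivity$value),
              fmt(x$multiplet$specificity$value),
              100 * x$purity_threshold))
  if (!is.null(x$multiplet$one_vs_two_color)) {
    cat(sprintf("  one- vs two-colour       : %s\n",
                fmt(x$multiplet$one_vs_two_color$value)))
  }
  cat(sprintf("  est. multiplet rate      : %s\n", fmt(x$doublet_rate$rate)))
  invisible(x)
}
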
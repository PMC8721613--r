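# Marker-based estimation of the mixing fraction.
#
# In a sex-mismatched coculture, Y-chromosome transcripts come only from the
# male-donor population, so the ratio coculture/monoculture of a chrY marker
# estimates the fraction of the coculture transcriptome contributed by that
# population. The estimator is the arithmetic mean of per-marker ratios
# (mean-of-ratios), matching how the published per-donor averages are formed;
# it is not the ratio of summed marker signal.

#' Per-marker contribution ratio
#'
#' `100 * coculture / monoculture` for one population-exclusive marker gene:
#' the percentage of the marker-bearing population's monoculture signal that
#' survives in the coculture.
#'
#' @param mono_value Marker RPKM in the carrier population's monoculture
#'   (must be > 0).
#' @param co_value Marker RPKM in the coculture (>= 0).
#' @return Ratio in percent.
#' @export
per_marker_ratio <- function(mono_value, co_value) {
  if (any(!is.finite(mono_value)) || any(mono_value <= 0))
    stop("marker unusable: monoculture value must be > 0")
  if (any(!is.finite(co_value)) || any(co_value < 0))
    stop("coculture marker value must be finite and >= 0")
  100 * co_value / mono_value
}

#' Estimate the surviving-population fraction for one donor pair
#'
#' For each marker gene, computes the coculture/monoculture percentage via
#' [per_marker_ratio()] and averages over markers. Markers whose carrier
#' monoculture value does not exceed `floor` are excluded (ratios are
#' unstable near zero) and listed with the reason.
#'
#' The default estimator ignores residual marker expression in the
#' non-carrier population (chrY markers show trace RPKM in female
#' chondrocytes but are treated as absent). Setting `corrected = TRUE`
#' instead solves the one-step mixture `co = pi * carrier + (1 - pi) *
#' other` per marker, subtracting the scaled non-carrier residual; this is
#' an extension beyond the plain ratio estimator.
#'
#' @param mat Expression matrix (RPKM).
#' @param design A `coc_design`.
#' @param markers A `marker_set`.
#' @param pair_id Donor pair to estimate.
#' @param floor Marker usability floor on the monoculture RPKM (default 0.3).
#' @param corrected Use the residual-corrected estimator (default FALSE).
#' @return A list of class `proportion_estimate`: `pair_id`,
#'   `per_marker_ratio` (named percent vector over markers used),
#'   `mean_ratio` (percent), `n_markers_used`, `excluded_markers`
#'   (data.frame of id + reason), `corrected`.
#' @export
estimate_proportion <- function(mat, design, markers, pair_id,
                                floor = 0.3, corrected = FALSE) {
  check_design_matrix(design, mat)
  check_markers_matrix(markers, mat)
  trio <- trio_samples(design, pair_id)
  carrier_sample <- if (markers$carrier == "msc") trio$msc_mono else trio$ch_mono
  other_sample <- if (markers$carrier == "msc") trio$ch_mono else trio$msc_mono

  mono <- mat[markers$gene_ids, carrier_sample]
  other <- mat[markers$gene_ids, other_sample]
  co <- mat[markers$gene_ids, trio$coculture]

  usable <- mono > floor
  excluded <- data.frame(
    gene_id = markers$gene_ids[!usable],
    reason = sprintf("monoculture RPKM %.6g <= floor %.6g", mono[!usable], floor),
    stringsAsFactors = FALSE)
  if (!any(usable))
    stop(sprintf("pair '%s': no usable markers (all monoculture values <= %g)",
                 pair_id, floor))

  if (corrected) {
    # solve co = pi*carrier + (1-pi)*other per marker; needs carrier > other
    denom <- mono[usable] - other[usable]
    if (any(denom <= 0))
      stop(sprintf("pair '%s': corrected estimator needs carrier > non-carrier for every usable marker", pair_id))
    ratios <- 100 * (co[usable] - other[usable]) / denom
  } else {
    ratios <- per_marker_ratio(mono[usable], co[usable])
  }
  names(ratios) <- markers$gene_ids[usable]

  structure(list(pair_id = pair_id,
                 per_marker_ratio = ratios,
                 mean_ratio = mean(ratios),
                 n_markers_used = sum(usable),
                 excluded_markers = excluded,
                 corrected = corrected),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("Proportion estimate for pair %s (%d marker%s%s)\n",
              x$pair_id, x$n_markers_used,
              if (x$n_markers_used == 1) "" else "s",
              if (x$corrected) ", residual-corrected" else ""))
  for (g in names(x$per_marker_ratio))
    cat(sprintf("  %-10s %9.5f %%\n", g, x$per_marker_ratio[[g]]))
  cat(sprintf("  %-10s %9.5f %%\n", "Average", x$mean_ratio))
  if (nrow(x$excluded_markers) > 0)
    cat("  excluded:", paste(x$excluded_markers$gene_id, collapse = ", "), "\n")
  invisible(x)
}

#' Pool per-pair estimates into one mixing fraction
#'
#' Averages the per-pair mean percentages and converts to a fraction
#' `pi` in `[0, 1]`. Pooling across pairs yields the single global weight
#' applied to every pair downstream (including pairs whose markers are
#' uninformative, e.g. a female-female pair with chrY markers). Rounding to
#' 2 decimals reproduces the conventional printed weights (0.57 / 0.43);
#' `rounding = NULL` keeps full precision and is preferred for new analyses.
#'
#' @param estimates List of `proportion_estimate` objects (or a single one).
#' @param rounding Decimal places for `pi`, or NULL for none (default 2).
#' @return A list of class `mixing_fraction`: `pi`, `pi_complement`,
#'   `per_pair` (named percent vector), `rounding`, `n_pairs`.
#' @export
pool_proportions <- function(estimates, rounding = 2) {
  if (inherits(estimates, "proportion_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0) stop("no proportion estimates to pool")
  means <- vapply(estimates, function(e) e$mean_ratio, numeric(1))
  names(means) <- vapply(estimates, function(e) e$pair_id, character(1))
  pi_hat <- mean(means) / 100
  if (!is.null(rounding)) pi_hat <- round(pi_hat, rounding)
  if (pi_hat > 1) {
    warning("estimated mixing fraction ", format(pi_hat), " exceeds 1; clamped")
    pi_hat <- 1
  }
  if (pi_hat < 0) {
    warning("estimated mixing fraction ", format(pi_hat), " below 0; clamped")
    pi_hat <- 0
  }
  structure(list(pi = pi_hat, pi_complement = 1 - pi_hat,
                 per_pair = means, rounding = rounding,
                 n_pairs = length(means)),
            class = "mixing_fraction")
}

#' @export
print.mixing_fraction <- function(x, ...) {
  cat(sprintf("Mixing fraction pi = %s (complement %s) pooled over %d pair%s\n",
              format(x$pi), format(x$pi_complement), x$n_pairs,
              if (x$n_pairs == 1) "" else "s"))
  invisible(x)
}

#' Compare the estimated fraction with the seeded fraction
#'
#' Cell attrition summary: how far the transcriptome-estimated fraction of
#' the marker-bearing population has dropped from its seeded proportion
#' (e.g. seeded at 80% MSCs but contributing only 57% of coculture RNA
#' after a week).
#'
#' @param pi Estimated mixing fraction, in (0, 1).
#' @param seeded_fraction Seeded proportion of the same population, in (0, 1).
#' @return A list: `seeded_fraction`, `estimated_fraction`, `drop`
#'   (seeded - estimated, in fraction units), `drop_percent_points`,
#'   `relative_retention` (estimated / seeded).
#' @export
attrition_report <- function(pi, seeded_fraction) {
  if (!is.finite(pi) || pi <= 0 || pi >= 1)
    stop("pi must be in (0, 1)")
  if (!is.finite(seeded_fraction) || seeded_fraction <= 0 || seeded_fraction >= 1)
    stop("seeded_fraction must be in (0, 1)")
  list(seeded_fraction = seeded_fraction,
       estimated_fraction = pi,
       drop = seeded_fraction - pi,
       drop_percent_points = 100 * (seeded_fraction - pi),
       relative_retention = pi / seeded_fraction)
}

#' Per-marker ratio table in the published layout
#'
#' Builds a data.frame with one row per marker and one ratio column per
#' donor pair, plus a final `Average` row, mirroring the familiar
#' marker-table layout (gene rows, `([pair + ch]/pair) * 100` columns).
#'
#' @param estimates List of `proportion_estimate` objects.
#' @return Data.frame with `gene_id` and one percent column per pair.
#' @export
proportion_table <- function(estimates) {
  if (inherits(estimates, "proportion_estimate")) estimates <- list(estimates)
  genes <- unique(unlist(lapply(estimates, function(e) names(e$per_marker_ratio))))
  out <- data.frame(gene_id = c(genes, "Average"), stringsAsFactors = FALSE)
  for (e in estimates) {
    col <- c(e$per_marker_ratio[genes], e$mean_ratio)
    out[[paste0("ratio_pct_", e$pair_id)]] <- unname(col)
  }
  out
}
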
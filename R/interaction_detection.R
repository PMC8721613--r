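# Additivity screening: expected coculture expression under a convex
# mixture of the two monocultures, fold-change deviation from that
# expectation, expression-floor filtering, per-gene calls and cross-pair
# consensus.
#
# The null model is additivity: a coculture's expression of a gene is the
# pi-weighted combination of the two monoculture values, with no cell-cell
# interaction effect. Genes whose observed/expected fold change clears the
# cutoffs are called interaction-regulated.

#' Expected coculture expression under additivity
#'
#' `pi * msc_mono + (1 - pi) * ch_mono`: the convex combination of the two
#' monoculture RPKM values weighted by the mixing fraction.
#'
#' @param msc_mono MSC monoculture RPKM (>= 0; vectorised).
#' @param ch_mono Chondrocyte monoculture RPKM (>= 0; vectorised).
#' @param pi Mixing fraction in `[0, 1]`.
#' @return Expected coculture RPKM.
#' @export
expected_coculture <- function(msc_mono, ch_mono, pi) {
  if (!is.finite(pi) || pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  if (any(!is.finite(msc_mono)) || any(msc_mono < 0) ||
      any(!is.finite(ch_mono)) || any(ch_mono < 0))
    stop("monoculture values must be finite and >= 0")
  pi * msc_mono + (1 - pi) * ch_mono
}

#' Fold change of observed vs expected coculture expression
#'
#' `co_observed / co_expected`; a value near 1 means the observed
#' expression matches the additive expectation.
#'
#' @param co_observed Observed coculture RPKM.
#' @param co_expected Expected coculture RPKM (> 0; genes whose trio fails
#'   the expression floor must be filtered before this is evaluated).
#' @return Fold change (dimensionless).
#' @export
fold_change <- function(co_observed, co_expected) {
  if (any(!is.finite(co_expected)) || any(co_expected <= 0))
    stop("fold change undefined: expected value must be > 0 (filter first)")
  co_observed / co_expected
}

#' Expression floor filter for one trio
#'
#' A gene is kept only if its value is strictly above `floor` in each of
#' the trio's three samples (both monocultures and the coculture). This
#' guards the fold change against near-zero denominators.
#'
#' @param trio_values Numeric vector (or matrix with 3 columns, genes in
#'   rows) of the trio's RPKM values.
#' @param floor RPKM floor, default 0.3.
#' @return Logical: keep (TRUE) or drop (FALSE); vectorised over rows when
#'   given a matrix.
#' @export
floor_filter <- function(trio_values, floor = 0.3) {
  if (!is.finite(floor) || floor < 0) stop("floor must be >= 0 and finite")
  if (is.matrix(trio_values)) {
    apply(trio_values > floor, 1, all)
  } else {
    all(trio_values > floor)
  }
}

#' Classify a gene from its fold change
#'
#' Strict inequalities: `up` if `fc > up_cutoff`, `down` if
#' `fc < down_cutoff`, otherwise `additive`. The default cutoffs (2 and
#' 0.5) are symmetric on the log scale.
#'
#' @param fc Fold change(s).
#' @param up_cutoff Upper cutoff (default 2).
#' @param down_cutoff Lower cutoff (default 0.5).
#' @return Character vector: `"up"`, `"down"` or `"additive"`.
#' @export
classify_gene <- function(fc, up_cutoff = 2, down_cutoff = 0.5) {
  if (!(0 < down_cutoff && down_cutoff < up_cutoff))
    stop("need 0 < down_cutoff < up_cutoff")
  ifelse(fc > up_cutoff, "up", ifelse(fc < down_cutoff, "down", "additive"))
}

#' Additivity screen for one donor pair
#'
#' Runs the whole per-pair procedure: applies the expression floor to every
#' gene's trio, computes the additive expectation and fold change for
#' retained genes, and assigns each gene exactly one call (`up`, `down`,
#' `additive` or `filtered`).
#'
#' @param mat Expression matrix (RPKM).
#' @param design A `coc_design`.
#' @param pair_id Donor pair to screen.
#' @param pi Mixing fraction (e.g. from [pool_proportions()]; a
#'   `mixing_fraction` object is also accepted).
#' @param floor Expression floor (default 0.3).
#' @param up_cutoff,down_cutoff Fold-change cutoffs (defaults 2 and 0.5).
#' @param floor_scope `"trio"` (default): the floor applies to the three
#'   samples of this pair's trio; `"global"`: to every sample in the matrix.
#' @return A list of class `additivity_result`: `pair_id`, `pi`, `table`
#'   (data.frame gene_id, msc_mono, ch_mono, co_observed, co_expected, fc,
#'   call — genes in lexicographic order, fc/co_expected NA for filtered
#'   genes), and `counts` (n_up, n_down, n_additive, n_filtered).
#' @export
detect_pair <- function(mat, design, pair_id, pi, floor = 0.3,
                        up_cutoff = 2, down_cutoff = 0.5,
                        floor_scope = c("trio", "global")) {
  floor_scope <- match.arg(floor_scope)
  if (inherits(pi, "mixing_fraction")) pi <- pi$pi
  check_design_matrix(design, mat)
  trio <- trio_samples(design, pair_id)

  ord <- order(rownames(mat))
  msc <- mat[ord, trio$msc_mono]
  ch <- mat[ord, trio$ch_mono]
  co <- mat[ord, trio$coculture]

  keep <- if (floor_scope == "trio") {
    floor_filter(cbind(msc, ch, co), floor)
  } else {
    apply(mat[ord, , drop = FALSE] > floor, 1, all)
  }

  expected <- rep(NA_real_, length(msc))
  fc <- rep(NA_real_, length(msc))
  call <- rep("filtered", length(msc))
  if (any(keep)) {
    expected[keep] <- expected_coculture(msc[keep], ch[keep], pi)
    fc[keep] <- fold_change(co[keep], expected[keep])
    call[keep] <- classify_gene(fc[keep], up_cutoff, down_cutoff)
  }

  tab <- data.frame(gene_id = rownames(mat)[ord],
                    msc_mono = unname(msc), ch_mono = unname(ch),
                    co_observed = unname(co), co_expected = unname(expected),
                    fc = unname(fc), call = call,
                    stringsAsFactors = FALSE)
  counts <- c(n_up = sum(call == "up"), n_down = sum(call == "down"),
              n_additive = sum(call == "additive"),
              n_filtered = sum(call == "filtered"))
  structure(list(pair_id = pair_id, pi = pi, table = tab, counts = counts,
                 params = list(floor = floor, up_cutoff = up_cutoff,
                               down_cutoff = down_cutoff,
                               floor_scope = floor_scope)),
            class = "additivity_result")
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf("Additivity screen for pair %s (pi = %s): %d up, %d down, %d additive, %d filtered\n",
              x$pair_id, format(x$pi), x$counts[["n_up"]], x$counts[["n_down"]],
              x$counts[["n_additive"]], x$counts[["n_filtered"]]))
  invisible(x)
}

#' Consensus of per-pair calls across donor pairs
#'
#' Intersects the up- and down-call sets of two or more pairs: per-gene
#' call counts, membership in every exclusive Venn region of the pairwise
#' decomposition, and the k-of-n intersection lists (the headline sets are
#' the all-pairs intersections). Gene order in every output is
#' lexicographic for determinism.
#'
#' @param results List of `additivity_result` objects over the same gene
#'   universe.
#' @return A list of class `consensus_result`: `pair_ids`; `genes`
#'   (data.frame gene_id, up_count, down_count); `regions` (data.frame
#'   direction, region — pair ids joined by `&` —, n_genes); `k_of_n`
#'   (nested list `up`/`down` of gene-id vectors by minimum pair count);
#'   `n_pairs`.
#' @export
consensus <- function(results) {
  if (length(results) < 2) stop("consensus needs >= 2 pairs")
  universe <- results[[1]]$table$gene_id
  for (r in results[-1]) {
    if (!identical(sort(r$table$gene_id), sort(universe)))
      stop("mismatched gene universes across pairs")
  }
  universe <- sort(universe)
  pair_ids <- vapply(results, function(r) r$pair_id, character(1))
  if (anyDuplicated(pair_ids)) stop("duplicate pair ids in consensus input")
  n <- length(results)

  calls <- sapply(results, function(r) r$table$call[match(universe, r$table$gene_id)])
  up <- calls == "up"
  down <- calls == "down"

  genes <- data.frame(gene_id = universe,
                      up_count = rowSums(up), down_count = rowSums(down),
                      stringsAsFactors = FALSE)

  # exclusive Venn regions: one row per non-empty subset of pairs
  region_rows <- list()
  subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  members <- list(up = list(), down = list())
  for (dir in c("up", "down")) {
    inset <- if (dir == "up") up else down
    for (s in subsets) {
      in_region <- rowSums(inset[, s, drop = FALSE]) == length(s) &
        rowSums(inset[, -s, drop = FALSE]) == 0
      key <- paste(pair_ids[s], collapse = "&")
      region_rows[[length(region_rows) + 1]] <-
        data.frame(direction = dir, region = key, n_genes = sum(in_region),
                   stringsAsFactors = FALSE)
      members[[dir]][[key]] <- universe[in_region]
    }
  }
  regions <- do.call(rbind, region_rows)

  k_of_n <- list(up = list(), down = list())
  for (k in seq_len(n)) {
    k_of_n$up[[k]] <- universe[genes$up_count >= k]
    k_of_n$down[[k]] <- universe[genes$down_count >= k]
  }

  structure(list(pair_ids = pair_ids, genes = genes, regions = regions,
                 region_members = members, k_of_n = k_of_n, n_pairs = n),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  n_up <- length(x$k_of_n$up[[x$n_pairs]])
  n_down <- length(x$k_of_n$down[[x$n_pairs]])
  cat(sprintf("Consensus over %d pairs (%s): %d genes up in all, %d down in all\n",
              x$n_pairs, paste(x$pair_ids, collapse = ", "), n_up, n_down))
  invisible(x)
}

#' Parametric-bootstrap p-value for a fold-change deviation
#'
#' Optional significance measure for one gene's deviation from additivity;
#' off by default in the pipeline, which calls genes on fold-change
#' thresholds alone. Under the null (pure additivity with multiplicative
#' log-normal measurement noise of standard deviation `sigma` on the
#' coculture measurement and on each monoculture), the trio is resampled,
#' the fold change recomputed, and the p-value is the two-sided tail
#' probability of `|log fc|` at least as extreme as observed, with add-one
#' correction `p = (1 + n_extreme) / (1 + n_resamples)`.
#'
#' @param msc_mono,ch_mono,co_observed The trio's RPKM values for the gene.
#' @param pi Mixing fraction.
#' @param sigma Log-scale noise standard deviation (> 0 for a meaningful
#'   null; `sigma = 0` with a non-unit fold change returns the add-one
#'   floor with a warning).
#' @param n_resamples Number of bootstrap resamples (>= 100; default 999).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return p-value in (0, 1].
#' @export
deviation_pvalue <- function(msc_mono, ch_mono, co_observed, pi, sigma,
                             n_resamples = 999, seed = 1) {
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  expected <- expected_coculture(msc_mono, ch_mono, pi)
  fc_obs <- fold_change(co_observed, expected)
  stat_obs <- abs(log(fc_obs))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  e_m <- stats::rnorm(n_resamples, 0, sigma)
  e_c <- stats::rnorm(n_resamples, 0, sigma)
  e_o <- stats::rnorm(n_resamples, 0, sigma)
  expected_b <- expected_coculture(msc_mono * exp(e_m), ch_mono * exp(e_c), pi)
  co_b <- expected * exp(e_o)
  stat_b <- abs(log(fold_change(co_b, expected_b)))

  if (sigma == 0 && stat_obs > 0)
    warning("sigma = 0 with a non-unit fold change: p-value is the add-one floor")
  p <- (1 + sum(stat_b >= stat_obs)) / (1 + n_resamples)
  min(p, 1)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
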
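# End-to-end pipeline: estimate the mixing fraction from markers, screen
# every donor pair for deviation from additivity, intersect the calls, and
# write audited result tables plus a run manifest.

#' Pipeline configuration
#'
#' Bundles input paths and screen parameters, with the conventional
#' defaults (0.3 expression floor, fold-change cutoffs 2 and 0.5, pooled
#' mixing fraction rounded to 2 decimals). Accepts either explicit
#' arguments or a YAML file with the same keys (flat `paths:` /
#' `parameters:` sections).
#'
#' @param matrix,design,markers,outdir Input file paths and output
#'   directory.
#' @param floor Expression floor (RPKM).
#' @param up_cutoff,down_cutoff Fold-change cutoffs.
#' @param rounding Decimal places for the pooled mixing fraction, or NULL.
#' @param floor_scope `"trio"` or `"global"`.
#' @param pooling `"global"` (one fraction for all pairs) or `"per_pair"`.
#' @param pvalues Compute bootstrap deviation p-values (off by default; the
#'   screen calls genes on fold-change thresholds alone).
#' @param pvalue_sigma,pvalue_resamples Bootstrap null parameters, used
#'   only when `pvalues = TRUE`.
#' @param seed Integer seed for any resampling.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, design, markers, outdir,
                            floor = 0.3, up_cutoff = 2, down_cutoff = 0.5,
                            rounding = 2, floor_scope = "trio",
                            pooling = c("global", "per_pair"),
                            pvalues = FALSE, pvalue_sigma = 0.1,
                            pvalue_resamples = 999, seed = 1) {
  pooling <- match.arg(pooling)
  stopifnot(floor >= 0, 0 < down_cutoff, down_cutoff < up_cutoff)
  structure(list(paths = list(matrix = matrix, design = design,
                              markers = markers, outdir = outdir),
                 parameters = list(floor = floor, up_cutoff = up_cutoff,
                                   down_cutoff = down_cutoff,
                                   rounding = rounding,
                                   floor_scope = floor_scope,
                                   pooling = pooling, pvalues = pvalues,
                                   pvalue_sigma = pvalue_sigma,
                                   pvalue_resamples = pvalue_resamples),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with `paths:` and `parameters:` sections (and an
#'   optional top-level `seed:`), keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- c(y$paths, y$parameters)
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipeline_config, args)
}

#' Run the full coculture additivity pipeline
#'
#' Stages: read and validate inputs; estimate the marker-based proportion
#' for every pair whose markers are usable; pool into the mixing
#' fraction(s); screen every pair against the additive expectation;
#' intersect calls across pairs. Writes, under `outdir`:
#' `proportion_table.tsv` (per-marker ratios plus Average row),
#' `pair_<id>_results.tsv` per pair, `consensus_genes.tsv`,
#' `venn_regions.tsv`, and `manifest.json` (parameters, seed, package
#' version, input checksums). Every table carries `# key=value` header
#' lines recording the parameters that produced it. Progress is logged to
#' stderr; results go to files only.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, a list with `proportions`, `pi`, `pairs` (per-pair
#'   `additivity_result`s), `consensus` (NULL if < 2 pairs) and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$parameters
  log_msg <- function(stage, fmt, ...)
    message(sprintf("[cocultex] %s: %s", stage, sprintf(fmt, ...)))

  log_msg("read", "loading %s", config$paths$matrix)
  mat <- read_expression_table(config$paths$matrix)
  design <- read_design(config$paths$design)
  markers <- read_markers(config$paths$markers)
  check_design_matrix(design, mat)
  check_markers_matrix(markers, mat)
  pair_ids <- sort(unique(design$pair_id))
  log_msg("read", "%d genes, %d samples, %d pairs, %d markers",
          nrow(mat), ncol(mat), length(pair_ids), length(markers$gene_ids))

  estimates <- list()
  for (pid in pair_ids) {
    est <- tryCatch(
      estimate_proportion(mat, design, markers, pid, floor = p$floor),
      error = function(e) NULL)
    if (is.null(est)) {
      log_msg("estimate", "pair %s: markers uninformative, using pooled fraction", pid)
    } else {
      log_msg("estimate", "pair %s: mean ratio %.5f%% over %d markers",
              pid, est$mean_ratio, est$n_markers_used)
      estimates[[pid]] <- est
    }
  }
  if (length(estimates) == 0)
    stop("stage estimate: no pair has usable markers")

  pooled <- pool_proportions(estimates, rounding = p$rounding)
  pi_for <- function(pid) {
    if (p$pooling == "per_pair" && pid %in% names(pooled$per_pair)) {
      v <- pooled$per_pair[[pid]] / 100
      if (!is.null(p$rounding)) v <- round(v, p$rounding)
      min(max(v, 0), 1)
    } else pooled$pi
  }
  log_msg("pool", "mixing fraction pi = %s (complement %s, pooling = %s)",
          format(pooled$pi), format(pooled$pi_complement), p$pooling)

  results <- list()
  for (pid in pair_ids) {
    res <- detect_pair(mat, design, pid, pi_for(pid), floor = p$floor,
                       up_cutoff = p$up_cutoff, down_cutoff = p$down_cutoff,
                       floor_scope = p$floor_scope)
    if (isTRUE(p$pvalues)) {
      tab <- res$table
      keep <- tab$call != "filtered"
      pv <- rep(NA_real_, nrow(tab))
      pv[keep] <- vapply(which(keep), function(i)
        deviation_pvalue(tab$msc_mono[i], tab$ch_mono[i], tab$co_observed[i],
                         res$pi, p$pvalue_sigma, p$pvalue_resamples,
                         seed = config$seed + i), numeric(1))
      res$table$p_value <- pv
    }
    log_msg("detect", "pair %s: %d up, %d down, %d additive, %d filtered",
            pid, res$counts[["n_up"]], res$counts[["n_down"]],
            res$counts[["n_additive"]], res$counts[["n_filtered"]])
    results[[pid]] <- res
  }

  cons <- NULL
  if (length(results) >= 2) {
    cons <- consensus(results)
    log_msg("consensus", "%d genes up in all %d pairs, %d down in all",
            length(cons$k_of_n$up[[cons$n_pairs]]), cons$n_pairs,
            length(cons$k_of_n$down[[cons$n_pairs]]))
  }

  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(pi = format(pooled$pi), floor = p$floor, up_cutoff = p$up_cutoff,
           down_cutoff = p$down_cutoff, floor_scope = p$floor_scope,
           pooling = p$pooling, seed = config$seed)
  paths <- c(proportions = file.path(outdir, "proportion_table.tsv"))
  write_results(paths[["proportions"]], proportion_table(estimates), hdr)
  for (pid in names(results)) {
    f <- file.path(outdir, sprintf("pair_%s_results.tsv", pid))
    write_results(f, results[[pid]]$table, hdr)
    paths[[paste0("pair_", pid)]] <- f
  }
  if (!is.null(cons)) {
    paths[["consensus"]] <- file.path(outdir, "consensus_genes.tsv")
    write_results(paths[["consensus"]], cons$genes, hdr)
    paths[["venn"]] <- file.path(outdir, "venn_regions.tsv")
    write_results(paths[["venn"]], cons$regions, hdr)
  }

  manifest <- list(
    package = "cocultex",
    version = as.character(utils::packageVersion("cocultex")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = p,
    inputs = lapply(config$paths[c("matrix", "design", "markers")], function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    pi = pooled$pi,
    per_pair_mean_ratio_pct = as.list(pooled$per_pair),
    # file names relative to outdir so reruns elsewhere stay byte-identical
    outputs = lapply(as.list(paths), basename))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths[["manifest"]] <- manifest_path
  log_msg("write", "results under %s", outdir)

  invisible(list(proportions = estimates, pi = pooled, pairs = results,
                 consensus = cons, paths = paths))
}
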
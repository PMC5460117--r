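#' Write the full report of a cutoff scan
#'
#' Writes, per cutoff `c` (with persistence filter `p`):
#' `edges_cutoff<c>_pcrit<p>.tsv` (edge list),
#' `hubs_cutoff<c>.csv`, `components_cutoff<c>.csv`,
#' `jackknife_cutoff<c>.csv`, plus one machine-readable `summary.json`
#' holding the per-cutoff summary, hub histograms, top-k component sizes
#' and jackknife estimates. Output contains no timestamps; re-running on
#' identical inputs produces byte-identical files.
#'
#' @param result a [CutoffScanResult-class]
#' @param outdir output directory (created if missing)
#' @return character vector of files written, invisibly
#' @export
writeReport <- function(result, outdir) {
  stopifnot(is(result, "CutoffScanResult"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, mode = 2L) != 0L)
    stop("output directory not writable: ", outdir)
  cfg <- result@config
  files <- character(0)
  summary_list <- list(
    parameters = list(
      cutoffs = cfg@cutoffs, p_crit = cfg@pCrit, n_subsets = cfg@nSubsets,
      min_hub_degree = cfg@minHubDegree, top_k = cfg@topK,
      excluded_resnames = cfg@excludedResnames,
      min_seq_separation = cfg@minSeqSeparation,
      n_nodes = nrow(result@nodes)),
    per_cutoff = list())

  for (key in names(result@perCutoff)) {
    pc <- result@perCutoff[[key]]
    tag <- sprintf("cutoff%s_pcrit%g", key, cfg@pCrit)
    f_edges <- file.path(outdir, paste0("edges_", tag, ".tsv"))
    writeEdgeList(pc$graph, f_edges)
    f_hubs <- file.path(outdir, sprintf("hubs_cutoff%s.csv", key))
    writeHubCsv(pc$hubs, f_hubs)
    f_comp <- file.path(outdir, sprintf("components_cutoff%s.csv", key))
    writeComponentCsv(pc$components, f_comp)
    f_jack <- file.path(outdir, sprintf("jackknife_cutoff%s.csv", key))
    writeJackknifeCsv(pc$jackknife, f_jack)
    files <- c(files, f_edges, f_hubs, f_comp, f_jack)

    hist <- degreeHistogram(pc$hubs)
    sz <- componentSizes(pc$components)
    topk <- utils::head(sz, cfg@topK)
    est <- estimates(pc$jackknife)
    summary_list$per_cutoff[[key]] <- list(
      cutoff = pc$cutoff,
      n_edges = pc$nEdges,
      n_hubs = nrow(hubs(pc$hubs)),
      hub_histogram = as.list(stats::setNames(as.integer(hist),
                                              names(hist))),
      n_components = length(sz),
      n_non_singleton_components = pc$nNonSingletonComponents,
      fraction_largest_component = pc$fractionLargestComponent,
      top_component_sizes = as.integer(topk),
      jackknife = lapply(seq_len(nrow(est)), function(r) list(
        observable = est$observable[r],
        full_value = est$full_value[r],
        theta_dot = est$theta_dot[r],
        se = est$se[r],
        n = est$n[r]))
    )
  }

  f_json <- file.path(outdir, "summary.json")
  json <- jsonlite::toJSON(summary_list, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
  writeLines(json, f_json)
  files <- c(files, f_json)
  invisible(files)
}

#' Read back a scan summary written by [writeReport()]
#'
#' @param path path to `summary.json`
#' @return the parsed summary list
#' @export
readReportSummary <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
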
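#' Run the full enrichment + network pipeline
#'
#' Orchestrates atlas load, per-gene highest-expression sets, Monte-Carlo
#' reference simulation, region scoring, and — when significant regions
#' exist — the incidence matrix, weighted gene network, nodal strength,
#' betweenness, Louvain clustering and per-region cluster composition.
#' All module outputs are written as TSV (plus GraphML for the network)
#' under `out_dir` together with a `manifest.json` recording every analytic
#' choice, seed and derived quantity needed to reproduce the run
#' bit-exactly. On a stage error, outputs produced so far are retained and
#' a `FAILED` marker file names the stage.
#'
#' @param atlas Path to an atlas TSV, or an `ExpressionAtlas`.
#' @param genes Path to a gene-list text file, or a `GeneList` / character
#'   vector.
#' @param out_dir Output directory (created if needed).
#' @param dialect Atlas dialect for file input ([read_atlas()]).
#' @param z_high Highest-expression threshold multiplier (default 1.96).
#' @param sd_method SD denominator convention (default `"sample"`).
#' @param iterations Reference-simulation iterations (default 1e6; use
#'   1e4 for a fast profile).
#' @param seed Seed for the reference simulation.
#' @param alpha,correction,tail,n_tests,p_source Passed to
#'   [score_regions()]; `n_tests` defaults to the number of atlas regions;
#'   `p_source = "empirical"` implies `keep_histogram = TRUE`.
#' @param include_empty_genes Null universe includes empty-set genes
#'   (default TRUE).
#' @param keep_histogram Retain per-iteration counts for empirical
#'   p-values (default FALSE).
#' @param distance_mode Betweenness distance transform (default
#'   `"inverse_weight"`).
#' @param resolution,louvain_seed Louvain parameters.
#' @param stability_k Seeds for the Louvain stability report (default 10).
#' @return Invisibly, a list with all intermediate objects (`index`,
#'   `reference`, `enrichment`, `incidence`, `network`, `clusters`,
#'   `composition`, ...) and the manifest.
#' @export
run_pipeline <- function(atlas, genes, out_dir,
                         dialect = c("wide", "hpa_long"),
                         z_high = 1.96,
                         sd_method = c("sample", "population"),
                         iterations = 1e6L, seed = 1L,
                         alpha = 0.05,
                         correction = c("bonferroni", "none"),
                         tail = c("one", "two"),
                         p_source = c("normal", "empirical"),
                         n_tests = NULL,
                         include_empty_genes = TRUE,
                         keep_histogram = FALSE,
                         distance_mode = c("inverse_weight", "unweighted",
                                           "weight_as_cost"),
                         resolution = 1.0, louvain_seed = 1L,
                         stability_k = 10L) {
  dialect <- match.arg(dialect)
  sd_method <- match.arg(sd_method)
  correction <- match.arg(correction)
  tail <- match.arg(tail)
  p_source <- match.arg(p_source)
  if (p_source == "empirical") keep_histogram <- TRUE
  distance_mode <- match.arg(distance_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  res <- list()
  tryCatch({
    stage <- "atlas_load"
    if (is.character(atlas)) atlas <- read_atlas(atlas, dialect)
    stopifnot(inherits(atlas, "ExpressionAtlas"))
    stage <- "gene_list"
    gl <- if (is.character(genes) && length(genes) == 1 && file.exists(genes))
      read_gene_list(genes) else gene_list(genes)
    stage <- "resolve"
    rr <- resolve_genes(atlas, gl)
    X <- length(rr$resolved)
    stage <- "high_expression"
    index <- high_expression_sets(atlas, z_high, sd_method)
    write_high_expression(index, file.path(out_dir, "high_expression.tsv"))
    stage <- "reference_simulation"
    reference <- simulate_reference(index, X, iterations, seed,
                                    include_empty_genes, keep_histogram)
    write_reference(reference, file.path(out_dir, "reference.tsv"))
    stage <- "scoring"
    if (is.null(n_tests)) n_tests <- length(atlas_regions(atlas))
    obs <- observed_counts(index, rr$resolved)
    enrichment <- score_regions(obs, reference, alpha, n_tests,
                                correction, tail, p_source)
    write_enrichment(enrichment, file.path(out_dir, "enrichment.tsv"))
    sig <- significant_regions(enrichment)
    res <- list(atlas = atlas, resolved = rr$resolved,
                missing = rr$missing, X = X, index = index,
                reference = reference, enrichment = enrichment,
                significant_regions = sig)
    if (length(sig)) {
      stage <- "incidence"
      incidence <- build_incidence(index, rr$resolved, sig)
      write_incidence(incidence, file.path(out_dir, "incidence.tsv"))
      stage <- "network"
      net <- project_network(incidence)
      write_edge_list(net, file.path(out_dir, "edges.tsv"))
      write_graphml(net, file.path(out_dir, "network.graphml"))
      stage <- "nodal_metrics"
      strength <- nodal_strength(net)
      btw <- betweenness_centrality(net, distance_mode)
      stage <- "louvain"
      clusters <- louvain_cluster(net, resolution, louvain_seed)
      stability <- louvain_stability(net, resolution, louvain_seed,
                                     stability_k)
      fwrite(stability, file.path(out_dir, "louvain_stability.tsv"),
             sep = "\t")
      write_nodal_metrics(net, strength, btw, clusters,
                          file.path(out_dir, "nodal_metrics.tsv"))
      write_cluster_gene_lists(clusters, out_dir)
      stage <- "composition"
      composition <- region_cluster_composition(incidence, clusters)
      write_composition(composition, file.path(out_dir, "composition.tsv"))
      res <- c(res, list(incidence = incidence, network = net,
                         strength = strength, betweenness = btw,
                         clusters = clusters, stability = stability,
                         composition = composition))
    } else {
      message("no significant regions; network stage skipped")
    }
    stage <- "manifest"
    manifest <- list(
      package = "neuroenrich",
      version = as.character(utils::packageVersion("neuroenrich")),
      n_genes = nrow(atlas$values), n_regions = ncol(atlas$values),
      gene_list_provenance = attr(gl, "provenance"),
      n_list = length(gl), X = X,
      n_missing = length(rr$missing),
      universe_size = reference$universe_size,
      z_high = z_high, sd_method = sd_method,
      iterations = as.integer(iterations), seed = as.integer(seed),
      alpha = alpha, correction = correction, tail = tail,
      p_source = p_source,
      n_tests = n_tests,
      per_test_level = attr(enrichment, "per_test_level"),
      include_empty_genes = include_empty_genes,
      keep_histogram = keep_histogram,
      distance_mode = distance_mode,
      resolution = resolution, louvain_seed = as.integer(louvain_seed),
      significant_regions = as.list(sig),
      n_contributing_genes = if (length(sig)) nrow(res$incidence) else 0L,
      n_clusters = if (length(sig)) res$clusters$n_clusters else NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Emit a synthetic dataset to disk
#'
#' Writes the atlas (wide TSV), the truth (JSON) and one gene-list text
#' file per requested list, for driving the pipeline from files.
#'
#' @param spec A `SyntheticSpec`.
#' @param out_dir Output directory.
#' @param lists Named list of `list(n_signal=, n_background=, seed=,
#'   program=)` specs for [generate_gene_list()]; one text file per entry.
#' @return Invisibly, the `generate_atlas()` result.
#' @export
write_synthetic_dataset <- function(spec, out_dir, lists = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_atlas(spec)
  write_atlas(gen$atlas, file.path(out_dir, "atlas.tsv"))
  truth <- list(
    gene_program = as.list(gen$truth$gene_program),
    programs = lapply(gen$truth$programs, function(p)
      list(members = p$members, regions = p$regions,
           multiplier = p$multiplier)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(lists)) {
    a <- lists[[nm]]
    gl <- generate_gene_list(gen$truth, a$n_signal, a$n_background,
                             seed = a$seed %||% 1L,
                             program = a$program)
    writeLines(as.character(gl), file.path(out_dir, paste0(nm, ".txt")))
  }
  invisible(gen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
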
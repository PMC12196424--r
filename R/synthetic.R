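#' Specify a synthetic expression atlas
#'
#' Describes a synthetic gene x region nTPM atlas emulating the structure a
#' brain expression atlas presents to the pipeline: per-gene log-normal
#' baselines (non-negative, heavy right skew, levels and dispersions varying
#' across genes) plus a minority of "program" genes whose expression in a
#' few target regions is multiplied by a large factor — the planted
#' region-specific high-expression signal.
#'
#' Defaults match the desk-scale validation world: 2000 genes, 50 regions,
#' one 40-gene program targeting one region with multiplier 50. Baseline
#' per-gene parameters are drawn as `meanlog ~ U(-1, 3)` and
#' `sdlog ~ U(0.5, 1.5)`, giving median region values of roughly 0.4-20
#' nTPM with occasional large outliers, the shape bulk transcriptomic
#' abundances show.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_regions Number of regions (>= 6; below that the z > 1.96 rule
#'   can never fire under the n-1 SD convention).
#' @param programs List of programs, each a list with `regions` (integer
#'   region indices or region ids), `n_genes` (program size) and
#'   `multiplier` (> 1). Program gene sets are disjoint.
#' @param meanlog_range,sdlog_range Ranges for per-gene log-normal baseline
#'   parameters.
#' @param seed Integer seed.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_regions = 50L,
                           programs = list(list(regions = 1L,
                                                n_genes = 40L,
                                                multiplier = 50)),
                           meanlog_range = c(-1, 3),
                           sdlog_range = c(0.5, 1.5),
                           seed = 1L) {
  n_genes <- as.integer(n_genes); n_regions <- as.integer(n_regions)
  if (is.na(n_genes) || n_genes < 1)
    stop("invalid `n_genes`: must be a positive integer", call. = FALSE)
  if (is.na(n_regions) || n_regions < 6)
    stop("invalid `n_regions`: need >= 6 regions for the high-expression rule to be attainable",
         call. = FALSE)
  total_prog <- 0L
  for (i in seq_along(programs)) {
    p <- programs[[i]]
    if (is.null(p$regions) || !length(p$regions))
      stop(sprintf("invalid `programs[[%d]]$regions`: empty", i), call. = FALSE)
    if (is.numeric(p$regions) && any(p$regions < 1 | p$regions > n_regions))
      stop(sprintf("invalid `programs[[%d]]$regions`: out of range", i),
           call. = FALSE)
    if (is.null(p$n_genes) || p$n_genes < 1)
      stop(sprintf("invalid `programs[[%d]]$n_genes`", i), call. = FALSE)
    if (is.null(p$multiplier) || p$multiplier <= 1)
      stop(sprintf("invalid `programs[[%d]]$multiplier`: must be > 1", i),
           call. = FALSE)
    total_prog <- total_prog + as.integer(p$n_genes)
  }
  if (total_prog > n_genes)
    stop("invalid `programs`: total program genes exceed `n_genes`",
         call. = FALSE)
  if (diff(meanlog_range) < 0 || diff(sdlog_range) < 0 || sdlog_range[1] < 0)
    stop("invalid baseline parameter range", call. = FALSE)
  structure(list(n_genes = n_genes, n_regions = n_regions,
                 programs = programs, meanlog_range = meanlog_range,
                 sdlog_range = sdlog_range, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic atlas with planted programs
#'
#' Draws the atlas described by a [synthetic_spec()]: each gene's regional
#' values are i.i.d. log-normal with that gene's baseline parameters;
#' program genes then have their target-region values multiplied by the
#' program's effect multiplier (multiplicative, so the flagging rule's
#' scale invariance is exercised). Deterministic under the spec seed.
#'
#' @param spec A `SyntheticSpec`.
#' @return List with `atlas` (an `ExpressionAtlas`, genes `g0001`...,
#'   regions `R01`...) and `truth` (a `SyntheticTruth`: per-program member
#'   genes and target regions, plus a per-gene program id, 0 = background).
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  G <- spec$n_genes; R <- spec$n_regions
  genes <- sprintf("g%04d", seq_len(G))
  regions <- sprintf("R%02d", seq_len(R))
  meanlog <- runif(G, spec$meanlog_range[1], spec$meanlog_range[2])
  sdlog <- runif(G, spec$sdlog_range[1], spec$sdlog_range[2])
  vals <- matrix(exp(rnorm(G * R, mean = meanlog, sd = sdlog)), G, R,
                 dimnames = list(genes, regions))
  gene_program <- integer(G)
  prog_truth <- vector("list", length(spec$programs))
  pool <- seq_len(G)
  for (i in seq_along(spec$programs)) {
    p <- spec$programs[[i]]
    members <- sample(pool, p$n_genes)
    pool <- setdiff(pool, members)
    target <- if (is.character(p$regions)) match(p$regions, regions)
              else as.integer(p$regions)
    vals[members, target] <- vals[members, target] * p$multiplier
    gene_program[members] <- i
    prog_truth[[i]] <- list(members = genes[sort(members)],
                            regions = regions[target],
                            multiplier = p$multiplier)
  }
  truth <- structure(list(programs = prog_truth,
                          gene_program = setNames(gene_program, genes)),
                     class = "SyntheticTruth")
  list(atlas = expression_atlas(vals), truth = truth)
}

#' Draw a gene list from synthetic truth
#'
#' Stands in for a curated disease gene list: a uniform draw of `n_signal`
#' program genes (from `program`, or from all programs) mixed with
#' `n_background` background genes, shuffled.
#'
#' @param truth A `SyntheticTruth` from [generate_atlas()].
#' @param n_signal Number of program genes to include.
#' @param n_background Number of background genes to include.
#' @param seed Integer seed.
#' @param program Program index to draw signal genes from (default: any).
#' @return A `GeneList` with a `signal_genes` attribute naming the planted
#'   members included.
#' @export
generate_gene_list <- function(truth, n_signal, n_background, seed = 1L,
                               program = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  gp <- truth$gene_program
  signal_pool <- if (is.null(program)) names(gp)[gp > 0]
                 else names(gp)[gp == program]
  background_pool <- names(gp)[gp == 0]
  if (n_signal > length(signal_pool))
    stop(sprintf("requested %d signal genes but only %d available",
                 n_signal, length(signal_pool)), call. = FALSE)
  if (n_background > length(background_pool))
    stop(sprintf("requested %d background genes but only %d available",
                 n_background, length(background_pool)), call. = FALSE)
  if (n_signal + n_background < 1)
    stop("requested list is empty", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  sig <- if (n_signal > 0) sample(signal_pool, n_signal) else character(0)
  bg <- if (n_background > 0) sample(background_pool, n_background)
        else character(0)
  out <- sample(c(sig, bg))
  gl <- gene_list(out, provenance = "synthetic")
  attr(gl, "signal_genes") <- sig
  gl
}

#' Positive-control synthetic preset
#'
#' Reproduces the shape of a positive-control validation: three disjoint
#' programs, each targeting its own distinct region (mimicking e.g.
#' cerebellum-, thalamus- and hypothalamus-specific lists), so that feeding
#' each program's member list through the pipeline should flag only that
#' program's region.
#'
#' @param seed Integer seed.
#' @param n_genes,n_regions Atlas size.
#' @return As [generate_atlas()].
#' @export
positive_control_atlas <- function(seed = 1L, n_genes = 2000L,
                                   n_regions = 50L) {
  spec <- synthetic_spec(
    n_genes = n_genes, n_regions = n_regions,
    programs = list(list(regions = 1L, n_genes = 40L, multiplier = 50),
                    list(regions = 2L, n_genes = 40L, multiplier = 50),
                    list(regions = 3L, n_genes = 40L, multiplier = 50)),
    seed = seed)
  generate_atlas(spec)
}
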
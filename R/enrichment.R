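#' Observed per-region counts for a gene list
#'
#' For each region, how many resolved list genes carry that region in their
#' highest-expression set, and which genes those are.
#'
#' @param index A `HighExpressionIndex`.
#' @param resolved Gene symbols, all present in the index (use
#'   [resolve_genes()] first).
#' @return List with `counts` (named integer vector over all regions) and
#'   `contributing` (named list of gene ids per region).
#' @export
observed_counts <- function(index, resolved) {
  stopifnot(inherits(index, "HighExpressionIndex"))
  resolved <- as.character(resolved)
  bad <- setdiff(resolved, index$genes)
  if (length(bad))
    stop("gene(s) not in the index universe: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  sub <- index$membership[match(resolved, index$genes), , drop = FALSE]
  counts <- as.integer(colSums(sub))
  names(counts) <- index$regions
  contributing <- apply(sub, 2L, function(col) resolved[col], simplify = FALSE)
  list(counts = counts, contributing = contributing)
}

#' Monte-Carlo reference count distribution
#'
#' The enrichment null: each iteration draws `X` distinct genes uniformly
#' without replacement from the whole index universe (including genes whose
#' highest-expression set is empty) and tallies per-region counts. The
#' empirical mean and SD over iterations parameterise the null for a gene
#' list of length `X`. Because the draw is a uniform subset, the exact
#' marginal law of each region's count is hypergeometric; see
#' [analytic_reference()].
#'
#' @param index A `HighExpressionIndex`.
#' @param X List length (1 <= X <= universe size).
#' @param iterations Number of resampling iterations (default 1e6; tests and
#'   quick runs use 1e4-1e5).
#' @param seed Integer seed; fixed seed gives bit-identical output. The
#'   caller's RNG state is preserved.
#' @param include_empty_genes Keep genes with empty highest-expression sets
#'   in the sampling universe (default TRUE).
#' @param keep_histogram Retain the full iterations x regions count matrix
#'   (enables exact empirical p-values; memory is
#'   `iterations * n_regions` integers, e.g. ~770 MB at 1e6 x 193, so the
#'   default is FALSE).
#' @return A `ReferenceDistribution`: list with per-region `ref_mean`,
#'   `ref_sd`, `ref_max`, metadata (`X`, `iterations`, `seed`,
#'   `universe_size`, `method = "simulated"`) and optionally `histogram`.
#' @export
simulate_reference <- function(index, X, iterations = 1e6L, seed = 1L,
                               include_empty_genes = TRUE,
                               keep_histogram = FALSE) {
  stopifnot(inherits(index, "HighExpressionIndex"))
  M <- universe_membership(index, include_empty_genes)
  G <- nrow(M)
  X <- as.integer(X)
  iterations <- as.integer(iterations)
  if (is.na(X) || X < 1L) stop("X must be a positive integer", call. = FALSE)
  if (X > G) stop(sprintf("X (%d) exceeds universe size (%d)", X, G),
                  call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)

  mode(M) <- "double"
  R <- ncol(M)
  s1 <- numeric(R); s2 <- numeric(R); mx <- numeric(R)
  hist <- if (keep_histogram)
    matrix(NA_integer_, iterations, R, dimnames = list(NULL, colnames(M)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  chunk <- 1000L
  done <- 0L
  while (done < iterations) {
    k <- min(chunk, iterations - done)
    for (i in seq_len(k)) {
      idx <- sample.int(G, X)
      cnt <- colSums(M[idx, , drop = FALSE])
      s1 <- s1 + cnt
      s2 <- s2 + cnt * cnt
      mx <- pmax(mx, cnt)
      if (keep_histogram) hist[done + i, ] <- as.integer(cnt)
    }
    done <- done + k
  }
  ref_mean <- s1 / iterations
  varhat <- if (iterations > 1L)
    pmax(0, (s2 - iterations * ref_mean^2) / (iterations - 1)) else
    rep(0, R)
  structure(list(regions = colnames(M),
                 ref_mean = setNames(ref_mean, colnames(M)),
                 ref_sd = setNames(sqrt(varhat), colnames(M)),
                 ref_max = setNames(mx, colnames(M)),
                 X = X, iterations = iterations, seed = as.integer(seed),
                 universe_size = G, method = "simulated",
                 histogram = hist),
            class = "ReferenceDistribution")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

universe_membership <- function(index, include_empty_genes) {
  M <- index$membership
  if (!include_empty_genes) {
    keep <- rowSums(M) > 0
    if (!any(keep)) stop("universe is empty after excluding empty-set genes",
                         call. = FALSE)
    M <- M[keep, , drop = FALSE]
  }
  M
}

#' Exact hypergeometric reference distribution
#'
#' Closed-form counterpart of [simulate_reference()]: for a uniform draw of
#' `X` genes from a universe of `G`, the count for a region carried by `m`
#' universe genes is Hypergeometric(G, m, X) with mean `X m / G` and SD
#' `sqrt(X (m/G)(1 - m/G)(G - X)/(G - 1))`. Used as the independent oracle
#' for the Monte-Carlo null and available as a fast drop-in reference.
#'
#' @inheritParams simulate_reference
#' @return A `ReferenceDistribution` with `method = "analytic"`.
#' @export
analytic_reference <- function(index, X, include_empty_genes = TRUE) {
  stopifnot(inherits(index, "HighExpressionIndex"))
  M <- universe_membership(index, include_empty_genes)
  G <- nrow(M)
  X <- as.integer(X)
  if (is.na(X) || X < 1L) stop("X must be a positive integer", call. = FALSE)
  if (X > G) stop(sprintf("X (%d) exceeds universe size (%d)", X, G),
                  call. = FALSE)
  m <- colSums(M)
  p <- m / G
  mu <- X * p
  v <- if (G > 1) X * p * (1 - p) * (G - X) / (G - 1) else rep(0, ncol(M))
  structure(list(regions = colnames(M),
                 ref_mean = setNames(mu, colnames(M)),
                 ref_sd = setNames(sqrt(v), colnames(M)),
                 ref_max = setNames(pmin(m, X), colnames(M)),
                 X = X, iterations = NA_integer_, seed = NA_integer_,
                 universe_size = G, method = "analytic", histogram = NULL),
            class = "ReferenceDistribution")
}

#' @export
print.ReferenceDistribution <- function(x, ...) {
  cat(sprintf(
    "ReferenceDistribution (%s): %d regions, X = %d, universe = %d%s\n",
    x$method, length(x$regions), x$X, x$universe_size,
    if (x$method == "simulated")
      sprintf(", iterations = %d, seed = %d", x$iterations, x$seed) else ""))
  invisible(x)
}

#' Score regions against the reference distribution
#'
#' Per region: `z = (observed - ref_mean)/ref_sd`, one-sided upper-tail
#' normal p, Bonferroni-corrected significance, and fold-enrichment
#' (`observed / ref_mean`). Under the default one-sided Bonferroni rule at
#' `alpha = 0.05` over 193 tests the implied critical z is ~3.47. Regions
#' with a degenerate null (`ref_sd = 0`) get `z = NA` and are significant
#' only when the observed count exceeds the null maximum.
#'
#' @param observed Result of [observed_counts()] (or a named integer vector
#'   of per-region counts).
#' @param reference A `ReferenceDistribution` covering every observed region.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of comparisons for the correction; defaults to the
#'   number of regions scored.
#' @param correction `"bonferroni"` (significant iff p < alpha / n_tests) or
#'   `"none"` (p < alpha).
#' @param tail `"one"` (default; upper tail) or `"two"` (p doubled before
#'   thresholding, enrichment direction still required).
#' @param p_source `"normal"` (default) decides significance on the normal
#'   tail of the simulated-null z; `"empirical"` uses the exact resampling
#'   p-value `(1 + exceedances) / (iterations + 1)` and requires a
#'   reference built with `keep_histogram = TRUE`. The normal tail is a
#'   good approximation near the centre but is anticonservative in the far
#'   upper tail of the skewed discrete null; prefer `"empirical"` when
#'   strict family-wise error control matters and memory allows.
#' @return An `EnrichmentTable` (data.table) with columns `region`,
#'   `observed`, `ref_mean`, `ref_sd`, `z`, `z_squared`, `p`, `p_empirical`
#'   (NA unless the reference kept its histogram), `significant`,
#'   `fold_enrichment` (NA when `ref_mean = 0`) and `contributing_genes`
#'   (list column; empty when plain counts were supplied). Attributes record
#'   the decision rule.
#' @export
score_regions <- function(observed, reference, alpha = 0.05, n_tests = NULL,
                          correction = c("bonferroni", "none"),
                          tail = c("one", "two"),
                          p_source = c("normal", "empirical")) {
  stopifnot(inherits(reference, "ReferenceDistribution"))
  correction <- match.arg(correction)
  tail <- match.arg(tail)
  p_source <- match.arg(p_source)
  if (p_source == "empirical" && is.null(reference$histogram))
    stop("p_source = \"empirical\" needs a reference built with keep_histogram = TRUE",
         call. = FALSE)
  if (is.list(observed) && !is.null(observed$counts)) {
    counts <- observed$counts
    contributing <- observed$contributing
  } else {
    counts <- observed
    contributing <- NULL
  }
  if (is.null(names(counts)))
    stop("observed counts must be named by region", call. = FALSE)
  miss <- setdiff(names(counts), reference$regions)
  if (length(miss))
    stop("reference does not cover region(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  regions <- names(counts)
  mu <- reference$ref_mean[regions]
  sdv <- reference$ref_sd[regions]
  mxv <- reference$ref_max[regions]
  if (is.null(n_tests)) n_tests <- length(regions)
  level <- if (correction == "bonferroni") alpha / n_tests else alpha

  z <- ifelse(sdv > 0, (counts - mu) / sdv, NA_real_)
  p <- pnorm(z, lower.tail = FALSE)
  p_emp <- rep(NA_real_, length(regions))
  if (!is.null(reference$histogram)) {
    H <- reference$histogram[, regions, drop = FALSE]
    p_emp <- (1 + colSums(H >= rep(counts, each = nrow(H)))) /
      (nrow(H) + 1)
  }
  p_decide <- if (p_source == "empirical") p_emp else p
  p_adj_side <- if (tail == "two") pmin(1, 2 * p_decide) else p_decide
  significant <- ifelse(sdv > 0,
                        p_adj_side < level & counts > mu,
                        counts > mxv)
  if (p_source == "empirical")
    significant <- p_adj_side < level & counts > mu
  fold <- ifelse(mu > 0, counts / mu, NA_real_)
  out <- data.table(region = regions,
                    observed = as.integer(counts),
                    ref_mean = as.numeric(mu), ref_sd = as.numeric(sdv),
                    z = as.numeric(z), z_squared = as.numeric(z)^2,
                    p = as.numeric(p), p_empirical = p_emp,
                    significant = as.logical(significant),
                    fold_enrichment = as.numeric(fold))
  out$contributing_genes <- if (!is.null(contributing))
    unname(contributing[regions]) else rep(list(character(0)), length(regions))
  setattr(out, "class", c("EnrichmentTable", class(out)))
  setattr(out, "alpha", alpha)
  setattr(out, "n_tests", n_tests)
  setattr(out, "correction", correction)
  setattr(out, "tail", tail)
  setattr(out, "p_source", p_source)
  setattr(out, "per_test_level", level)
  out
}

#' Significant regions of an enrichment table
#' @param table An `EnrichmentTable`.
#' @return Character vector of region ids flagged significant.
#' @export
significant_regions <- function(table) {
  stopifnot(inherits(table, "EnrichmentTable"))
  table$region[table$significant]
}

#' Write reference / enrichment tables as TSV
#'
#' `write_reference` emits region, ref_mean, ref_sd plus the reproducibility
#' metadata (X, iterations, seed, universe size) on every row;
#' `write_enrichment` emits the scored table with contributing genes
#' semicolon-joined.
#'
#' @param reference A `ReferenceDistribution`.
#' @param table An `EnrichmentTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "ReferenceDistribution"))
  dt <- data.table(region = reference$regions,
                   ref_mean = as.numeric(reference$ref_mean),
                   ref_sd = as.numeric(reference$ref_sd),
                   X = reference$X, iterations = reference$iterations,
                   seed = reference$seed,
                   universe_size = reference$universe_size,
                   method = reference$method)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_reference
#' @export
write_enrichment <- function(table, path) {
  stopifnot(inherits(table, "EnrichmentTable"))
  dt <- as.data.table(table)
  dt$contributing_genes <- vapply(table$contributing_genes, paste,
                                  collapse = ";", "")
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
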
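#' Per-gene mean and SD of expression across regions
#'
#' For each gene, the mean and standard deviation of its nTPM values across
#' all regions of the atlas. These are the parameters of the per-gene
#' "highest expression" rule: a region is flagged when its value strictly
#' exceeds `mean + z_high * sd`.
#'
#' @param atlas An `ExpressionAtlas` with at least two regions.
#' @param sd_method `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @return data.table with columns `gene`, `mean`, `sd` in atlas gene order.
#' @export
gene_region_stats <- function(atlas, sd_method = c("sample", "population")) {
  stopifnot(inherits(atlas, "ExpressionAtlas"))
  sd_method <- match.arg(sd_method)
  v <- atlas$values
  n <- ncol(v)
  if (n < 2)
    stop("atlas must have >= 2 regions (SD undefined for a single region)",
         call. = FALSE)
  mu <- rowMeans(v)
  ss <- rowSums((v - mu)^2)
  denom <- if (sd_method == "sample") n - 1L else n
  data.table(gene = rownames(v), mean = mu, sd = sqrt(ss / denom))
}

#' Per-gene highest-expression region sets
#'
#' For every gene, the set of regions whose expression strictly exceeds
#' `mean + z_high * sd` of that gene across all regions. A gene with
#' constant expression (sd = 0) gets an empty set but stays in the index:
#' the index is the sampling universe for the enrichment null. Note that
#' with the sample (n-1) SD convention the maximum attainable z over n
#' regions is (n-1)/sqrt(n), so atlases with <= 5 regions can never flag
#' any region at the default threshold of 1.96.
#'
#' @param atlas An `ExpressionAtlas`.
#' @param z_high Positive threshold multiplier (default 1.96).
#' @inheritParams gene_region_stats
#' @return A `HighExpressionIndex`: list with `genes`, `regions`, `stats`
#'   (the [gene_region_stats()] table), a logical `membership` matrix
#'   (genes x regions, TRUE = flagged), `sets` (named list of flagged
#'   region ids per gene) and the `z_high` / `sd_method` used.
#' @export
high_expression_sets <- function(atlas, z_high = 1.96,
                                 sd_method = c("sample", "population")) {
  stopifnot(inherits(atlas, "ExpressionAtlas"))
  sd_method <- match.arg(sd_method)
  if (!is.numeric(z_high) || length(z_high) != 1 || z_high <= 0)
    stop("`z_high` must be a positive scalar", call. = FALSE)
  stats <- gene_region_stats(atlas, sd_method)
  cutoff <- stats$mean + z_high * stats$sd
  membership <- atlas$values > cutoff          # recycles cutoff per row
  membership[stats$sd == 0, ] <- FALSE
  regions <- atlas_regions(atlas)
  sets <- apply(membership, 1L, function(r) regions[r], simplify = FALSE)
  structure(list(genes = atlas_genes(atlas), regions = regions,
                 stats = stats, membership = membership, sets = sets,
                 z_high = z_high, sd_method = sd_method),
            class = "HighExpressionIndex")
}

#' @export
print.HighExpressionIndex <- function(x, ...) {
  cat(sprintf(
    "HighExpressionIndex: %d genes x %d regions (z > %.3g, %s SD); %d genes with >= 1 flagged region\n",
    length(x$genes), length(x$regions), x$z_high, x$sd_method,
    sum(rowSums(x$membership) > 0)))
  invisible(x)
}

#' Write a high-expression index as TSV
#'
#' Columns: gene, mean, sd, n_flagged, flagged_regions (semicolon-joined).
#'
#' @param index A `HighExpressionIndex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_high_expression <- function(index, path) {
  stopifnot(inherits(index, "HighExpressionIndex"))
  dt <- copy_stats(index)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

copy_stats <- function(index) {
  dt <- data.table(gene = index$stats$gene, mean = index$stats$mean,
                   sd = index$stats$sd,
                   n_flagged = rowSums(index$membership),
                   flagged_regions = vapply(index$sets, paste,
                                            collapse = ";", ""))
  dt
}
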
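#' @importFrom data.table fread fwrite data.table as.data.table setattr
#' @importFrom stats pnorm qnorm rnorm runif sd setNames
#' @importFrom utils head
NULL

#' Construct an expression atlas
#'
#' An `ExpressionAtlas` is a dense gene x region matrix of non-negative
#' expression values (nTPM). Genes are rows, regions are columns; both are
#' unique, non-empty character identifiers and every cell is populated.
#'
#' @param values Numeric matrix with genes as rownames and regions as
#'   colnames. All values must be finite and non-negative.
#' @return An object of class `ExpressionAtlas`.
#' @export
expression_atlas <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  regions <- colnames(values)
  if (is.null(genes) || is.null(regions))
    stop("`values` must have gene rownames and region colnames", call. = FALSE)
  if (any(!nzchar(genes)) || any(!nzchar(regions)))
    stop("gene and region identifiers must be non-empty strings", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(head(unique(genes[duplicated(genes)]), 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(regions))
    stop("duplicate region identifiers: ",
         paste(head(unique(regions[duplicated(regions)]), 5), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("atlas values must all be finite (no missing cells)", call. = FALSE)
  if (any(values < 0))
    stop("atlas values must be non-negative", call. = FALSE)
  structure(list(values = values), class = "ExpressionAtlas")
}

#' @export
print.ExpressionAtlas <- function(x, ...) {
  cat(sprintf("ExpressionAtlas: %d genes x %d regions\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionAtlas <- function(x) dim(x$values)

#' Gene and region identifiers of an atlas
#' @param atlas An `ExpressionAtlas`.
#' @return Character vector of identifiers in atlas order.
#' @export
atlas_genes <- function(atlas) rownames(atlas$values)

#' @rdname atlas_genes
#' @export
atlas_regions <- function(atlas) colnames(atlas$values)

#' Read an expression atlas from TSV
#'
#' Two dialects are supported. `"wide"` is a plain matrix: genes as rows
#' (first column holds the gene identifier), regions as columns, header row
#' of region names. `"hpa_long"` is the Human Protein Atlas brain-region
#' export: tab-separated with columns `Gene` (Ensembl id, ignored),
#' `Gene name`, `Brain region` and `nTPM`, one row per (gene, region) pair.
#' Gene identity is the symbol (`Gene name`) after whitespace stripping;
#' no alias or cross-identifier mapping is attempted.
#'
#' In the long dialect every gene must cover every region: under
#' `incomplete = "error"` (default) a gene with missing regions aborts the
#' load; under `"drop"` such genes are removed with a warning. Values are
#' never imputed.
#'
#' @param path Path to a TSV file.
#' @param dialect `"wide"` or `"hpa_long"`.
#' @param incomplete How to treat genes lacking some regions in long format:
#'   `"error"` or `"drop"`.
#' @return An [expression_atlas()] object. Gene and region order follow first
#'   appearance in the file.
#' @export
read_atlas <- function(path, dialect = c("wide", "hpa_long"),
                       incomplete = c("error", "drop")) {
  dialect <- match.arg(dialect)
  incomplete <- match.arg(incomplete)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "wide") read_atlas_wide(path) else
    read_atlas_hpa_long(path, incomplete)
}

read_atlas_wide <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1))
  if (ncol(dt) < 2)
    stop("wide atlas needs a gene column plus at least one region column",
         call. = FALSE)
  genes <- trimws(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(apply(dt[, -1, drop = FALSE], 2, function(x) !is.numeric(x)))
    stop("non-numeric nTPM values in column(s): ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  storage.mode(vals) <- "double"
  neg <- which(vals < 0, arr.ind = TRUE)
  if (length(neg))
    stop(sprintf("negative nTPM at data row %d, column %s",
                 neg[1, 1], colnames(vals)[neg[1, 2]]), call. = FALSE)
  rownames(vals) <- genes
  expression_atlas(vals)
}

read_atlas_hpa_long <- function(path, incomplete) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("Gene name", "Brain region", "nTPM")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("long atlas is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  gene <- trimws(as.character(dt[["Gene name"]]))
  region <- trimws(as.character(dt[["Brain region"]]))
  ntpm <- dt[["nTPM"]]
  if (!is.numeric(ntpm)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ntpm))))[1]
    stop(sprintf("non-numeric nTPM at data row %d", bad), call. = FALSE)
  }
  bad <- which(!is.finite(ntpm) | ntpm < 0)
  if (length(bad))
    stop(sprintf("negative or non-finite nTPM at data row %d", bad[1]),
         call. = FALSE)
  key <- paste(gene, region, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate (gene, region) pair at data row %d: %s / %s",
                 d, gene[d], region[d]), call. = FALSE)
  }
  genes <- unique(gene)
  regions <- unique(region)
  cover <- table(factor(gene, levels = genes))
  incomplete_genes <- names(cover)[cover < length(regions)]
  if (length(incomplete_genes)) {
    if (incomplete == "error")
      stop("gene(s) with incomplete region coverage: ",
           paste(head(incomplete_genes, 5), collapse = ", "),
           " (use incomplete = \"drop\" to discard them)", call. = FALSE)
    warning(sprintf("dropping %d gene(s) with incomplete region coverage",
                    length(incomplete_genes)), call. = FALSE)
    keep <- !(gene %in% incomplete_genes)
    gene <- gene[keep]; region <- region[keep]; ntpm <- ntpm[keep]
    genes <- setdiff(genes, incomplete_genes)
  }
  vals <- matrix(NA_real_, length(genes), length(regions),
                 dimnames = list(genes, regions))
  vals[cbind(match(gene, genes), match(region, regions))] <- ntpm
  if (anyNA(vals))
    stop("gene(s) with incomplete region coverage after filtering",
         call. = FALSE)
  expression_atlas(vals)
}

#' Write an atlas as a wide TSV
#'
#' Round-trips bit-exactly with `read_atlas(dialect = "wide")`.
#'
#' @param atlas An `ExpressionAtlas`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "ExpressionAtlas"))
  # shortest decimal representation that re-reads to the identical double,
  # so the wide dialect round-trips bit-exactly
  chr <- matrix(fmt_full(atlas$values), nrow(atlas$values),
                dimnames = dimnames(atlas$values))
  dt <- data.table(gene = atlas_genes(atlas))
  dt <- cbind(dt, as.data.table(chr))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

fmt_full <- function(x) {
  s <- sprintf("%.15g", x)
  redo <- as.numeric(s) != x
  if (any(redo)) s[redo] <- sprintf("%.17g", x[redo])
  s
}

#' Read a gene list from plain text
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored;
#' surrounding whitespace is stripped; case is preserved. Duplicates are
#' collapsed with a warning.
#'
#' @param path Path to the list file.
#' @param provenance Free-text label recorded on the result (defaults to the
#'   file name).
#' @return A `GeneList`: character vector of symbols in file order, with a
#'   `provenance` attribute.
#' @export
read_gene_list <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("gene list is empty after removing blanks and comments: ", path,
         call. = FALSE)
  if (anyDuplicated(lines)) {
    warning(sprintf("%d duplicate symbol(s) collapsed in %s",
                    sum(duplicated(lines)), path), call. = FALSE)
    lines <- unique(lines)
  }
  gene_list(lines, provenance)
}

#' @rdname read_gene_list
#' @param symbols Character vector of gene symbols.
#' @export
gene_list <- function(symbols, provenance = "user") {
  symbols <- trimws(as.character(symbols))
  if (!length(symbols) || any(!nzchar(symbols)))
    stop("gene list symbols must be non-empty strings", call. = FALSE)
  if (anyDuplicated(symbols)) symbols <- unique(symbols)
  structure(symbols, provenance = provenance, class = "GeneList")
}

#' @export
print.GeneList <- function(x, ...) {
  cat(sprintf("GeneList '%s': %d symbols\n", attr(x, "provenance"), length(x)))
  invisible(x)
}

#' Resolve a gene list against an atlas
#'
#' Exact string match of symbols against atlas gene identifiers. The number
#' of resolved symbols is the list length `X` used to size the resampling
#' null downstream.
#'
#' @param atlas An `ExpressionAtlas` (or a `HighExpressionIndex`).
#' @param list A `GeneList` or character vector.
#' @return List with `resolved` and `missing` `GeneList`s
#'   (`resolved` + `missing` partition the input).
#' @export
resolve_genes <- function(atlas, list) {
  universe <- if (inherits(atlas, "ExpressionAtlas")) atlas_genes(atlas)
              else if (inherits(atlas, "HighExpressionIndex")) atlas$genes
              else stop("`atlas` must be an ExpressionAtlas or HighExpressionIndex",
                        call. = FALSE)
  prov <- if (inherits(list, "GeneList")) attr(list, "provenance") else "user"
  symbols <- unique(trimws(as.character(list)))
  hit <- symbols %in% universe
  if (!any(hit))
    stop("no gene-list symbol matches the atlas; check identifiers",
         call. = FALSE)
  message(sprintf("resolved %d/%d gene-list symbols against the atlas",
                  sum(hit), length(symbols)))
  list(resolved = gene_list(symbols[hit], prov),
       missing = if (any(!hit)) symbols[!hit] else character(0))
}
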
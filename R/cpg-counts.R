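#' Per-CpG, per-library methylation count matrix
#'
#' Container for whole-genome bisulfite sequencing counts: for every CpG site
#' and sequencing library it stores the number of methylated reads and the
#' total number of reads. A total of zero means "no coverage" for that
#' site/library cell, which is distinct from an observed methylation
#' proportion of zero.
#'
#' @param sites data.frame with columns `contig` (character), `pos`
#'   (1-based integer position) and optionally `site_id`. When `site_id` is
#'   absent it is derived as `"<contig>:<pos>"`.
#' @param meth integer matrix of methylated read counts, sites x libraries.
#' @param total integer matrix of total read counts, same dimensions.
#' @param library_ids character vector of library identifiers, one per
#'   column; defaults to `colnames(meth)`.
#'
#' @return An object of class `cpg_counts` with elements `sites` (data.frame
#'   ordered as the matrix rows), `meth` and `total` (matrices with site ids
#'   as rownames and library ids as colnames).
#' @export
cpg_counts <- function(sites, meth, total, library_ids = colnames(meth)) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (!identical(dim(meth), dim(total))) {
    stop("'meth' and 'total' must have identical dimensions")
  }
  if (is.null(library_ids)) {
    stop("library ids are required (as 'library_ids' or colnames)")
  }
  library_ids <- as.character(library_ids)
  if (anyDuplicated(library_ids)) stop("library ids must be unique")
  if (length(library_ids) != ncol(meth)) {
    stop("length of 'library_ids' must equal the number of columns")
  }
  sites <- as.data.frame(sites)
  if (!all(c("contig", "pos") %in% names(sites))) {
    stop("'sites' needs columns 'contig' and 'pos'")
  }
  if (nrow(sites) != nrow(meth)) {
    stop("'sites' must have one row per matrix row")
  }
  if (is.null(sites$site_id)) {
    sites$site_id <- if (nrow(sites)) paste0(sites$contig, ":", sites$pos)
      else character(0)
  }
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop("site ids must be unique")
  storage.mode(meth) <- "double"
  storage.mode(total) <- "double"
  if (any(!is.finite(meth)) || any(!is.finite(total))) {
    stop("counts must be finite")
  }
  if (any(meth < 0) || any(total < 0) || any(meth > total)) {
    stop("counts must satisfy 0 <= methylated <= total")
  }
  dimnames(meth) <- dimnames(total) <- list(sites$site_id, library_ids)
  structure(
    list(sites = sites[, c("contig", "pos", "site_id")], meth = meth,
         total = total),
    class = "cpg_counts"
  )
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat(sprintf(
    "cpg_counts: %d sites x %d libraries (%d contigs)\n",
    nrow(x$meth), ncol(x$meth), length(unique(x$sites$contig))
  ))
  cat(sprintf("  mean coverage: %.1f reads; cells with no coverage: %d\n",
              mean(x$total), sum(x$total == 0)))
  invisible(x)
}

#' @export
dim.cpg_counts <- function(x) dim(x$meth)

#' Library identifiers of a count matrix
#' @param x a `cpg_counts` object.
#' @return Character vector of library ids.
#' @export
library_ids <- function(x) colnames(x$meth)

#' Subset a count matrix by site and/or library
#'
#' @param x a `cpg_counts` object.
#' @param sites site ids (character) or row indices to keep.
#' @param libraries library ids (character) or column indices to keep.
#' @return A `cpg_counts` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, sites = NULL, libraries = NULL) {
  stopifnot(inherits(x, "cpg_counts"))
  ri <- if (is.null(sites)) seq_len(nrow(x$meth)) else sites
  ci <- if (is.null(libraries)) seq_len(ncol(x$meth)) else libraries
  if (is.character(ri)) {
    ri <- match(ri, x$sites$site_id)
    if (anyNA(ri)) stop("unknown site id(s) in subset")
  }
  if (is.character(ci)) {
    ci <- match(ci, colnames(x$meth))
    if (anyNA(ci)) stop("unknown library id(s) in subset")
  }
  cpg_counts(x$sites[ri, , drop = FALSE],
             x$meth[ri, ci, drop = FALSE],
             x$total[ri, ci, drop = FALSE])
}

#' Methylation proportions from counts
#'
#' @param x a `cpg_counts` object.
#' @return Numeric matrix of methylated/total, with `NA` where a cell has no
#'   coverage (total = 0).
#' @export
methylation_proportions <- function(x) {
  stopifnot(inherits(x, "cpg_counts"))
  p <- x$meth / x$total
  p[x$total == 0] <- NA_real_
  p
}

## internal: validate a sample sheet against a count matrix
check_sample_sheet <- function(samples, counts = NULL) {
  samples <- as.data.frame(samples)
  need <- c("library_id", "treatment", "age_days")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  samples$library_id <- as.character(samples$library_id)
  if (anyDuplicated(samples$library_id)) {
    stop("sample sheet: duplicated library ids")
  }
  if (any(!is.finite(samples$age_days)) || any(samples$age_days <= 0)) {
    stop("sample sheet: ages must be positive and finite")
  }
  if (length(unique(samples$treatment)) != 2) {
    stop("sample sheet: exactly two treatment labels are required")
  }
  if (!is.null(counts)) {
    miss <- setdiff(library_ids(counts), samples$library_id)
    if (length(miss)) {
      stop("libraries absent from the sample sheet: ",
           paste(miss, collapse = ", "))
    }
  }
  samples
}
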
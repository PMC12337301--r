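#' Estimate the bisulfite non-conversion error rate from spike-in counts
#'
#' Unmethylated spike-in DNA (typically lambda phage) should read as fully
#' unmethylated after bisulfite conversion; any apparently methylated reads
#' measure the non-conversion error. The pooled estimate is the ratio of
#' methylated to total reads over all spike-in sites and libraries;
#' per-library rates are reported for QC.
#'
#' @param spikein a [cpg_counts()] matrix of spike-in sites.
#' @return A `conversion_estimate` list: `error_rate` (pooled), `total_reads`,
#'   `methylated_reads`, and `per_library` data.frame.
#' @export
estimate_conversion_error <- function(spikein) {
  stopifnot(inherits(spikein, "cpg_counts"))
  if (nrow(spikein$meth) == 0 || sum(spikein$total) == 0) {
    fail("no spike-in coverage: cannot estimate conversion error")
  }
  tot <- colSums(spikein$total)
  met <- colSums(spikein$meth)
  structure(
    list(error_rate = sum(met) / sum(tot),
         total_reads = sum(tot),
         methylated_reads = sum(met),
         per_library = data.frame(
           library_id = library_ids(spikein),
           total_reads = unname(tot), methylated_reads = unname(met),
           error_rate = unname(ifelse(tot > 0, met / tot, NA_real_))
         )),
    class = "conversion_estimate"
  )
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf(
    "bisulfite non-conversion: %.4f%% (%d of %d spike-in reads methylated)\n",
    100 * x$error_rate, x$methylated_reads, x$total_reads))
  invisible(x)
}

## one-sided binomial tail P(X >= k | n, p); exact, vectorized
binom_tail_upper <- function(k, n, p) {
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Classify CpG sites as methylated against the conversion-error background
#'
#' Tests, per site, the null hypothesis that all methylated reads arise from
#' bisulfite non-conversion: a one-sided binomial test of methylated count
#' against the spike-in error rate. In the default `"pooled"` mode counts
#' are summed across all libraries with coverage >= `min_coverage` before
#' testing (the more powerful choice for pooled libraries); in
#' `"per_library"` mode each qualifying library is tested separately and a
#' site must be significant in at least `min_samples` libraries. P-values
#' are Benjamini-Hochberg corrected across tested sites. Sites with fewer
#' than `min_samples` qualifying libraries are dropped before testing and do
#' not enter the multiple-testing family.
#'
#' @param counts genomic [cpg_counts()] (spike-in removed).
#' @param conversion a [estimate_conversion_error()] result, or a plain
#'   error-rate number in `[0, 1]`.
#' @param min_coverage minimum reads for a library to qualify at a site.
#' @param fdr_q Benjamini-Hochberg false-discovery-rate threshold.
#' @param min_samples minimum qualifying libraries per site; default half
#'   the libraries.
#' @param mode `"pooled"` (default) or `"per_library"`; see Details.
#' @return A `methylated_sites` list: `sites` data.frame (site id, counts,
#'   p, q, `methylated` flag), `site_ids` of the retained set, and the
#'   parameters used.
#' @export
call_methylated_sites <- function(counts, conversion,
                                  min_coverage = 10, fdr_q = 0.05,
                                  min_samples = NULL,
                                  mode = c("pooled", "per_library")) {
  stopifnot(inherits(counts, "cpg_counts"))
  mode <- match.arg(mode)
  err <- if (inherits(conversion, "conversion_estimate")) {
    conversion$error_rate
  } else {
    conversion
  }
  if (!is.numeric(err) || length(err) != 1 || err < 0 || err > 1) {
    fail("conversion error rate must be a single number in [0, 1]")
  }
  if (min_coverage < 1) fail("min_coverage must be >= 1")
  if (fdr_q <= 0 || fdr_q >= 1) fail("fdr_q must lie in (0, 1)")
  n_lib <- ncol(counts$meth)
  if (is.null(min_samples)) min_samples <- ceiling(n_lib / 2)

  if (nrow(counts$meth) == 0) {
    warning("empty count matrix: no sites to classify")
    return(structure(
      list(sites = data.frame(site_id = character(), n_libs = integer(),
                              meth = numeric(), total = numeric(),
                              p = numeric(), q = numeric(),
                              methylated = logical()),
           site_ids = character(), error_rate = err,
           min_coverage = min_coverage, fdr_q = fdr_q,
           min_samples = min_samples, mode = mode),
      class = "methylated_sites"
    ))
  }

  qualifies <- counts$total >= min_coverage
  n_qual <- rowSums(qualifies)
  tested <- n_qual >= min_samples

  met_q <- counts$meth * qualifies
  tot_q <- counts$total * qualifies
  pooled_met <- rowSums(met_q)
  pooled_tot <- rowSums(tot_q)

  p <- rep(NA_real_, nrow(counts$meth))
  if (mode == "pooled") {
    p[tested] <- binom_tail_upper(pooled_met[tested], pooled_tot[tested], err)
    q <- rep(NA_real_, length(p))
    q[tested] <- p.adjust(p[tested], method = "BH")
    methylated <- !is.na(q) & q <= fdr_q
  } else {
    plib <- matrix(NA_real_, nrow(counts$meth), n_lib)
    idx <- which(qualifies, arr.ind = TRUE)
    plib[idx] <- binom_tail_upper(counts$meth[idx], counts$total[idx], err)
    qlib <- apply(plib, 2, function(col) {
      out <- rep(NA_real_, length(col))
      out[!is.na(col)] <- p.adjust(col[!is.na(col)], method = "BH")
      out
    })
    n_sig <- rowSums(!is.na(qlib) & qlib <= fdr_q)
    methylated <- tested & n_sig >= min_samples
    ## site-level summary p: most significant qualifying library (QC only)
    p[tested] <- apply(plib[tested, , drop = FALSE], 1, min, na.rm = TRUE)
    q <- rep(NA_real_, length(p))
    q[tested] <- p.adjust(p[tested], method = "BH")
  }

  sites <- data.frame(
    site_id = counts$sites$site_id,
    contig = counts$sites$contig, pos = counts$sites$pos,
    n_libs = n_qual, meth = pooled_met, total = pooled_tot,
    p = p, q = q, methylated = methylated
  )
  structure(
    list(sites = sites, site_ids = sites$site_id[methylated],
         error_rate = err, min_coverage = min_coverage, fdr_q = fdr_q,
         min_samples = min_samples, mode = mode),
    class = "methylated_sites"
  )
}

#' @export
print.methylated_sites <- function(x, ...) {
  cat(sprintf(
    "methylation calling (%s mode): %d of %d tested sites methylated at q <= %g\n",
    x$mode, length(x$site_ids), sum(!is.na(x$sites$p)), x$fdr_q))
  invisible(x)
}
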
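#' Read Bismark-style coverage files into a count matrix
#'
#' Each coverage file is tab-separated with columns
#' `<contig> <start (1-based)> <end> <methylation %> <count methylated>
#' <count unmethylated>`. The percentage column is ignored: counts are
#' authoritative. The result is the union of sites across libraries,
#' ordered deterministically by (contig, position); a site absent from a
#' library gets total = 0 ("no coverage") there.
#'
#' @param paths character vector of file paths, named by library id. Unnamed
#'   paths take the file's base name (without `.cov`/`.cov.gz`/`.txt`) as
#'   library id.
#' @param sample_sheet data.frame with at least `library_id`, `treatment`,
#'   `age_days`; must cover every library in `paths`.
#' @return A [cpg_counts()] matrix over the union of sites.
#' @export
read_coverage_files <- function(paths, sample_sheet) {
  if (length(paths) == 0) fail("no coverage files given")
  ids <- names(paths)
  if (is.null(ids)) ids <- rep("", length(paths))
  auto <- !nzchar(ids)
  ids[auto] <- sub("\\.(cov|txt)(\\.gz)?$", "", basename(paths[auto]))
  sample_sheet <- check_sample_sheet(sample_sheet)
  unknown <- setdiff(ids, sample_sheet$library_id)
  if (length(unknown)) {
    fail("library not in sample sheet: %s", paste(unknown, collapse = ", "))
  }
  per_lib <- lapply(seq_along(paths), function(i) {
    parse_coverage_file(paths[i], ids[i])
  })
  ## union of sites in deterministic (contig, position) order
  all_sites <- unique(do.call(rbind, lapply(per_lib, function(d) {
    d[, c("contig", "pos")]
  })))
  all_sites <- all_sites[order(all_sites$contig, all_sites$pos), ,
                         drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$contig, all_sites$pos)
  meth <- total <- matrix(0, nrow(all_sites), length(paths))
  for (i in seq_along(per_lib)) {
    d <- per_lib[[i]]
    ri <- match(paste(d$contig, d$pos), key)
    meth[ri, i] <- d$meth
    total[ri, i] <- d$meth + d$unmeth
  }
  cpg_counts(all_sites, meth, total, library_ids = ids)
}

## parse one coverage file, with line-addressed error messages
parse_coverage_file <- function(path, library_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      meth = numeric(), unmeth = numeric()))
  }
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != 6)
  if (length(bad)) {
    fail("%s: malformed coverage line %d (expected 6 fields, got %d)",
         path, bad[1], length(parts[[bad[1]]]))
  }
  m <- do.call(rbind, parts)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 5]))
  unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(!is.finite(pos) | !is.finite(meth) | !is.finite(unmeth) |
                 meth < 0 | unmeth < 0 | pos != round(pos))
  if (length(bad)) {
    fail("%s: malformed coverage line %d (non-numeric or negative field)",
         path, bad[1])
  }
  d <- data.frame(contig = m[, 1], pos = as.integer(pos),
                  meth = meth, unmeth = unmeth)
  dup <- which(duplicated(paste(d$contig, d$pos)))
  if (length(dup)) {
    fail("%s: duplicate site %s:%d at line %d", path,
         d$contig[dup[1]], d$pos[dup[1]], dup[1])
  }
  d
}

#' Write a count matrix as per-library Bismark-style coverage files
#'
#' Writes one `<library_id>.cov` file per library into `dir`, containing
#' only the covered sites (total > 0) of that library. The written
#' methylation percentage is `100 * methylated / total`; a later
#' [read_coverage_files()] of these files reproduces every count exactly.
#'
#' @param counts a [cpg_counts()] matrix.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_coverage_files <- function(counts, dir) {
  stopifnot(inherits(counts, "cpg_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(library_ids(counts), function(lib) {
    keep <- counts$total[, lib] > 0
    d <- data.frame(
      contig = counts$sites$contig[keep],
      start = counts$sites$pos[keep],
      end = counts$sites$pos[keep],
      pct = format(100 * counts$meth[keep, lib] / counts$total[keep, lib],
                   digits = 10),
      meth = counts$meth[keep, lib],
      unmeth = counts$total[keep, lib] - counts$meth[keep, lib]
    )
    p <- file.path(dir, paste0(lib, ".cov"))
    utils::write.table(d, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Split spike-in sites from genomic sites
#'
#' Partitions a count matrix by contig into genomic sites and spike-in
#' (conversion-control) sites; counts are conserved.
#'
#' @param counts a [cpg_counts()] matrix.
#' @param spikein_contig contig name reserved for the spike-in.
#' @return A list with `genome` and `spikein` count matrices (either may
#'   have zero rows).
#' @export
split_spikein <- function(counts, spikein_contig = "lambda_spikein") {
  stopifnot(inherits(counts, "cpg_counts"))
  is_spike <- counts$sites$contig == spikein_contig
  list(genome = subset_counts(counts, sites = which(!is_spike)),
       spikein = subset_counts(counts, sites = which(is_spike)))
}

#' Export the clock CpG panel as a BED file
#'
#' Writes one row per CpG with a nonzero clock coefficient, converting the
#' 1-based site positions to BED's 0-based half-open convention. Columns:
#' chrom, start, end, site id, coefficient (days per unit methylation
#' proportion).
#'
#' @param model a [clock_model] as returned by [fit_elastic_net_clock()].
#' @param sites data.frame with `contig`, `pos`, `site_id` covering every
#'   panel site (e.g. `counts$sites`).
#' @param path output file path.
#' @return Invisibly, the number of rows written.
#' @export
write_clock_panel <- function(model, sites, path) {
  stopifnot(inherits(model, "clock_model"))
  panel <- clock_panel(model)
  miss <- setdiff(names(panel), sites$site_id)
  if (length(miss)) {
    fail("panel site(s) not in 'sites': %s", paste(miss, collapse = ", "))
  }
  ri <- match(names(panel), sites$site_id)
  d <- data.frame(chrom = sites$contig[ri], start = sites$pos[ri] - 1L,
                  end = sites$pos[ri], name = names(panel),
                  coefficient = unname(panel))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(d))
}

#' Read / write a sample sheet
#'
#' @param path CSV file path.
#' @return `read_sample_sheet()`: the validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  check_sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(check_sample_sheet(samples), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a clock model as JSON
#'
#' @param model a [clock_model].
#' @param path JSON file path.
#' @return `read_clock_model()` returns the restored [clock_model].
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  x <- list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    alpha = model$alpha,
    lambda = model$lambda,
    feature_center = as.list(model$feature_center),
    feature_scale = as.list(model$feature_scale),
    training_libraries = model$training_libraries,
    seed = model$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_clock_model(
    intercept = x$intercept,
    coefficients = unlist(x$coefficients),
    alpha = x$alpha, lambda = x$lambda,
    feature_center = unlist(x$feature_center),
    feature_scale = unlist(x$feature_scale),
    training_libraries = x$training_libraries,
    seed = x$seed
  )
}
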
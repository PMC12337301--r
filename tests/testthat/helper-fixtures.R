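## small programmatic fixtures shared across test files

## a sample sheet for `n_per_group` libraries per treatment at given ages
toy_samples <- function(ages = c(6, 12, 18, 24, 30), reps = 2,
                        treatments = c("control", "diapause")) {
  grid <- expand.grid(replicate = seq_len(reps), age_days = ages,
                      treatment = treatments, stringsAsFactors = FALSE)
  data.frame(
    library_id = sprintf("%s_d%02d_r%d", grid$treatment, grid$age_days,
                         grid$replicate),
    treatment = grid$treatment, age_days = grid$age_days,
    replicate = grid$replicate, pool_size = 10
  )
}

## counts object whose proportions follow `prop_fun(site, age)` exactly,
## using a large fixed total so proportions are exact multiples of 1/total
toy_counts <- function(samples, prop_matrix, total = 1000L,
                       contig = "synth1") {
  stopifnot(ncol(prop_matrix) == nrow(samples))
  n <- nrow(prop_matrix)
  sites <- data.frame(contig = contig, pos = seq(10L, by = 10L,
                                                 length.out = n),
                      site_id = sprintf("s%03d", seq_len(n)))
  meth <- round(prop_matrix * total)
  tot <- matrix(total, n, ncol(prop_matrix))
  cpg_counts(sites, meth, tot, library_ids = samples$library_id)
}

## write a coverage file from explicit lines
write_cov <- function(lines, path = tempfile(fileext = ".cov")) {
  writeLines(lines, path)
  path
}
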
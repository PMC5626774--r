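# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops/set logic so they never share code with the implementation
# they check.

component_maps <- function() {
  comp <- golden_components()
  list(struct = structure(comp$struct, names = comp$drug),
       func = structure(comp$func, names = comp$drug),
       side = structure(comp$side, names = comp$drug))
}

# brute-force consensus oracle: per drug, count distinct qualifying tools in
# each dataset, then count datasets clearing min_tools
oracle_consensus <- function(records, score_max, min_tools, min_datasets) {
  drugs <- unique(records$drug)
  keep <- character()
  for (d in drugs) {
    r <- records[records$drug == d & records$score <= score_max, ]
    ok_datasets <- 0L
    for (ds in unique(r$dataset)) {
      if (length(unique(r$tool[r$dataset == ds])) >= min_tools) {
        ok_datasets <- ok_datasets + 1L
      }
    }
    if (ok_datasets >= min_datasets) keep <- c(keep, d)
  }
  sort(keep)
}

# random score-record table over a drugs x tools x datasets grid
random_records <- function(n_drugs, n_tools = 3L, n_datasets = 3L,
                           density = 0.5) {
  grid <- expand.grid(drug = sprintf("d%02d", seq_len(n_drugs)),
                      tool = sprintf("t%d", seq_len(n_tools)),
                      dataset = sprintf("s%d", seq_len(n_datasets)),
                      method = c("m1", "m2"),
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < density, , drop = FALSE]
  grid$stage <- "st"
  grid$score <- runif(nrow(grid), -1, 1)
  rownames(grid) <- NULL
  grid
}

random_fingerprints <- function(n, bits = 64L) {
  fps <- lapply(seq_len(n), function(i) rbinom(bits, 1L, runif(1, 0.2, 0.8)))
  names(fps) <- sprintf("f%02d", seq_len(n))
  fps
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
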
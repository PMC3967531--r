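# Shared fixtures: reduced-size cohort specs and toy volumes, all built in
# code at test time.

# small cohort spec for fast end-to-end runs
small_spec <- function(seed = 7L, ...) {
  default_dmn_spec(n_young = 4L, n_elder = 4L, n_timepoints = 96L,
                   seed = seed, ...)
}

# a toy single-region label volume on an n^3 grid, 3 mm isotropic
toy_labels <- function(n = 8L, ids = 1L, tissue = "gray") {
  grid <- array(0L, c(n, n, n))
  grid[2:3, 2:3, 2:3] <- ids[1L]
  lt <- data.frame(id = ids, region = paste0("R", ids),
                   hemisphere = rep("L", length(ids)),
                   tissue = rep(tissue, length(ids)),
                   stringsAsFactors = FALSE)
  label_volume(grid, diag(c(3, 3, 3, 1)), lt)
}

# random multi-label volume + matching BOLD for oracle comparisons
random_labelled_bold <- function(n = 8L, n_labels = 10L, nt = 6L, seed = 99L) {
  set.seed(seed)
  grid <- array(sample(0:n_labels, n^3, replace = TRUE), c(n, n, n))
  lt <- data.frame(id = seq_len(n_labels),
                   region = paste0("R", seq_len(n_labels)),
                   hemisphere = "L", tissue = "gray",
                   stringsAsFactors = FALSE)
  labels <- label_volume(grid, diag(c(3, 3, 3, 1)), lt)
  bold <- bold_series(array(rnorm(n^3 * nt, 100, 10), c(n, n, n, nt)),
                      diag(c(3, 3, 3, 1)), 2)
  list(labels = labels, bold = bold)
}

# constant-parameter motion trace
flat_trace <- function(nt, value = 0) {
  matrix(value, nt, 6L)
}
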
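# Shared fixtures, all generated in code.

# small phantom + truth maps, memoised per (shape, seed) within a test run
small_phantom <- local({
  cache <- list()
  function(shape = c(16, 16, 8), seed = 1L) {
    key <- paste(c(shape, seed), collapse = "_")
    if (is.null(cache[[key]])) {
      spec <- phantom_spec(grid_shape = shape, seed = seed)
      lv <- make_label_phantom(spec)
      cache[[key]] <<- list(spec = spec, lv = lv, maps = truth_maps(lv, spec))
    }
    cache[[key]]
  }
})

# label_volume from a plain array, with a minimal lut covering its labels
lv_from_array <- function(arr, extra_ids = integer(0)) {
  ids <- sort(unique(c(setdiff(as.integer(arr), 0L), as.integer(extra_ids))))
  if (length(ids) == 0L) ids <- 1L
  label_volume(arr, data.frame(label_id = ids,
                               region_name = paste("region", ids),
                               hemisphere = "none"))
}

# tiny two-region block map pair (t1/t2-style values in a 3-D array)
block_map <- function(values, shape = c(4, 2, 2)) {
  stopifnot(prod(shape) %% length(values) == 0)
  array(rep(values, each = prod(shape) / length(values)), dim = shape)
}

# Rician sampler for independent checks
rician_sample <- function(s, sigma, n = length(s)) {
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# independent per-voxel counting oracle for label fusion: tabulate votes,
# smallest id wins ties
fuse_oracle <- function(arrs) {
  out <- array(0L, dim = dim(arrs[[1]]))
  for (v in seq_along(out)) {
    votes <- vapply(arrs, function(a) a[v], integer(1))
    tab <- table(votes)
    out[v] <- min(as.integer(names(tab)[tab == max(tab)]))
  }
  out
}

# brute-force rank-test oracles built on expand.grid (a different
# enumeration route than the package's combn/sign-matrix branches)
mw_oracle_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  u_of <- function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  grids <- expand.grid(rep(list(seq_len(n)), n1))
  keep <- apply(grids, 1, function(r) all(diff(sort(r)) > 0))
  us <- apply(grids[keep, , drop = FALSE], 1, function(r) u_of(as.integer(r)))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
wsr_oracle_p <- function(d) {
  d <- d[d != 0]
  rk <- rank(abs(d))
  wp_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), length(d)))
  ws <- apply(signs, 1, function(s) sum(rk[as.logical(s)]))
  min(1, 2 * min(mean(ws <= wp_obs + 1e-9), mean(ws >= wp_obs - 1e-9)))
}
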
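# Independent oracles used across tests. These deliberately share no code
# with the package internals.

# Brute-force flood-fill connected-component labelling (queue-based BFS over
# explicit neighbour enumeration).
flood_fill_label <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nextlab <- 0L
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  manh <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- switch(as.character(connectivity),
                 "6" = offs[manh == 1, ],
                 "18" = offs[manh <= 2, ],
                 "26" = offs)
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      co <- arrayInd(v, dm)
      for (k in seq_len(nrow(offs))) {
        z <- co[1] + offs$dz[k]; y <- co[2] + offs$dy[k]; x <- co[3] + offs$dx[k]
        if (z < 1 || z > dm[1] || y < 1 || y > dm[2] || x < 1 || x > dm[3]) next
        li <- z + (y - 1) * dm[1] + (x - 1) * dm[1] * dm[2]
        if (mask[li] != 0 && lab[li] == 0L) {
          lab[li] <- nextlab
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff relabelling each by first
# occurrence makes them identical.
canonical_labels <- function(lab) {
  idx <- which(lab != 0)
  v <- lab[idx]
  relab <- match(v, unique(v))
  out <- array(0L, dim(lab))
  out[idx] <- relab
  out
}

random_mask <- function(dim = c(5L, 12L, 12L), p = 0.3) {
  array(runif(prod(dim)) < p, dim)
}

# Closed-form 4PL, written independently of the package.
fourpl_oracle <- function(dose, bottom, top, mid, hill) {
  bottom + (top - bottom) / (1 + (dose / mid)^hill)
}

# Config used wherever a test needs guaranteed-exact segmentation: no noise
# floor, so every planted voxel and nothing else clears the threshold.
noise_free_config <- function(...) {
  sim_config(background_sd = 0, dapi_sd = 0, ...)
}

exact_params <- function(experiment_id = NULL) {
  foci_params(background_mean = 100, background_sd = 0,
              experiment_id = experiment_id)
}
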
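# Small parameter sets used across tests. Fields are kept modest so
# individual stacks generate in well under a second.

small_params <- function(...) {
  args <- list(field_size_px = c(96L, 96L), n_sections = 10L, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(synth_params, args)
}

# Construct a binary_stack directly from a logical array.
mask_stack <- function(mask, channel = "test", px = 0.1, th = 0.07) {
  binary_stack(mask, channel, px, th)
}

# Independent flood-fill labeling oracle: plain breadth-first search
# over the explicit voxel adjacency (8-neighbors in-plane, same-xy in
# consecutive sections). Deliberately slow and simple.
bfs_label_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  neighbors <- function(r, c, s) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2] && mask[rr, cc, s])
        out[[length(out) + 1L]] <- c(rr, cc, s)
    }
    for (ds in c(-1L, 1L)) {
      ss <- s + ds
      if (ss >= 1 && ss <= d[3] && mask[r, c, ss])
        out[[length(out) + 1L]] <- c(r, c, ss)
    }
    out
  }
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    start <- arrayInd(i, d)
    queue <- list(c(start))
    lab[i] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (nb in neighbors(v[1], v[2], v[3])) {
        if (lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# Exhaustive Mann-Whitney oracle: distribution of U over all
# assignments of the pooled values to group A (no ties assumed).
enum_mw_p <- function(a, b, alternative = "two.sided") {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}
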
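# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Seeds are explicit scenario fields, never ambient state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 8-connected component labelling of a logical matrix. EBImage::bwlabel
# gives 4-connected labels; labels whose components touch diagonally are
# then merged with union-find so that diagonal contact joins components.
labelComponents <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Quantile envelope of a vector of diameters: upper (resting) and lower
# (constricted) values.
envelopeQuantiles <- function(values, hiQuantile = 0.95, loQuantile = 0.05) {
  c(resting = unname(stats::quantile(values, hiQuantile)),
    constricted = unname(stats::quantile(values, loQuantile)))
}

# First grid time >= t (right quantization onto an observation grid).
snapToGrid <- function(t, grid) {
  idx <- findInterval(t, grid, left.open = TRUE) + 1L
  if (any(idx > length(grid)))
    stop("observation grid does not extend to ", max(t), " min")
  grid[idx]
}
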
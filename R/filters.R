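## Low-level neighbourhood filters built on integral images.
##
## All image matrices in this package are laid out with rows = y (increasing
## downward) and columns = x (increasing rightward); pixel (x, y) in the
## 0-based user-facing coordinate system is element [y + 1, x + 1].

# Local sum over a (2*ry+1) x (2*rx+1) window, replicate-padded borders.
# O(N) via a summed-area table (compiled).
box_sum <- function(m, ry, rx) {
  storage.mode(m) <- "double"
  .box_sum_cpp(m, as.integer(ry), as.integer(rx))
}

# Local standard deviation in a (2r+1)^2 neighbourhood (population SD).
local_sd <- function(m, r = 4L) {
  n <- (2 * r + 1)^2
  mu <- box_sum(m, r, r) / n
  mu2 <- box_sum(m * m, r, r) / n
  v <- mu2 - mu * mu
  v[v < 0] <- 0
  sqrt(v)
}

# Local Shannon entropy (bits) of the intensity histogram in a (2r+1)^2
# neighbourhood; intensities are quantized to `nbins` equal-width bins over
# the global range of the input.
local_entropy <- function(m, r = 4L, nbins = 16L) {
  rng <- range(m)
  if (rng[2] <= rng[1]) return(matrix(0, nrow(m), ncol(m)))
  q <- pmin(floor((m - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L, nbins)
  n <- (2 * r + 1)^2
  ent <- matrix(0, nrow(m), ncol(m))
  for (b in seq_len(nbins)) {
    p <- box_sum((q == b) * 1, r, r) / n
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

# Binary majority vote over an ry x rx half-size window (median of a binary
# image == majority filter).
majority_filter <- function(mask, ry, rx) {
  n <- (2 * ry + 1) * (2 * rx + 1)
  box_sum(mask * 1, ry, rx) > n / 2
}

# Shifted copy with replicated edges.
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

## 8-connected labelling.  EBImage::bwlabel() is 4-connected; labels that
## touch diagonally are merged with a union-find pass over the label graph.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  pairs <- NULL
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nrow(lab) - 1L), , drop = FALSE]
    if (d[2] == 1L) {
      a <- a[, seq_len(ncol(lab) - 1L), drop = FALSE]
      b <- lab[-1L, -1L, drop = FALSE]
    } else {
      a <- a[, -1L, drop = FALSE]
      b <- lab[-1L, seq_len(ncol(lab) - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lut <- c(0L, remap)
  matrix(lut[lab + 1L], nrow(lab), ncol(lab))
}

# Sizes of labelled objects (pixel counts), indexed by label.
label_sizes <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = n)
}

# Keep only labels for which `keep` (logical vector indexed by label) is TRUE.
filter_labels <- function(lab, keep) {
  lut <- c(FALSE, keep)
  m <- matrix(lut[lab + 1L], nrow(lab), ncol(lab))
  m
}

# Largest connected component of a binary mask (8-connected); empty mask
# is returned unchanged.
largest_component <- function(mask) {
  lab <- label8(mask)
  sz <- label_sizes(lab)
  if (length(sz) == 0L) return(mask & FALSE)
  lab == which.max(sz)
}
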
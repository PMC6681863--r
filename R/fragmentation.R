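## Fragmentation of compound ("fork-like") glands.
##
## Adjacent glands occasionally merge into one labelled object through a
## thin bridge. Such objects are detected from the column-wise pixel-count
## profile and the moment-ellipse orientation, and split by vertical cuts
## at significant profile minima. A split is only accepted when all
## resulting fragments look like glands (near-vertical, elongated);
## otherwise the object passes through unchanged. The control flow is a
## reconstruction: only the five gate thresholds are published for the
## original device, and they are kept as the defaults here.

#' Fragmentation gate thresholds
#'
#' @param NlTH max allowed number of significant column-profile minima
#'   before a split is attempted.
#' @param OTH max allowed deviation of the object orientation from
#'   vertical (degrees) before a split is attempted.
#' @param NoTH minimum number of fragments a split must produce.
#' @param O2TH max deviation from vertical (degrees) allowed for every
#'   fragment of an accepted split.
#' @param RTH minimum length/width ratio for every fragment.
#' @param min_prominence_frac a profile minimum is significant when its
#'   depth below the lower flanking maximum is at least this fraction of
#'   the profile maximum.
#' @return A list of class `mg_frag_params`.
#' @export
fragmentation_params <- function(NlTH = 1L, OTH = 50, NoTH = 1L, O2TH = 50,
                                 RTH = 3, min_prominence_frac = 0.2) {
  p <- list(NlTH = NlTH, OTH = OTH, NoTH = NoTH, O2TH = O2TH, RTH = RTH,
            min_prominence_frac = min_prominence_frac)
  if (any(unlist(p) <= 0)) parameter_error("all thresholds must be positive")
  structure(p, class = "mg_frag_params")
}

# Significant local minima of a column profile. A column is a significant
# minimum when it is a local minimum (plateaus allowed) and its depth below
# the lower of the two flanking maxima is >= frac * max(profile).
# Returns a logical vector over the profile.
profile_minima <- function(prof, frac) {
  n <- length(prof)
  sig <- rep(FALSE, n)
  if (n < 3L) return(sig)
  thr <- frac * max(prof)
  runs <- rle(prof)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    l <- starts[k]; r <- ends[k]; v <- runs$values[k]
    if (l == 1L || r == n) next                      # border plateaus
    if (prof[l - 1L] <= v || prof[r + 1L] <= v) next # not a local minimum
    depth <- min(max(prof[1:l]), max(prof[r:n])) - v
    if (depth >= thr) sig[l:r] <- TRUE
  }
  sig
}

# Moment-ellipse length/width ratio of a pixel set.
aspect_ratio <- function(pixels) {
  m <- moment_ellipse(pixels)
  m$length / max(m$width, 1e-9)
}

# Attempt to fragment one object (logical matrix). Returns a list of
# logical matrices (same dims) covering exactly the input pixels.
fragment_object <- function(obj, params) {
  cols <- which(colSums(obj) > 0)
  prof <- colSums(obj)[cols]
  pix <- which(obj, arr.ind = TRUE)
  orient <- tryCatch(object_orientation(pix),
                     degenerate_object_error = function(e) 90)
  sig <- profile_minima(prof, params$min_prominence_frac)
  Nl <- sum(sig)
  if (!(Nl > params$NlTH || abs(orient - 90) > params$OTH))
    return(list(obj))
  if (Nl == 0L) return(list(obj))      # nothing to cut along
  # centers of contiguous runs of significant minima -> cut columns
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cut_local <- floor((starts[runs$values] + ends[runs$values]) / 2)
  cuts <- cols[cut_local]
  bounds <- c(min(cols) - 1L, cuts, max(cols))
  frags <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    f <- obj
    f[, setdiff(seq_len(ncol(obj)), (bounds[k] + 1L):bounds[k + 1L])] <- FALSE
    if (any(f)) frags[[length(frags) + 1L]] <- f
  }
  if (length(frags) <= params$NoTH) return(list(obj))
  ok <- vapply(frags, function(f) {
    fp <- which(f, arr.ind = TRUE)
    if (nrow(fp) < 3L) return(FALSE)
    ang <- object_orientation(fp)
    abs(ang - 90) <= params$O2TH && aspect_ratio(fp) >= params$RTH
  }, logical(1))
  if (!all(ok)) return(list(obj))
  # recurse on accepted fragments
  out <- list()
  for (f in frags) out <- c(out, fragment_object(f, params))
  out
}

#' Fragment compound glands
#'
#' For each labelled object, the number of significant local minima `Nl`
#' of the column-wise pixel-count profile is computed. When `Nl > NlTH`
#' or the object orientation deviates from vertical by more than `OTH`
#' degrees, the object is split by vertical cuts at the minima. The split
#' is accepted only if it produces more than `NoTH` fragments and every
#' fragment is within `O2TH` degrees of vertical with a length/width
#' ratio of at least `RTH`; otherwise the object is kept. Accepted
#' fragments are re-examined recursively. Foreground pixels are conserved
#' exactly and the operation is idempotent.
#'
#' @param labelmap an `mg_labelmap` from [label_glands()].
#' @param params an `mg_frag_params` (see [fragmentation_params()]).
#' @return An `mg_labelmap` with fragments relabelled left-to-right.
#' @export
fragment_compound_glands <- function(labelmap, params = fragmentation_params()) {
  lab <- labelmap$labels
  n <- max(lab)
  if (n == 0L) return(labelmap)
  pieces <- list()
  for (l in seq_len(n)) {
    obj <- lab == l
    pieces <- c(pieces, fragment_object(obj, params))
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(pieces)) out[pieces[[k]]] <- k
  mg_labelmap(relabel_by_column(out))
}
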
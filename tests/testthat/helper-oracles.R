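# Independent oracles used by several test files.

# Total within-class variance minimizer by direct partition evaluation on
# the raw (integer-binned) values; candidate thresholds between the
# observed unique values. Returns the last value of each lower class.
brute_force_otsu <- function(values, n_classes = 4L) {
  v <- round(values)
  lv <- sort(unique(v))
  cand <- utils::combn(lv[-length(lv)], n_classes - 1L)
  cost_of <- function(thr) {
    cls <- findInterval(v, c(-Inf, thr + 0.5, Inf))
    sum(vapply(split(v, cls), function(g) sum((g - mean(g))^2), numeric(1)))
  }
  costs <- apply(cand, 2L, cost_of)
  cand[, which.min(costs)]
}
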
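# Integer interval arithmetic on 0-based half-open intervals.
#
# Intervals are 2-column matrices (start, end) with start < end. All region
# logic in the package (constitutive introns, region classes, probe-set
# containment) is built on these primitives; tests verify them against
# base-wise brute force.

iv <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("NA interval bounds")
  if (any(start >= end)) stop("interval start must be < end")
  m <- cbind(start = start, end = end)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

iv_empty <- function() {
  cbind(start = integer(0), end = integer(0))
}

# merge overlapping/adjacent intervals into maximal disjoint intervals
iv_union <- function(m) {
  if (nrow(m) == 0L) return(iv_empty())
  o <- order(m[, 1L], m[, 2L])
  s <- m[o, 1L]; e <- m[o, 2L]
  hi <- cummax(e)
  new_grp <- c(TRUE, s[-1L] > hi[-length(hi)])
  end_idx <- c(which(new_grp[-1L]), length(s))
  cbind(start = s[new_grp], end = hi[end_idx])
}

iv_intersect <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L])
    e <- pmin(a[i, 2L], b[, 2L])
    keep <- s < e
    out_s <- c(out_s, s[keep]); out_e <- c(out_e, e[keep])
  }
  if (length(out_s) == 0L) return(iv_empty())
  iv_union(cbind(out_s, out_e))
}

iv_setdiff <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (nrow(a) == 0L) return(iv_empty())
  if (nrow(b) == 0L) return(a)
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1L]; e <- a[i, 2L]
    ov <- b[b[, 2L] > s & b[, 1L] < e, , drop = FALSE]
    cur <- s
    if (nrow(ov) > 0L) {
      for (j in seq_len(nrow(ov))) {
        if (ov[j, 1L] > cur) { out_s <- c(out_s, cur); out_e <- c(out_e, ov[j, 1L]) }
        cur <- max(cur, ov[j, 2L])
      }
    }
    if (cur < e) { out_s <- c(out_s, cur); out_e <- c(out_e, e) }
  }
  if (length(out_s) == 0L) return(iv_empty())
  cbind(start = out_s, end = out_e)
}

# is [s, e) contained in a single interval of the (disjoint, sorted) set m?
iv_contains <- function(m, s, e) {
  if (nrow(m) == 0L) return(rep(FALSE, length(s)))
  idx <- findInterval(s, m[, 1L])
  ok <- idx >= 1L
  ok[ok] <- s[ok] >= m[idx[ok], 1L] & e[ok] <= m[idx[ok], 2L]
  ok
}

# does [s, e) overlap any interval of m?
iv_overlaps <- function(m, s, e) {
  if (nrow(m) == 0L) return(rep(FALSE, length(s)))
  out <- logical(length(s))
  for (i in seq_len(nrow(m))) out <- out | (s < m[i, 2L] & e > m[i, 1L])
  out
}

iv_width <- function(m) if (nrow(m) == 0L) 0L else sum(m[, 2L] - m[, 1L])
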
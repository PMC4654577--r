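# Half-open interval [start, end) algebra on two-column tibbles.
# All pipeline interval sets (segments, turns, speaking/listening) use this
# convention so that a beat belongs to exactly one side of any boundary.

iv <- function(start, end) {
  stopifnot(length(start) == length(end))
  tibble::tibble(start = as.numeric(start), end = as.numeric(end))
}

iv_empty <- function() iv(numeric(0), numeric(0))

#' @noRd
iv_merge <- function(x) {
  x <- x[x$end > x$start, , drop = FALSE]
  if (nrow(x) < 2) return(x[order(x$start), ])
  x <- x[order(x$start, x$end), ]
  start <- x$start[1]; end <- x$end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(x))[-1]) {
    if (x$start[i] <= end) {
      end <- max(end, x$end[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- x$start[i]; end <- x$end[i]
    }
  }
  iv(c(out_s, start), c(out_e, end))
}

iv_union <- function(a, b) iv_merge(rbind(a[c("start", "end")], b[c("start", "end")]))

#' @noRd
iv_setdiff <- function(a, b) {
  a <- iv_merge(a); b <- iv_merge(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    cuts <- b[b$end > s & b$start < e, , drop = FALSE]
    pos <- s
    if (nrow(cuts) > 0) {
      for (j in seq_len(nrow(cuts))) {
        if (cuts$start[j] > pos) {
          out_s <- c(out_s, pos); out_e <- c(out_e, cuts$start[j])
        }
        pos <- max(pos, cuts$end[j])
      }
    }
    if (pos < e) {
      out_s <- c(out_s, pos); out_e <- c(out_e, e)
    }
  }
  iv(out_s, out_e)
}

#' @noRd
iv_intersect <- function(a, b) iv_setdiff(a, iv_setdiff(a, b))

iv_total <- function(x) sum(pmax(x$end - x$start, 0))

# membership of points in the union of intervals (half-open)
iv_contains <- function(x, t) {
  x <- iv_merge(x)
  if (nrow(x) == 0) return(rep(FALSE, length(t)))
  idx <- findInterval(t, x$start)
  idx > 0 & t < x$end[pmax(idx, 1)]
}
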
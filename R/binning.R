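#' Assign heartbeats to respiratory bins
#'
#' Groups heartbeats into respiratory phases from the foot-head navigator
#' displacement.  Bins start as equal-population quantile bins; if any
#' bin's displacement range exceeds `max_width` the bin count is increased
#' (up to 5); if the guard still fails at 5 bins, a greedy width-capped
#' segmentation of the sorted displacements is used instead.  Positive
#' `d_FH` is foot-to-head displacement away from end-expiration, so the bin
#' whose centre displacement is smallest is the end-expiration reference
#' (ties broken by the first such bin).
#'
#' @param trace Data frame with columns `beat`, `d_LR`, `d_FH` (mm).
#' @param n_bins Requested number of bins, 3 to 5.
#' @param max_width Maximum bin displacement range (mm), default 3.5.
#' @return A `respiratory_bins` object: tibble `(beat, bin)` plus
#'   attributes `centres` (median displacement per bin, mm), `widths`,
#'   `reference`.
#' @export
assign_bins <- function(trace, n_bins = 4, max_width = 3.5) {
  if (n_bins < 3 || n_bins > 5)
    stop("n_bins must be between 3 and 5")
  d <- trace$d_FH
  make_quantile_bins <- function(k) {
    if (diff(range(d)) == 0) return(rep(1L, length(d)))
    qs <- quantile(d, probs = seq(0, 1, length.out = k + 1), type = 7)
    qs[1] <- -Inf
    qs[k + 1] <- Inf
    qs <- unique(qs)
    as.integer(cut(d, breaks = qs, include.lowest = TRUE))
  }
  widths_of <- function(bins) {
    vapply(split(d, bins), function(x) diff(range(x)), numeric(1))
  }
  k <- n_bins
  bins <- make_quantile_bins(k)
  while (any(widths_of(bins) > max_width) && k < 5) {
    k <- k + 1
    bins <- make_quantile_bins(k)
  }
  if (any(widths_of(bins) > max_width)) {
    # greedy width-capped segmentation of the sorted displacements
    ord <- order(d)
    bins <- integer(length(d))
    cur <- 1L
    start <- d[ord[1]]
    for (i in ord) {
      if (d[i] - start > max_width) {
        cur <- cur + 1L
        start <- d[i]
      }
      bins[i] <- cur
    }
  }
  centres <- vapply(split(d, bins), median, numeric(1))
  out <- tibble(beat = trace$beat, bin = as.integer(bins))
  structure(out,
            class = c("respiratory_bins", class(out)),
            centres = centres,
            widths = widths_of(bins),
            reference = as.integer(names(centres)[which.min(centres)]))
}

#' @export
print.respiratory_bins <- function(x, ...) {
  cat(sprintf("<respiratory_bins> %d beats in %d bins (reference bin %d)\n",
              nrow(x), length(attr(x, "centres")), attr(x, "reference")))
  cat("centres (mm):", paste(signif(attr(x, "centres"), 3), collapse = ", "),
      "\n")
  invisible(x)
}
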
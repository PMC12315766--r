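binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h   # H(0) = H(1) = 0 by continuity
}

#' Information transfer rate curve
#'
#' For a binary task, `ITR = (1 - H(p)) / T` bits per second, where `H` is
#' the binary entropy of the per-window accuracy probability `p` and `T`
#' the elapsed decoding time of the window (see [build_windows()]). When a
#' decoding curve is supplied, `p` defaults to the window's mean AUC used
#' as the accuracy probability — the conventional proxy when scoring is
#' AUC-based; any probability-like series may be passed instead. Under the
#' incremental convention the metric is bounded by `1 / 0.1 = 10` bits/s
#' (perfect accuracy in the first 100 ms window).
#'
#' @param x a `bb_curve` from [crossval_decode()], or a numeric vector of
#'   per-window accuracy probabilities.
#' @param windows a [build_windows()] result (taken from the curve when
#'   omitted).
#' @return an object of class `bb_itr`: data.frame with `start`, `end`,
#'   `T`, `p`, `H`, `itr` (bits/s).
#' @export
compute_itr <- function(x, windows = NULL) {
  if (inherits(x, "bb_curve")) {
    if (is.null(windows)) windows <- x$windows
    p <- x$mean
  } else {
    p <- as.numeric(x)
  }
  if (is.null(windows)) stop("windows required")
  win <- windows$windows
  if (length(p) != nrow(win))
    stop("shape error: one probability per window required")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(win$T <= 0)) stop("nonpositive window time cost T")
  H <- binary_entropy(p)
  structure(data.frame(start = win$start, end = win$end, T = win$T,
                       p = p, H = H, itr = (1 - H) / win$T),
            class = c("bb_itr", "data.frame"))
}
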
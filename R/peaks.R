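# Peak detection on a 1D signal, following the conventions of the common
# scientific peak finders: a peak is a strict local maximum (plateaus
# reduced to their middle sample), its prominence is measured against the
# lowest point separating it from higher terrain on either side, and its
# width is measured at half prominence by linear interpolation.

find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i - 1L] < x[i]) {
      # scan forward over a possible plateau
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

peak_prominence <- function(x, p) {
  n <- length(x)
  # left: walk until a value higher than the peak or the signal start
  i <- p - 1L
  left_min <- x[p]
  while (i >= 1L && x[i] <= x[p]) {
    if (x[i] < left_min) left_min <- x[i]
    i <- i - 1L
  }
  j <- p + 1L
  right_min <- x[p]
  while (j <= n && x[j] <= x[p]) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  x[p] - max(left_min, right_min)
}

peak_width <- function(x, p, prominence, rel_height = 0.5) {
  h <- x[p] - rel_height * prominence
  n <- length(x)
  i <- p
  while (i > 1L && x[i - 1L] > h) i <- i - 1L
  left <- if (i > 1L) i - (x[i] - h) / (x[i] - x[i - 1L]) else 1
  j <- p
  while (j < n && x[j + 1L] > h) j <- j + 1L
  right <- if (j < n) j + (x[j] - h) / (x[j] - x[j + 1L]) else n
  right - left
}

#' Find peaks in a numeric vector
#'
#' Local maxima filtered by minimum height and by minimum width at half
#' prominence (linear interpolation between samples). `NA` values are
#' treated as 0.
#'
#' @param x numeric vector.
#' @param height minimum peak value.
#' @param width minimum width (in samples) at half prominence.
#' @return data.frame with `pos` (index), `height`, `prominence`, `width`.
#' @export
find_peaks <- function(x, height = -Inf, width = 0) {
  x[is.na(x)] <- 0
  cand <- find_local_maxima(x)
  cand <- cand[x[cand] >= height]
  if (!length(cand))
    return(data.frame(pos = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  prom <- vapply(cand, function(p) peak_prominence(x, p), 0)
  wid <- mapply(function(p, pr) peak_width(x, p, pr), cand, prom)
  keep <- wid >= width
  data.frame(pos = cand[keep], height = x[cand[keep]],
             prominence = prom[keep], width = wid[keep])
}
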
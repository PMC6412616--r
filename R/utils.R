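# Error taxonomy: content errors (invalid data for an otherwise readable
# input) vs format errors (unreadable or lossy encodings). Both inherit
# from "qube_error" so callers can trap everything the package raises.

abort_content <- function(msg, ...) {
  abort(msg, class = c("qube_content_error", "qube_error"), ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("qube_format_error", "qube_error"), ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_scalar_number(x) || x < min || x > max) {
    abort_content(sprintf("`%s` must be a finite number in [%s, %s]",
                          name, format(min), format(max)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is_scalar_number(x) || x %% 1 != 0 || x < min) {
    abort_content(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Mean (box) filter with edge replication; the output pixel sits at index
# floor(side/2) of the window, so odd sides are symmetric. Computed with a
# padded summed-area table; exact up to floating point.
box_mean <- function(x, side) {
  side <- check_count(side, "side", min = 1L)
  nr <- nrow(x)
  nc <- ncol(x)
  if (side > nr || side > nc) abort_content("smoothing window larger than frame")
  if (side == 1L) return(x)
  lo <- side %/% 2L
  hi <- side - 1L - lo
  ridx <- pmin(pmax(seq_len(nr + side - 1L) - lo, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + side - 1L) - lo, 1L), nc)
  p <- x[ridx, cidx, drop = FALSE]
  # summed-area table with a zero border
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- seq_len(nr)
  c1 <- seq_len(nc)
  (s[r1 + side, c1 + side, drop = FALSE] - s[r1, c1 + side, drop = FALSE] -
      s[r1 + side, c1, drop = FALSE] + s[r1, c1, drop = FALSE]) / (side * side)
}
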
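# Raw-stack pre-processing: histogram matching across the 9 frames (so phase
# stepping does not change the intensity statistics the reconstruction sees)
# and median filtering (impulse noise rejection). Both operate on plain
# numeric matrices.

#' Median filter with reflected edges
#'
#' Each pixel is replaced by the median of its `window x window`
#' neighbourhood; edges are handled by mirror reflection. `window = 1` is the
#' identity. The common 3 x 3 case uses a vectorized median-of-9 sorting
#' network; larger windows fall back to a generic (slower) path.
#'
#' @param image numeric matrix.
#' @param window odd integer window size (>= 1).
#' @return Filtered matrix.
#' @examples
#' median_filter(matrix(c(1, 2, 9, 2, 1), 1), 3)  # 1 2 2 2 1
#' @export
median_filter <- function(image, window = 3L) {
  if (window %% 2 != 1 || window < 1) stop("`window` must be an odd integer >= 1")
  if (window == 1L) return(image)
  p <- (window - 1L) %/% 2L
  pad <- reflect_pad(image, p)
  nr <- nrow(image); nc <- ncol(image)
  shifts <- expand.grid(dy = 0:(window - 1L), dx = 0:(window - 1L))
  if (window == 3L) {
    v <- lapply(seq_len(9L), function(i) {
      as.numeric(pad[shifts$dy[i] + seq_len(nr), shifts$dx[i] + seq_len(nc)])
    })
    return(matrix(median9(v), nr, nc))
  }
  stack <- vapply(seq_len(nrow(shifts)), function(i) {
    as.numeric(pad[shifts$dy[i] + seq_len(nr), shifts$dx[i] + seq_len(nc)])
  }, numeric(nr * nc))
  matrix(apply(stack, 1L, median), nr, nc)
}

# Mirror-reflect a matrix by p pixels on every side (edge row/col not
# duplicated, the usual "reflect" convention).
reflect_pad <- function(x, p) {
  nr <- nrow(x); nc <- ncol(x)
  if (p >= nr || p >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(p) + 1L), seq_len(nr), nr - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(nc), nc - seq_len(p))
  x[ri, ci, drop = FALSE]
}

# Vectorized exact median of 9 equal-length vectors (pairwise min/max
# sorting network).
median9 <- function(v) {
  sw <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  v[[5]]
}

#' Histogram matching
#'
#' Applies the monotone intensity mapping `T = CDF_ref^{-1} o CDF_src` so the
#' output's empirical distribution matches the reference's. Implemented on
#' the unique source values (every occurrence of a value maps to the same
#' output, so pixel rank order is preserved), interpolating the reference's
#' quantile curve between its knots.
#'
#' @param source,reference numeric matrices (any common intensity domain).
#' @return Matrix shaped like `source` with the reference's distribution.
#' @export
histogram_match <- function(source, reference) {
  if (length(unique(as.numeric(reference))) < 2L) {
    stop("degenerate reference: histogram matching needs a non-constant reference")
  }
  src <- as.numeric(source)
  tab <- sort(unique(src))
  # source CDF evaluated at its own unique values
  src_cdf <- cumsum(tabulate(match(src, tab), nbins = length(tab))) / length(src)
  # reference quantile curve
  ref_sorted <- sort(as.numeric(reference))
  ref_cdf <- seq_along(ref_sorted) / length(ref_sorted)
  mapped <- approx(ref_cdf, ref_sorted, xout = src_cdf, rule = 2, ties = "ordered")$y
  matrix(mapped[match(src, tab)], nrow(source), ncol(source))
}

#' Pre-process a raw stack
#'
#' Every frame is histogram-matched to the reference frame, then
#' median-filtered (match first, filter second).
#'
#' @param stack a `sim_stack`.
#' @param reference_index frame (1..9) anchoring the match; default 1.
#' @param window median window (odd); `1` disables filtering.
#' @return A `sim_stack` with processed frames (metadata preserved, with a
#'   `preprocess` record appended).
#' @export
preprocess_stack <- function(stack, reference_index = 1L, window = 3L) {
  stopifnot(inherits(stack, "sim_stack"))
  if (reference_index < 1 || reference_index > 9) {
    stop("`reference_index` must be in 1..9")
  }
  ref <- stack$frames[[reference_index]]
  frames <- lapply(stack$frames, function(f) {
    median_filter(histogram_match(f, ref), window)
  })
  meta <- stack$meta
  meta$preprocess <- list(reference_index = as.integer(reference_index),
                          median_window = as.integer(window))
  sim_stack(frames, meta = meta)
}
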
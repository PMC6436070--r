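# Internal helpers shared across modules.

# Cell label codes used on the raster grid and in the text mask dialect.
LBL_OUTSIDE  <- 0L
LBL_MYO      <- 1L
LBL_CAVITY   <- 2L
LBL_FIBROSIS <- 3L  # myocardium + fibrosis, text dialect only

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count local maxima of a sampled curve
#'
#' Hysteresis (zigzag) counting: a peak is counted each time the curve,
#' having risen to a running maximum, falls below it by more than
#' `min_prominence * diff(range(x))`; the next peak requires a rise of the
#' same amount above the intervening valley.  Used to count contrast-agent
#' passes in signal-intensity curves without picking up discretization
#' ripple.
#'
#' @param x numeric vector, the sampled curve.
#' @param min_prominence minimum two-sided prominence as a fraction of the
#'   curve range.
#' @return integer, number of local maxima.
#' @export
count_local_maxima <- function(x, min_prominence = 0.02) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) return(0L)
  rng <- diff(range(x))
  if (rng <= 0) return(0L)
  thr <- min_prominence * rng
  count <- 0L
  up <- TRUE
  ref <- x[1L]
  for (v in x[-1L]) {
    if (up) {
      if (v > ref) {
        ref <- v
      } else if (ref - v >= thr) {
        count <- count + 1L
        up <- FALSE
        ref <- v
      }
    } else {
      if (v < ref) {
        ref <- v
      } else if (v - ref >= thr) {
        up <- TRUE
        ref <- v
      }
    }
  }
  count
}

# stopifnot with a clearer message
fail_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
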
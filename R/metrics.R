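# Segmentation quality indicators. P is the algorithm's binary mask, Q the
# gold-standard mask; both metrics are pixel-count set ratios.

check_mask <- function(m, name) {
  if (!is.matrix(m)) stop("`", name, "` must be a matrix")
  v <- as.vector(m)
  if (is.logical(v)) v <- as.integer(v)
  if (!all(v %in% c(0L, 1L))) {
    stop("`", name, "` must be binary (values strictly in {0, 1})")
  }
  invisible(m)
}

check_mask_pair <- function(p, q) {
  check_mask(p, "p")
  check_mask(q, "q")
  if (any(dim(p) != dim(q))) {
    stop("mask shapes differ: ", nrow(p), "x", ncol(p), " vs ",
         nrow(q), "x", ncol(q))
  }
}

#' Correct classification ratio
#'
#' `CCR = |P intersect Q| / |P|` by pixel counting: the fraction of the
#' predicted mask that overlaps the gold standard. Note the denominator is
#' the *prediction* P, making this a precision-like (not sensitivity-like)
#' quantity and deliberately asymmetric in its arguments; the
#' `denominator = "gold"` override divides by `|Q|` instead.
#'
#' @param p Predicted binary mask (matrix of 0/1 or logical).
#' @param q Gold-standard binary mask, same shape.
#' @param denominator `"prediction"` (default) or `"gold"`.
#' @return Fraction in `[0, 1]`. Errors (rather than silently returning 0)
#'   when the denominator mask is empty: an empty-mask convention would
#'   silently corrupt averages.
#' @export
ccr <- function(p, q, denominator = c("prediction", "gold")) {
  denominator <- match.arg(denominator)
  check_mask_pair(p, q)
  den <- if (denominator == "prediction") sum(p != 0) else sum(q != 0)
  if (den == 0L) {
    stop("CCR is undefined: the ", denominator, " mask is empty")
  }
  sum(p != 0 & q != 0) / den
}

#' Dice similarity coefficient
#'
#' `DISC = 2 |P intersect Q| / (|P| + |Q|)`: symmetric overlap between
#' prediction and gold standard, 1 iff the masks are identical.
#'
#' @inheritParams ccr
#' @return Fraction in `[0, 1]`. Errors when both masks are empty.
#' @export
disc <- function(p, q) {
  check_mask_pair(p, q)
  np <- sum(p != 0)
  nq <- sum(q != 0)
  if (np + nq == 0L) {
    stop("Dice coefficient is undefined: both masks are empty")
  }
  2 * sum(p != 0 & q != 0) / (np + nq)
}

#' Timed segmentation
#'
#' Runs [pdeac_segment()] `repeats` times on the same input and reports the
#' median wall-clock time in milliseconds. The segmentation result is taken
#' from the first run (the algorithm is deterministic, so all runs agree).
#' Timing is hardware-dependent and informational only.
#'
#' @inheritParams pdeac_segment
#' @param repeats Number of timed runs (>= 1).
#' @return List with `result` (a `pdeac_result`) and `ast_ms` (median
#'   milliseconds).
#' @export
timed_segment <- function(image, params = model_params(), init,
                          repeats = 1L) {
  repeats <- as.integer(check_scalar(repeats, "repeats", 1))
  times <- numeric(repeats)
  result <- NULL
  for (i in seq_len(repeats)) {
    t0 <- proc.time()[["elapsed"]]
    r <- pdeac_segment(image, params, init)
    times[i] <- (proc.time()[["elapsed"]] - t0) * 1000
    if (i == 1L) result <- r
  }
  list(result = result, ast_ms = stats::median(times))
}
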
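# internal numerical helpers

#' @keywords internal
.softmaxVec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# row-wise softmax of a score matrix restricted to masked entries;
# unmasked entries get weight 0.  Every row must contain >= 1 TRUE.
#' @keywords internal
.rowSoftmaxMasked <- function(E, mask) {
  E[!mask] <- -Inf
  .rowSoftmax(E)
}

# row-wise softmax; -Inf entries get weight 0 (each row needs one finite)
#' @keywords internal
.rowSoftmax <- function(E) {
  n <- nrow(E)
  mx <- E[cbind(seq_len(n), max.col(E, ties.method = "first"))]
  Z <- exp(E - mx)         # column recycling: subtracts mx[i] from row i
  Z / rowSums(Z)
}

# additive neighbourhood mask: 0 where attention is allowed, -Inf elsewhere
#' @keywords internal
.maskAdd <- function(mask) {
  M <- matrix(-Inf, nrow(mask), ncol(mask))
  M[mask] <- 0
  M
}

# derive a reproducible sub-seed from a master seed and a stream offset;
# keeps the result a valid 32-bit integer
#' @keywords internal
.subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}

#' @keywords internal
.assertFinite <- function(x, stage) {
  if (!all(is.finite(x)))
    stop("non-finite values produced at stage '", stage, "'", call. = FALSE)
  invisible(x)
}

# stop() with a consistent prefix for user-input validation problems
#' @keywords internal
.vstop <- function(...) stop(..., call. = FALSE)

# activations: ELU for embedding updates / hidden layers, LeakyReLU (slope
# 0.2) for attention scores.  Gradients are recovered from the outputs so
# the backward pass needs no extra cache.
#' @keywords internal
.elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

#' @keywords internal
.eluGradFromOut <- function(y) ifelse(y > 0, 1, y + 1)

#' @keywords internal
.lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)

#' @keywords internal
.lreluGradFromOut <- function(y) ifelse(y > 0, 1, 0.2)
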
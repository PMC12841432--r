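# Sparsemax: Euclidean projection onto the probability simplex.
# Unlike softmax it assigns exact zeros, which is what makes the attentive
# masks instance-wise sparse feature selectors.

#' Sparsemax transformation
#'
#' Projects each row of `z` onto the probability simplex
#' (`argmin_p ||p - z||^2` subject to `p >= 0`, `sum(p) = 1`). Rows sum to 1
#' and may contain exact zeros.
#'
#' @param z numeric vector or matrix (rows are projected independently).
#' @return Object of the same shape as `z`.
#' @export
#' @examples
#' sparsemax(c(0, 0))        # 0.5 0.5
#' sparsemax(c(10, 0, 0))    # 1 0 0
sparsemax <- function(z) {
  vec_in <- is.null(dim(z))
  if (vec_in) z <- matrix(z, nrow = 1)
  if (!length(z)) stop("sparsemax: empty input")
  if (!all(is.finite(z))) stop("sparsemax: input must be finite")
  B <- nrow(z); D <- ncol(z)
  if (D == 1) {
    p <- matrix(1, B, 1)
    return(if (vec_in) drop(p) else p)
  }
  zs <- matrix(0, B, D)
  for (b in seq_len(B)) zs[b, ] <- sort.int(z[b, ], decreasing = TRUE, method = "quick")
  cs <- t(apply(zs, 1, cumsum))
  k <- matrix(seq_len(D), B, D, byrow = TRUE)
  feasible <- 1 + k * zs > cs
  kz <- rowSums(feasible)                      # support size
  tau <- (cs[cbind(seq_len(B), kz)] - 1) / kz
  p <- pmax(z - tau, 0)
  if (vec_in) drop(p) else p
}

# gradient of a scalar loss wrt sparsemax input, given output p and upstream
# gradient g: on the support S, dz = g - mean(g over S); off support, 0.
sparsemax_backward <- function(p, g) {
  S <- p > 0
  ns <- rowSums(S)
  v <- rowSums(g * S) / ns
  S * (g - v)
}
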
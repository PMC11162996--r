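#' Zero-phase IIR filtering in second-order-section form
#'
#' Tools to factor a transfer-function filter design into biquad
#' (second-order) sections and apply it forward-backward with
#' steady-state initial conditions.  Cascading biquads keeps 6th-order
#' Butterworth designs with very low normalized cutoffs (0.3 Hz at
#' 512 Hz sampling) numerically stable where the expanded polynomial
#' form loses the stopband entirely.
#'
#' @name sosfilt
#' @keywords internal
NULL

# polynomial with given roots, leading coefficient 1 (complex-safe)
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Factor transfer-function coefficients into second-order sections
#'
#' @param b,a numerator and denominator polynomial coefficients
#'   (decreasing powers of z^-1), as returned by [signal::butter()].
#' @return numeric matrix with one row per biquad and columns
#'   `b0,b1,b2,a0,a1,a2`; the overall gain is folded into the first
#'   section.
#' @keywords internal
tf2sos <- function(b, a) {
  stopifnot(a[1] != 0)
  k <- b[1] / a[1]
  z <- if (length(b) > 1) polyroot(rev(b / b[1])) else complex(0)
  p <- polyroot(rev(a / a[1]))
  z <- z[order(-Mod(z))]
  p <- p[order(-Mod(p))]
  nsec <- max(1L, ceiling(length(p) / 2))
  sos <- matrix(0, nsec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  used_p <- rep(FALSE, length(p))
  used_z <- rep(FALSE, length(z))
  for (s in seq_len(nsec)) {
    rem <- which(!used_p)
    psec <- complex(0)
    if (length(rem)) {
      i1 <- rem[1]
      used_p[i1] <- TRUE
      psec <- p[i1]
      rem <- which(!used_p)
      if (length(rem)) {
        # conjugate partner (or nearest remaining pole for real poles)
        j <- rem[which.min(Mod(p[rem] - Conj(p[i1])))]
        used_p[j] <- TRUE
        psec <- c(psec, p[j])
      }
    }
    zsec <- complex(0)
    for (dummy in seq_len(length(psec))) {
      remz <- which(!used_z)
      if (!length(remz)) break
      anchor <- if (length(psec)) psec[1] else 0 + 0i
      jz <- remz[which.min(Mod(z[remz] - anchor))]
      used_z[jz] <- TRUE
      zsec <- c(zsec, z[jz])
    }
    bsec <- Re(poly_from_roots(zsec))
    asec <- Re(poly_from_roots(psec))
    sos[s, 1:3] <- c(bsec, numeric(3 - length(bsec)))
    sos[s, 4:6] <- c(asec, numeric(3 - length(asec)))
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# steady-state (step-response) initial state of one biquad,
# direct form II transposed
biquad_zi <- function(b, a) {
  A <- rbind(-a[2:3], c(1, 0))
  Bv <- b[2:3] - a[2:3] * b[1]
  solve(diag(2) - t(A), Bv)
}

sos_zi <- function(sos) {
  zi <- matrix(0, nrow(sos), 2)
  scale <- 1
  for (s in seq_len(nrow(sos))) {
    zi[s, ] <- biquad_zi(sos[s, 1:3], sos[s, 4:6]) * scale
    # DC gain of this section feeds the next section's steady state
    scale <- scale * sum(sos[s, 1:3]) / sum(sos[s, 4:6])
  }
  zi
}

#' Forward-backward (zero-phase) filtering of one channel
#'
#' Applies a second-order-section cascade forward and backward with
#' odd-reflection padding and steady-state initial conditions, so the
#' net filter has zero group delay and the squared magnitude response
#' of the one-pass design.
#'
#' @param sos second-order sections from [tf2sos()].
#' @param x numeric vector.
#' @param padlen extension length in samples at each end; defaults to
#'   `3 * (2 * nrow(sos) + 1)`. Must be `< length(x)`.
#' @return filtered vector, same length as `x`.
#' @keywords internal
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3L * (2L * nrow(sos) + 1L)
  padlen <- as.integer(padlen)
  if (n <= padlen) {
    stop("signal too short to pad: length ", n,
         " <= pad length ", padlen)
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- sos_zi(sos)
  y <- .sosfilt_cpp(sos, ext, zi * ext[1])
  y <- rev(.sosfilt_cpp(sos, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}
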
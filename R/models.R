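#' HKY+Gamma substitution model
#'
#' Constructs an HKY85 model with discrete-Gamma rate variation across sites.
#' The rate matrix is normalised so that branch lengths are in expected
#' substitutions per site at rate multiplier 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param freqs Stationary base frequencies, length 4 in A, C, G, T order;
#'   must sum to 1.
#' @param alpha Shape of the Gamma distribution of site rates (> 0).
#'   `Inf` gives equal rates.
#' @param ncat Number of discrete Gamma categories (default 4).
#' @return An object of class `"hky_model"`.
#' @examples
#' m <- hky_model(kappa = 2, freqs = rep(0.25, 4), alpha = 0.5)
#' @export
hky_model <- function(kappa = 2, freqs = rep(0.25, 4), alpha = Inf, ncat = 4L) {
  stopifnot(length(freqs) == 4, kappa > 0, alpha > 0, ncat >= 1)
  if (abs(sum(freqs) - 1) > 1e-8) stop("base frequencies must sum to 1")
  structure(
    list(kappa = kappa, freqs = as.numeric(freqs), alpha = alpha,
         ncat = as.integer(ncat), eigen = hky_eigen(kappa, freqs),
         cat_rates = gamma_cat_rates(alpha, ncat)),
    class = "hky_model"
  )
}

#' @exportS3Method base::print
print.hky_model <- function(x, ...) {
  cat(sprintf("HKY+G model: kappa = %.4g, alpha = %.4g (%d categories)\n",
              x$kappa, x$alpha, x$ncat))
  cat("  base frequencies (A,C,G,T):", sprintf("%.4f", x$freqs), "\n")
  invisible(x)
}

# Eigen system of the normalised HKY rate matrix, exploiting reversibility
# (symmetrise with diag(sqrt(pi)) so eigen() stays numerically exact).
hky_eigen <- function(kappa, freqs) {
  p <- as.numeric(freqs)
  Q <- matrix(0, 4, 4)
  transition <- matrix(FALSE, 4, 4)
  transition[1, 3] <- transition[3, 1] <- TRUE  # A <-> G
  transition[2, 4] <- transition[4, 2] <- TRUE  # C <-> T
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- ifelse(transition[i, j], kappa, 1) * p[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(p * diag(Q))
  Q <- Q / scale
  sq <- sqrt(p)
  S <- (sq %o% (1 / sq)) * Q  # diag(sq) %*% Q %*% diag(1/sq), symmetric
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(V = (1 / sq) * e$vectors, d = e$values, Vinv = t(e$vectors * sq))
}

# Mean rates of the ncat equal-probability categories of a Gamma(alpha, alpha)
# distribution (Yang 1994 category-mean discretisation).
gamma_cat_rates <- function(alpha, ncat = 4L) {
  if (!is.finite(alpha)) return(rep(1, ncat))
  if (ncat == 1L) return(1)
  b <- stats::qgamma(seq_len(ncat - 1) / ncat, shape = alpha, rate = alpha)
  pb <- c(0, stats::pgamma(b, shape = alpha + 1, rate = alpha), 1)
  r <- ncat * diff(pb)
  r / mean(r) * 1  # guard against rounding drift; already mean 1
}

# 4x4 HKY transition probability matrix for one branch length (R-side helper,
# used by the sequence simulator and small oracles; the likelihood kernel
# recomputes this in C++).
hky_pmatrix <- function(model, t) {
  e <- model$eigen
  P <- e$V %*% (exp(e$d * t) * e$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

BASES <- c("A", "C", "G", "T")
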
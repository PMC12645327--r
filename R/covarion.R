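## Binary covarion model: visible states {absent, present} crossed with
## hidden {fast, slow} categories. State order used throughout:
##   1 = absent/fast, 2 = present/fast, 3 = absent/slow, 4 = present/slow.

#' Covarion rate matrix (generator)
#'
#' Within-category substitution runs at relative rate 1 (fast) or alpha
#' (slow) scaled by the target visible frequency; hidden switching is
#' symmetric at rate \code{switchRate} and preserves the visible state. The
#' generator is rescaled so the expected visible substitution rate per unit
#' time at stationarity equals \code{overallRate}.
#'
#' @param model a \linkS4class{CovarionModel}.
#' @return 4x4 generator with zero row sums.
#' @examples
#' Q <- covarionGenerator(CovarionModel())
#' rowSums(Q)
#' @export
covarionGenerator <- function(model) {
  validObject(model)
  p0 <- model@freq[1]; p1 <- model@freq[2]
  a <- model@alpha; s <- model@switchRate
  Q <- matrix(0, 4, 4, dimnames = list(
    c("0f", "1f", "0s", "1s"), c("0f", "1f", "0s", "1s")))
  Q[1, 2] <- p1;     Q[2, 1] <- p0       # fast category
  Q[3, 4] <- a * p1; Q[4, 3] <- a * p0   # slow category
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- s
  diag(Q) <- -rowSums(Q)
  # expected visible substitution rate at stationarity: (1 + alpha) pi0 pi1
  scale <- model@overallRate / ((1 + a) * p0 * p1)
  Q * scale
}

#' @rdname covarionGenerator
#' @export
CovarionModel <- function(freq = c(0.5, 0.5), alpha = 0.5, switchRate = 0.5,
    overallRate = 1) {
  new("CovarionModel", freq = freq / sum(freq), alpha = alpha,
    switchRate = switchRate, overallRate = overallRate)
}

#' Stationary distribution of the covarion chain
#'
#' Hidden categories are equally frequent; visible marginals equal the model's
#' visible frequencies.
#'
#' @param model a \linkS4class{CovarionModel}.
#' @export
covarionStationary <- function(model) {
  c(model@freq[1] / 2, model@freq[2] / 2, model@freq[1] / 2,
    model@freq[2] / 2)
}

# eigendecomposition of the (reversible) covarion generator via
# symmetrisation: S = D^(1/2) Q D^(-1/2) is symmetric for D = diag(pi)
covarionEigen <- function(model) {
  Q <- covarionGenerator(model)
  pi4 <- covarionStationary(model)
  sq <- sqrt(pi4)
  S <- (sq * Q) %*% diag(1 / sq)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  V <- diag(1 / sq) %*% es$vectors
  Vinv <- t(es$vectors) %*% diag(sq)
  list(values = es$values, V = V, Vinv = Vinv, Q = Q, pi = pi4)
}

#' Transition probability matrix exp(Qt)
#'
#' For a reversible generator this uses the symmetrised eigendecomposition;
#' a scaling-and-squaring series fallback covers general generators.
#'
#' @param Q a rate matrix with zero row sums.
#' @param t duration, >= 0.
#' @return Row-stochastic matrix.
#' @export
transitionProbabilities <- function(Q, t) {
  if (t < 0) stop("duration must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("Q rows must sum to 0")
  n <- nrow(Q)
  if (t == 0) return(diag(n))
  P <- tryCatch({
    es <- eigen(Q)
    if (any(abs(Im(es$values)) > 1e-9)) stop("complex spectrum")
    V <- Re(es$vectors)
    Re(V %*% diag(exp(Re(es$values) * t), n) %*% solve(V))
  }, error = function(e) expmSeries(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# scaling-and-squaring truncated series, adequate for small generators
expmSeries <- function(A, order = 16) {
  s <- max(0L, ceiling(log2(max(1e-12, max(abs(A))))) + 2L)
  A <- A / 2^s
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' Closed-form two-state transition probabilities
#'
#' For the plain binary CTMC with stationary frequencies \code{freq} and
#' expected substitution rate \code{overallRate}:
#' \code{P[i, j](t) = pi_j + (delta_ij - pi_j) exp(-beta t)} with
#' \code{beta = overallRate / (2 pi_0 pi_1)}.
#'
#' @param freq length-2 visible frequencies.
#' @param overallRate expected substitutions per unit time.
#' @param t duration.
#' @export
twoStateProbabilities <- function(freq, overallRate, t) {
  beta <- overallRate / (2 * freq[1] * freq[2])
  e <- exp(-beta * t)
  matrix(c(freq[1] + freq[2] * e, freq[2] * (1 - e),
           freq[1] * (1 - e), freq[2] + freq[1] * e),
    2, 2, byrow = TRUE,
    dimnames = list(c("0", "1"), c("0", "1")))
}

#' Construct a clock model
#'
#' @param kind "strict" or "relaxed".
#' @param meanRate mean substitution rate per unit time.
#' @param stdevLog log-scale standard deviation of branch-rate multipliers
#'   (relaxed clock only).
#' @export
ClockModel <- function(kind = c("strict", "relaxed"), meanRate = 1,
    stdevLog = 0) {
  kind <- match.arg(kind)
  new("ClockModel", kind = kind, meanRate = meanRate, stdevLog = stdevLog)
}

#' Draw per-branch clock rates
#'
#' Strict clocks give every branch \code{meanRate}. Relaxed clocks multiply
#' \code{meanRate} by i.i.d. lognormal draws parameterised to have mean one
#' (\code{mu = -stdevLog^2 / 2}), so the expected rate is preserved.
#'
#' @param clock a \linkS4class{ClockModel}.
#' @param phy an \code{ape::phylo} tree (one rate per edge).
#' @param seed integer seed for reproducibility.
#' @return Numeric vector of per-edge rates, ordered as \code{phy$edge}.
#' @export
drawBranchRates <- function(clock, phy, seed = NULL) {
  validObject(clock)
  ne <- nrow(phy$edge)
  if (clock@kind == "strict" || clock@stdevLog == 0)
    return(rep(clock@meanRate, ne))
  if (!is.null(seed)) set.seed(seed)
  s <- clock@stdevLog
  clock@meanRate * rlnorm(ne, meanlog = -s^2 / 2, sdlog = s)
}
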
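## Birth-death and fossilised birth-death tree prior densities in the
## telescoped q/p0 form. Conventions (documented in the methods vignette):
## densities are conditional on the root age, with both root lineages
## required to leave at least one sampled descendant; fossils are terminal
## tips sampled with removal; constant (parameter-free) combinatorial
## factors are omitted.

#' @rdname bdLogDensity
#' @export
BirthDeathParams <- function(lambda = 1, mu = 0, rho = 1, psi = 0) {
  new("BirthDeathParams", lambda = lambda, mu = mu, rho = rho, psi = psi)
}

# c1, c2 constants of the FBD process (plain-number core; S4 wrapper below)
fbdConstantsNum <- function(lambda, mu, rho, psi) {
  c1 <- sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
  if (c1 <= 0)
    stop("degenerate birth-death parameters (critical process unsupported)")
  c2 <- -(lambda - mu - 2 * lambda * rho - psi) / c1
  list(c1 = c1, c2 = c2, lambda = lambda, mu = mu, rho = rho, psi = psi)
}
fbdConstants <- function(p) fbdConstantsNum(p@lambda, p@mu, p@rho, p@psi)

# log q(t): per-lineage factor for an observed lineage at time t; q(0) = 1
fbdLogQ <- function(t, p = NULL, k = fbdConstants(p)) {
  e <- exp(-k$c1 * t)
  log(4) - k$c1 * t - 2 * log(e * (1 - k$c2) + (1 + k$c2))
}

# p0(t): probability a lineage at time t leaves no sampled descendants
fbdP0 <- function(t, p = NULL, k = fbdConstants(p)) {
  e <- exp(-k$c1 * t)
  (k$lambda + k$mu + k$psi +
      k$c1 * (e * (1 - k$c2) - (1 + k$c2)) / (e * (1 - k$c2) + (1 + k$c2))) /
    (2 * k$lambda)
}

fbdCore <- function(phy, p, conditionOnSurvival = TRUE, fossilTol = 1e-8) {
  validObject(p)
  ages <- nodeAges(phy)
  n <- ape::Ntip(phy)
  tipAges <- ages[seq_len(n)]
  intAges <- ages[(n + 1L):(n + phy$Nnode)]
  rootAge <- intAges[1]
  fossil <- tipAges > fossilTol
  k <- fbdConstants(p)
  ll <- 2 * fbdLogQ(rootAge, p, k) +
    sum(log(p@lambda) + fbdLogQ(intAges[-1], p, k)) +
    sum(!fossil) * log(p@rho)
  if (any(fossil))
    ll <- ll + sum(log(p@psi) - fbdLogQ(tipAges[fossil], p, k))
  if (conditionOnSurvival)
    ll <- ll - 2 * log1p(-fbdP0(rootAge, p, k))
  ll
}

#' Birth-death tree prior log density
#'
#' Log density of a labelled time tree under the reconstructed birth-death
#' process with extant sampling fraction rho, conditioned on the root age and
#' on each root lineage leaving at least one sampled descendant. With mu = 0
#' and rho = 1 this is the conditioned Yule density
#' \code{(n-2) log lambda - lambda L} (L the total branch length including
#' both root edges). All tips must be extant; fossil tips require the
#' fossilised variant \code{fbdLogDensity}.
#'
#' @param phy an \code{ape::phylo} time tree.
#' @param p a \linkS4class{BirthDeathParams} with \code{psi = 0}.
#' @param conditionOnSurvival include the survival conditioning term
#'   (default TRUE).
#' @return Finite log density.
#' @export
bdLogDensity <- function(phy, p, conditionOnSurvival = TRUE) {
  if (p@psi != 0) stop("psi must be 0 for the plain birth-death prior")
  ages <- nodeAges(phy)
  if (any(ages[seq_len(ape::Ntip(phy))] > 1e-8))
    stop("fossil (non-contemporaneous) tip present: use fbdLogDensity")
  fbdCore(phy, p, conditionOnSurvival)
}

#' Fossilised birth-death tree prior log density
#'
#' Extends \code{bdLogDensity} with fossil sampling at rate psi: fossils are
#' non-contemporaneous terminal tips, each contributing a psi sampling factor
#' (sampling with removal; sampled ancestors on internal branches are not
#' supported). With \code{psi = 0} and no fossil tips the value reduces
#' exactly to the plain birth-death density.
#'
#' @inheritParams bdLogDensity
#' @param p a \linkS4class{BirthDeathParams}.
#' @export
fbdLogDensity <- function(phy, p, conditionOnSurvival = TRUE) {
  ages <- nodeAges(phy)
  hasFossil <- any(ages[seq_len(ape::Ntip(phy))] > 1e-8)
  if (hasFossil && p@psi == 0)
    stop("fossil tips present but psi = 0: the fossilised process cannot ",
      "have sampled them")
  fbdCore(phy, p, conditionOnSurvival)
}

#' Construct a calibration constraint
#'
#' @param kind "mrca" (node age of the MRCA of \code{taxa}) or "tip"
#'   (age of one fossil tip).
#' @param taxa taxon label(s).
#' @param lower,upper uniform hard bounds (same time units as the trees,
#'   conventionally years BP with present = 1950 CE).
#' @export
Calibration <- function(kind = c("mrca", "tip"), taxa, lower, upper) {
  kind <- match.arg(kind)
  new("Calibration", kind = kind, taxa = as.character(taxa),
    lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Convert a CE calendar range to years BP
#'
#' Radiocarbon convention: present = 1950 CE, so BP = 1950 - CE. A CE
#' interval [a, b] maps to the BP interval [1950 - b, 1950 - a].
#'
#' @param ce numeric calendar years CE.
#' @param epoch present epoch in CE (default 1950).
#' @export
ceToBP <- function(ce, epoch = 1950) epoch - ce

#' Calibration log prior
#'
#' Returns 0 when every constrained MRCA or tip age lies inside its bounds
#' and \code{-Inf} otherwise (uniform hard bounds).
#'
#' @param phy an \code{ape::phylo} time tree.
#' @param constraints list of \linkS4class{Calibration} objects.
#' @export
calibrationLogPrior <- function(phy, constraints) {
  if (length(constraints) == 0) return(0)
  for (cc in constraints) {
    unknown <- setdiff(cc@taxa, phy$tip.label)
    if (length(unknown) > 0)
      stop("calibration references unknown taxa: ",
        paste(unknown, collapse = ", "))
    age <- mrcaAge(phy, cc@taxa)
    if (age < cc@lower || age > cc@upper) return(-Inf)
  }
  0
}
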
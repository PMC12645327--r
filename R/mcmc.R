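## Metropolis-Hastings sampler over tree topology, node ages, clock,
## substitution, partition and tree-prior parameters.
##
## Internal state encoding: nodes 1..n are tips (fixed label order = taxa of
## the data matrix), n+1..2n-1 internal; `parent` maps each node to its
## parent (0 at the root); `ages` holds node ages. Uniform base measure over
## parent-vector encodings corresponds to the uniform measure over labelled
## topologies, so tree-prior densities need no topology factor.

arraysToPhylo <- function(parent, ages, labels) {
  n <- length(labels)
  N <- length(parent)
  root <- which(parent == 0L)
  # renumber internals so the root gets index n+1 (ape convention)
  newIdx <- integer(N)
  newIdx[seq_len(n)] <- seq_len(n)
  ordInt <- c(root, setdiff((n + 1L):N, root))
  newIdx[ordInt] <- n + seq_along(ordInt)
  child <- which(parent != 0L)
  edge <- cbind(newIdx[parent[child]], newIdx[child])
  len <- ages[parent[child]] - ages[child]
  phy <- structure(list(edge = edge, edge.length = pmax(len, 0),
    tip.label = labels, Nnode = N - n), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# MRCA node index for a set of tip indices
mrcaArrays <- function(parent, tips) {
  anc <- function(i) {
    out <- i
    while (parent[i] != 0L) { i <- parent[i]; out <- c(out, i) }
    out
  }
  common <- anc(tips[1])
  for (t in tips[-1]) common <- intersect(common, anc(t))
  common[1]
}

fbdLogDensityArrays <- function(parent, ages, nTip, k,
    conditionOnSurvival = TRUE, fossilTol = 1e-8) {
  if (is.null(k)) return(-Inf)
  root <- which(parent == 0L)
  tipAges <- ages[seq_len(nTip)]
  others <- setdiff((nTip + 1L):length(parent), root)
  fossil <- tipAges > fossilTol
  if (any(fossil) && k$psi == 0) return(-Inf)
  ll <- 2 * fbdLogQ(ages[root], k = k) +
    sum(log(k$lambda) + fbdLogQ(ages[others], k = k)) +
    sum(!fossil) * log(k$rho)
  if (any(fossil))
    ll <- ll + sum(log(k$psi) - fbdLogQ(tipAges[fossil], k = k))
  if (conditionOnSurvival) {
    p0 <- fbdP0(ages[root], k = k)
    if (p0 >= 1) return(-Inf)
    ll <- ll - 2 * log1p(-p0)
  }
  ll
}

calibrationLogPriorArrays <- function(parent, ages, labels, calibs) {
  if (length(calibs) == 0) return(0)
  for (cc in calibs) {
    idx <- match(cc@taxa, labels)
    age <- if (length(idx) == 1) ages[idx] else ages[mrcaArrays(parent, idx)]
    if (age < cc@lower || age > cc@upper) return(-Inf)
  }
  0
}

# default hyperprior settings; all means are on natural scale
defaultHyper <- function() {
  list(rateMean = 1, switchMean = 1, lambdaMean = 1, muMean = 1,
    psiMean = 1, clockSdMean = 0.5, partMean = 1, rootMax = 10,
    estimateBD = TRUE)
}

paramLogPrior <- function(st, hyper, relaxed, nPart) {
  lp <- stats::dexp(st$rate, 1 / hyper$rateMean, log = TRUE) +
    stats::dexp(st$switch, 1 / hyper$switchMean, log = TRUE) +
    stats::dunif(st$alpha, 0, 1, log = TRUE) +
    stats::dunif(st$piPresent, 0, 1, log = TRUE)
  if (hyper$estimateBD)
    lp <- lp + stats::dexp(st$lambda, 1 / hyper$lambdaMean, log = TRUE) +
      stats::dexp(st$mu, 1 / hyper$muMean, log = TRUE)
  if (nPart > 1)
    lp <- lp + sum(stats::dexp(st$partRates, 1 / hyper$partMean, log = TRUE))
  if (relaxed) {
    s <- st$clockSd
    lp <- lp + stats::dexp(s, 1 / hyper$clockSdMean, log = TRUE)
    if (s > 0)
      lp <- lp + sum(stats::dlnorm(st$branchMult[st$multNodes],
        -s^2 / 2, s, log = TRUE))
    else if (any(st$branchMult[st$multNodes] != 1)) lp <- lp - Inf
  }
  lp
}

# UPGMA-style starting tree from Hamming distances between taxon rows;
# heights rescaled so the root sits at `rootTarget`. Tips must be extant
# (zero ages), else the caller falls back to a random start.
distanceStartTree <- function(states, rootTarget) {
  D <- matrix(0, nrow(states), nrow(states))
  for (i in seq_len(nrow(states) - 1))
    for (j in (i + 1):nrow(states)) {
      d <- abs(states[i, ] - states[j, ])
      D[i, j] <- D[j, i] <- mean(d, na.rm = TRUE) + 1e-6
    }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  n <- nrow(states)
  parent <- integer(2 * n - 1)
  ages <- numeric(2 * n - 1)
  h <- hc$height / max(hc$height) * rootTarget
  h <- cummax(h + seq_along(h) * 1e-9)  # strictly increasing ages
  for (k in seq_len(n - 1)) {
    nd <- n + k
    ages[nd] <- h[k]
    for (ch in hc$merge[k, ])
      parent[if (ch < 0) -ch else n + ch] <- nd
  }
  list(parent = parent, ages = ages)
}

# random calibration-compatible starting tree: sequential joins above the
# current lineage ages
randomStartTree <- function(nTip, tipAges, scale, rootMax) {
  parent <- integer(2 * nTip - 1)
  ages <- c(tipAges, numeric(nTip - 1))
  active <- seq_len(nTip)
  cur <- max(tipAges)
  for (k in seq_len(nTip - 1)) {
    nd <- nTip + k
    pick <- sample(length(active), 2)
    pr <- active[pick]
    cur <- max(cur, max(ages[pr])) + rexp(1, length(active) / scale)
    ages[nd] <- cur
    parent[pr] <- nd
    active <- c(active[-pick], nd)
  }
  if (ages[2 * nTip - 1] >= rootMax) return(NULL)
  list(parent = parent, ages = ages)
}

descendantsOf <- function(parent, v) {
  out <- v
  frontier <- v
  repeat {
    kids <- which(parent %in% frontier)
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Run the phylogenetic MCMC
#'
#' Samples from the posterior proportional to likelihood^beta x tree prior x
#' calibration prior x parameter priors, over tree topology, node ages (and
#' fossil tip ages when calibrated), the covarion parameters, the clock, the
#' partition rate multipliers and the birth-death parameters. Operators:
#' node-age slide, root-age scale, whole-tree scale, narrow exchange,
#' subtree-prune-regraft (age-windowed, Wilson-Balding style), fossil-tip age
#' moves, and multiplicative/reflected-walk parameter moves. Operator scales
#' adapt during burn-in only.
#'
#' @param m a \linkS4class{TraitMatrix}, or NULL for a data-free
#'   (prior-sampling) chain.
#' @param model initial \linkS4class{CovarionModel}.
#' @param clock a \linkS4class{ClockModel}; "relaxed" samples per-branch
#'   lognormal rate multipliers and their log-sd.
#' @param partition optional \linkS4class{PartitionScheme}; its multipliers
#'   are sampled (renormalised to character-weighted mean 1).
#' @param treePrior a \linkS4class{BirthDeathParams} (initial values;
#'   lambda/mu are sampled under diffuse exponential hyperpriors unless
#'   \code{hyper$estimateBD = FALSE}; rho and psi stay fixed).
#' @param calibrations list of \linkS4class{Calibration} hard bounds.
#' @param chainLength total MCMC steps.
#' @param sampleEvery thinning interval.
#' @param burninFraction fraction of the chain discarded (default 0.1).
#' @param seed integer seed (chain is fully reproducible given it).
#' @param beta power-posterior likelihood exponent (1 = posterior).
#' @param fixedTree optional \code{ape::phylo}: fixes topology and ages.
#' @param sampleSubstParams set FALSE to hold covarion parameters fixed.
#' @param freeParams which covarion parameters move (subset of
#'   "rate", "alpha", "switch", "pi"); e.g. \code{"rate"} alone gives the
#'   homogeneous-rate-only sampler used in the marginal-likelihood toys.
#' @param hyper named list overriding \code{rateMean, switchMean, lambdaMean,
#'   muMean, clockSdMean, partMean, rootMax, estimateBD}. \code{rootMax} is
#'   the upper bound of the uniform root-age prior.
#' @param checkEvery if > 0, recompute the cached posterior from scratch
#'   every that many steps and stop on disagreement beyond 1e-8 (consistency
#'   diagnostic).
#' @return A \linkS4class{PhyloPosterior}.
#' @export
runMcmc <- function(m, model = CovarionModel(), clock = ClockModel(),
    partition = NULL, treePrior = BirthDeathParams(), calibrations = list(),
    chainLength = 10000, sampleEvery = 10, burninFraction = 0.1,
    seed = 1, beta = 1, fixedTree = NULL, sampleSubstParams = !is.null(m),
    freeParams = c("rate", "alpha", "switch", "pi"),
    hyper = list(), checkEvery = 0) {
  if (chainLength < sampleEvery) stop("chain length must be >= thinning")
  hy <- defaultHyper()
  hy[names(hyper)] <- hyper
  set.seed(as.integer(seed))
  hasData <- !is.null(m)
  labels <- if (hasData) taxa(m) else attr(calibrations, "taxa")
  if (is.null(labels) && !is.null(fixedTree)) labels <- fixedTree$tip.label
  if (is.null(labels)) stop("taxon labels required (data or fixedTree or ",
    "attr(calibrations, 'taxa'))")
  n <- length(labels)
  relaxed <- clock@kind == "relaxed"
  nPart <- if (is.null(partition)) 1L else length(partition@groups)

  ## --- initial state -------------------------------------------------
  tipCal <- Filter(function(cc) cc@kind == "tip", calibrations)
  tipAges <- numeric(n)
  for (cc in tipCal)
    tipAges[match(cc@taxa, labels)] <- (cc@lower + cc@upper) / 2
  st <- NULL
  if (!is.null(fixedTree)) {
    tt <- ttreeFromPhylo(fixedTree, labels)
    st <- list(parent = tt$parent, ages = tt$ages)
  } else {
    if (hasData && all(tipAges == 0) && length(calibrations) == 0 && n > 2) {
      st <- tryCatch(distanceStartTree(traitStates(m), hy$rootMax / 5),
        error = function(e) NULL)
    }
    for (try in seq_len(100)) {
      if (!is.null(st)) break
      cand <- randomStartTree(n, tipAges,
        scale = max(hy$rootMax / 10, max(tipAges) * 2, 1e-3), hy$rootMax)
      if (is.null(cand)) next
      ok <- calibrationLogPriorArrays(cand$parent, cand$ages, labels,
        calibrations)
      if (is.finite(ok)) { st <- cand; break }
    }
    if (is.null(st))
      stop("initialisation failed: no calibration-compatible starting tree ",
        "found in 100 attempts")
  }
  N <- 2L * n - 1L
  st$rate <- model@overallRate
  st$alpha <- model@alpha
  st$switch <- model@switchRate
  st$piPresent <- model@freq[2]
  st$lambda <- treePrior@lambda
  st$mu <- treePrior@mu
  st$partRates <- rep(1, nPart)
  st$clockSd <- if (relaxed) max(clock@stdevLog, 0.1) else 0
  st$branchMult <- rep(1, N)
  st$multNodes <- integer(0)
  rootIdx <- function(s) which(s$parent == 0L)
  if (relaxed) st$multNodes <- setdiff(seq_len(N), rootIdx(st))

  pc <- if (hasData) partitionClasses(m, partition) else NULL
  tipStates <- if (hasData) traitStates(m) else NULL
  wts <- if (hasData) charWeights(m) else NULL

  bdK <- function(s) tryCatch(fbdConstantsNum(s$lambda, s$mu,
    treePrior@rho, treePrior@psi), error = function(e) NULL)

  eigCache <- new.env()
  eigCache$key <- NULL
  computeLik <- function(s) {
    if (!hasData) return(0)
    key <- c(s$piPresent, s$alpha, s$switch, s$rate)
    if (is.null(eigCache$key) || any(eigCache$key != key)) {
      cm <- CovarionModel(freq = c(1 - s$piPresent, s$piPresent),
        alpha = s$alpha, switchRate = s$switch, overallRate = s$rate)
      eigCache$eig <- covarionEigen(cm)
      eigCache$key <- key
    }
    eig <- eigCache$eig
    cr <- pc$classRate
    if (nPart > 1) {
      r <- s$partRates
      cr <- r / (sum(wts * r[pc$classOfChar]) / sum(wts))
    }
    mult <- s$branchMult
    ll <- .covarionPruning(s$parent, s$ages, n, mult, 1, tipStates,
      pc$classOfChar, cr, eig$values, eig$V, eig$Vinv, eig$pi)
    sum(wts * ll)
  }
  computePrior <- function(s) {
    ra <- s$ages[rootIdx(s)]
    if (ra > hy$rootMax) return(-Inf)
    lp <- calibrationLogPriorArrays(s$parent, s$ages, labels, calibrations)
    if (!is.finite(lp)) return(lp)
    lp <- lp + fbdLogDensityArrays(s$parent, s$ages, n, bdK(s)) -
      log(hy$rootMax)
    if (!is.finite(lp)) return(lp)
    lp + paramLogPrior(s, hy, relaxed, nPart)
  }

  ## --- operators -----------------------------------------------------
  scaleMove <- function(field, idx = NULL, lik = TRUE) function(s, delta) {
    f <- exp(delta * (runif(1) - 0.5))
    if (is.null(idx)) s[[field]] <- s[[field]] * f
    else {
      i <- if (length(idx) == 1) idx else sample(idx, 1)
      s[[field]][i] <- s[[field]][i] * f
    }
    list(s = s, logH = log(f), lik = lik)
  }
  reflect <- function(x, lo, hi) {
    while (x < lo || x > hi) {
      if (x < lo) x <- 2 * lo - x
      if (x > hi) x <- 2 * hi - x
    }
    x
  }
  slideMove <- function(field, lo, hi) function(s, delta) {
    s[[field]] <- reflect(s[[field]] + delta * (runif(1) - 0.5), lo, hi)
    list(s = s, logH = 0, lik = TRUE)
  }
  nodeSlide <- function(s, delta) {
    root <- rootIdx(s)
    cand <- setdiff((n + 1L):N, root)
    if (length(cand) == 0) return(NULL)
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    kids <- which(s$parent == i)
    lo <- max(s$ages[kids]); hi <- s$ages[s$parent[i]]
    if (hi <= lo) return(NULL)
    s$ages[i] <- runif(1, lo, hi)
    list(s = s, logH = 0, lik = TRUE)
  }
  rootScale <- function(s, delta) {
    root <- rootIdx(s)
    f <- exp(delta * (runif(1) - 0.5))
    newAge <- s$ages[root] * f
    kids <- which(s$parent == root)
    if (newAge <= max(s$ages[kids]) || newAge > hy$rootMax) return(NULL)
    s$ages[root] <- newAge
    list(s = s, logH = log(f), lik = TRUE)
  }
  treeScale <- function(s, delta) {
    f <- exp(delta * (runif(1) - 0.5))
    ints <- (n + 1L):N
    s$ages[ints] <- s$ages[ints] * f
    ch <- which(s$parent != 0L)
    if (any(s$ages[s$parent[ch]] < s$ages[ch])) return(NULL)
    if (s$ages[rootIdx(s)] > hy$rootMax) return(NULL)
    list(s = s, logH = length(ints) * log(f), lik = TRUE)
  }
  # ridge move: stretch the time scale while shrinking the clock rate, so
  # branch length x rate products (hence the likelihood, for extant tips)
  # stay put and the rate-depth ridge is traversed quickly
  rateTreeScale <- function(s, delta) {
    f <- exp(delta * (runif(1) - 0.5))
    ints <- (n + 1L):N
    s$ages[ints] <- s$ages[ints] * f
    s$rate <- s$rate / f
    ch <- which(s$parent != 0L)
    if (any(s$ages[s$parent[ch]] < s$ages[ch])) return(NULL)
    if (s$ages[rootIdx(s)] > hy$rootMax) return(NULL)
    list(s = s, logH = (length(ints) - 1) * log(f), lik = TRUE)
  }
  narrowExchange <- function(s, delta) {
    root <- rootIdx(s)
    cand <- setdiff((n + 1L):N, root)
    if (length(cand) == 0) return(NULL)
    v <- if (length(cand) == 1) cand else sample(cand, 1)
    u <- s$parent[v]
    sibs <- setdiff(which(s$parent == u), v)
    w <- if (length(sibs) == 1) sibs else sample(sibs, 1)
    kidsV <- which(s$parent == v)
    cc <- if (length(kidsV) == 1) kidsV else sample(kidsV, 1)
    if (s$ages[w] >= s$ages[v]) return(NULL)
    s$parent[cc] <- u
    s$parent[w] <- v
    list(s = s, logH = 0, lik = TRUE)
  }
  sprMove <- function(s, delta) {
    root <- rootIdx(s)
    v <- sample(setdiff(seq_len(N), root), 1)
    u <- s$parent[v]
    sibs <- setdiff(which(s$parent == u), v)
    w <- sibs[1]
    g <- s$parent[u]
    lenOld <- (if (g == 0L) hy$rootMax else s$ages[g]) -
      max(s$ages[w], s$ages[v])
    # detach
    sub <- descendantsOf(s$parent, v)
    if (g == 0L) { s$parent[w] <- 0L } else { s$parent[w] <- g }
    detRoot <- if (g == 0L) w else root
    candB <- setdiff(seq_len(N), c(sub, u))
    lows <- pmax(s$ages[candB], s$ages[v])
    upps <- rep(hy$rootMax, length(candB))   # detached-tree root gets the cap
    notRoot <- candB != detRoot
    upps[notRoot] <- s$ages[s$parent[candB[notRoot]]]
    feas <- which(upps > lows)
    if (length(feas) == 0) return(NULL)
    pick <- feas[sample(length(feas), 1)]
    b <- candB[pick]
    lenNew <- upps[pick] - lows[pick]
    newAge <- runif(1, lows[pick], upps[pick])
    s$parent[u] <- if (b == detRoot) 0L else s$parent[b]
    s$parent[b] <- u
    s$ages[u] <- newAge
    list(s = s, logH = log(lenNew) - log(lenOld), lik = TRUE)
  }
  fossilIdx <- which(tipAges > 0)
  fossilMove <- function(s, delta) {
    i <- if (length(fossilIdx) == 1) fossilIdx else sample(fossilIdx, 1)
    cc <- Filter(function(x) x@kind == "tip" &&
        match(x@taxa, labels) == i, tipCal)[[1]]
    newAge <- runif(1, cc@lower, cc@upper)
    if (newAge >= s$ages[s$parent[i]]) return(NULL)
    s$ages[i] <- newAge
    list(s = s, logH = 0, lik = TRUE)
  }

  ops <- list()
  addOp <- function(name, fn, weight, delta = 0.5, lik = TRUE) {
    ops[[length(ops) + 1]] <<- list(name = name, fn = fn, weight = weight,
      delta = delta, lik = lik)
  }
  if (is.null(fixedTree)) {
    addOp("nodeSlide", nodeSlide, 30)
    addOp("rootScale", rootScale, 10, delta = 0.8)
    addOp("treeScale", treeScale, 10, delta = 0.5)
    if (n > 2) {
      addOp("narrowExchange", narrowExchange, 15)
      addOp("spr", sprMove, 15)
    }
    if (length(fossilIdx) > 0) addOp("fossilAge", fossilMove, 5)
    if (hasData && sampleSubstParams && "rate" %in% freeParams)
      addOp("rateTreeScale", rateTreeScale, 15, delta = 0.7)
  }
  if (hasData && sampleSubstParams) {
    if ("rate" %in% freeParams) addOp("rate", scaleMove("rate"), 10,
      delta = 1)
    if ("alpha" %in% freeParams)
      addOp("alpha", slideMove("alpha", 1e-6, 1), 5, delta = 0.4)
    if ("switch" %in% freeParams)
      addOp("switch", scaleMove("switch"), 5, delta = 1)
    if ("pi" %in% freeParams)
      addOp("pi", slideMove("piPresent", 1e-4, 1 - 1e-4), 5, delta = 0.2)
  }
  if (hy$estimateBD) {
    addOp("lambda", scaleMove("lambda", lik = FALSE), 4, delta = 1)
    if (treePrior@mu > 0)
      addOp("mu", scaleMove("mu", lik = FALSE), 4, delta = 1)
  }
  if (nPart > 1)
    addOp("partRate", scaleMove("partRates", seq_len(nPart)), 10, delta = 0.8)
  if (relaxed) {
    addOp("clockSd", scaleMove("clockSd", lik = FALSE), 5, delta = 0.8)
    addOp("branchMult", scaleMove("branchMult", st$multNodes), 20, delta = 1)
  }
  wOp <- vapply(ops, `[[`, 0, "weight")
  pOp <- wOp / sum(wOp)
  deltas <- vapply(ops, `[[`, 0, "delta")
  nAcc <- nProp <- numeric(length(ops))

  curLik <- computeLik(st)
  curPrior <- computePrior(st)
  if (!is.finite(curPrior) || !is.finite(curLik))
    stop("zero-probability starting state")

  burnin <- as.integer(floor(chainLength * burninFraction))
  keepTrees <- list(); keepRows <- list()
  partNames <- if (nPart > 1) paste0("mult_", names(partition@groups)) else
    character(0)
  for (step in seq_len(chainLength)) {
    k <- sample.int(length(ops), 1, prob = pOp)
    prop <- ops[[k]]$fn(st, deltas[k])
    nProp[k] <- nProp[k] + 1
    if (!is.null(prop)) {
      newPrior <- computePrior(prop$s)
      if (is.finite(newPrior)) {
        newLik <- if (prop$lik && hasData) computeLik(prop$s) else curLik
        logAcc <- beta * (newLik - curLik) + newPrior - curPrior + prop$logH
        if (log(runif(1)) < logAcc) {
          st <- prop$s; curLik <- newLik; curPrior <- newPrior
          nAcc[k] <- nAcc[k] + 1
        }
      }
    }
    if (step <= burnin && nProp[k] %% 20 == 0) {   # burn-in-only adaptation
      rateAcc <- nAcc[k] / nProp[k]
      deltas[k] <- deltas[k] * exp(0.3 * (rateAcc - 0.3))
      deltas[k] <- min(max(deltas[k], 1e-3), 10)
    }
    if (checkEvery > 0 && step %% checkEvery == 0) {
      if (abs(computeLik(st) - curLik) > 1e-8 ||
          abs(computePrior(st) - curPrior) > 1e-8)
        stop("cached posterior disagrees with recomputation at step ", step)
    }
    if (step > burnin && step %% sampleEvery == 0) {
      keepTrees[[length(keepTrees) + 1]] <-
        arraysToPhylo(st$parent, st$ages, labels)
      row <- c(step = step, logPost = beta * curLik + curPrior,
        logLik = curLik, logPrior = curPrior, rate = st$rate,
        alpha = st$alpha, switch = st$switch, piPresent = st$piPresent,
        lambda = st$lambda, mu = st$mu, clockSd = st$clockSd,
        rootAge = st$ages[rootIdx(st)])
      if (nPart > 1) {
        r <- st$partRates
        nm <- if (hasData) r / (sum(wts * r[pc$classOfChar]) / sum(wts)) else
          r / mean(r)
        row <- c(row, setNames(nm, partNames))
      }
      keepRows[[length(keepRows) + 1]] <- row
    }
  }
  trace <- as.data.frame(do.call(rbind, keepRows))
  new("PhyloPosterior", trees = keepTrees, trace = trace,
    sampleEvery = as.integer(sampleEvery), burnin = burnin,
    seed = as.integer(seed),
    acceptance = setNames(ifelse(nProp > 0, nAcc / nProp, NA_real_),
      vapply(ops, `[[`, "", "name")))
}

#' Effective sample size of an MCMC trace
#'
#' Initial-positive-sequence estimator: autocovariances are summed over
#' consecutive lag pairs until a pair sum turns negative, and
#' \code{ESS = n / (1 + 2 sum(acf))}, capped at n. A constant trace triggers
#' a degeneracy warning and reports n.
#'
#' @param trace numeric vector, length >= 10.
#' @export
effectiveSampleSize <- function(trace) {
  nn <- length(trace)
  if (nn < 10) stop("trace too short (need >= 10)")
  v <- var(trace)
  if (v == 0 || !is.finite(v)) {
    warning("degenerate (constant) trace; reporting ESS = n")
    return(nn)
  }
  x <- trace - mean(trace)
  maxLag <- min(nn - 2, 2000)
  ac <- vapply(seq_len(maxLag), function(l)
    sum(x[1:(nn - l)] * x[(1 + l):nn]) / nn, 0) / (v * (nn - 1) / nn)
  s <- 0
  l <- 1
  while (l + 1 <= maxLag) {
    pairSum <- ac[l] + ac[l + 1]
    if (pairSum < 0) break
    s <- s + pairSum
    l <- l + 2
  }
  min(nn, nn / (1 + 2 * s))
}

# shortest interval containing prob mass of the sample
hpdInterval <- function(x, prob = 0.95) {
  x <- sort(x)
  nn <- length(x)
  m <- max(1L, ceiling(prob * nn))
  if (m >= nn) return(c(lower = x[1], upper = x[nn]))
  widths <- x[(m + 1):nn] - x[1:(nn - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Posterior MRCA age summaries for named clades
#'
#' For each named taxon set, takes the MRCA age in every sampled tree
#' (monophyly is not required: the MRCA is found per tree) and reports the
#' median, the 95\% HPD interval, and a kernel density grid.
#'
#' @param sample a \linkS4class{PhyloPosterior}.
#' @param clades named list of taxon-label vectors.
#' @param prob HPD mass (default 0.95).
#' @return Named list with \code{median}, \code{hpd}, \code{density},
#'   \code{ages} per clade.
#' @export
summariseAges <- function(sample, clades, prob = 0.95) {
  out <- lapply(clades, function(tps) {
    ages <- vapply(sample@trees, function(tr) mrcaAge(tr, tps), 0)
    dens <- if (length(unique(ages)) > 1) stats::density(ages) else NULL
    list(median = median(ages), hpd = hpdInterval(ages, prob),
      density = dens, ages = ages)
  })
  names(out) <- names(clades)
  out
}
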
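## Config-driven orchestration: simulate / infer / compare / bf stages over
## a single declarative YAML (or list) configuration. Every stochastic stage
## derives its stream from the config's root seed; calibrations declare
## their unit (CE or BP) explicitly and are converted at load time.

readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must set a root seed")
  config
}

configCalibrations <- function(entries, epoch = 1950) {
  lapply(entries, function(e) {
    lo <- as.numeric(e$lower); up <- as.numeric(e$upper)
    if (!is.null(e$unit) && toupper(e$unit) == "CE") {
      b <- sort(ceToBP(c(lo, up), epoch))
      lo <- b[1]; up <- b[2]
    }
    Calibration(kind = if (is.null(e$kind)) "mrca" else e$kind,
      taxa = unlist(e$taxa), lower = lo, upper = up)
  })
}

configModel <- function(mc) {
  if (is.null(mc)) return(CovarionModel())
  CovarionModel(
    freq = if (is.null(mc$freq)) c(0.5, 0.5) else unlist(mc$freq),
    alpha = if (is.null(mc$alpha)) 0.5 else mc$alpha,
    switchRate = if (is.null(mc$switch)) 0.5 else mc$switch,
    overallRate = if (is.null(mc$rate)) 1 else mc$rate)
}

configTreePrior <- function(tp) {
  if (is.null(tp)) return(BirthDeathParams())
  BirthDeathParams(
    lambda = if (is.null(tp$lambda)) 1 else tp$lambda,
    mu = if (is.null(tp$mu)) 0 else tp$mu,
    rho = if (is.null(tp$rho)) 1 else tp$rho,
    psi = if (is.null(tp$psi)) 0 else tp$psi)
}

levelPartition <- function(m) {
  if (is.null(charLevels(m))) stop("partition_by level needs level annotations")
  gr <- split(charIds(m), charLevels(m))
  new("PartitionScheme", name = "levels", groups = gr,
    rateMultipliers = setNames(rep(1, length(gr)), names(gr)))
}

#' Simulate a fixture bundle from a pipeline config
#'
#' Writes the simulated matrix (CSV + annotation CSV), the generating tree
#' (newick), the generating parameters (JSON) and a manifest with the seed
#' and per-file md5 checksums.
#'
#' @param config YAML path or list with blocks \code{seed} and
#'   \code{simulate} (n_extant, lambda, mu, rho, root_max, rate,
#'   chars_per_level, level_multipliers, fossil_windows, burst_fraction).
#' @param outputDir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
pipelineSimulate <- function(config, outputDir) {
  cfg <- readPipelineConfig(config)
  sc <- cfg$simulate
  if (is.null(sc)) stop("config lacks a simulate block")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))
  tp <- configTreePrior(sc)
  rootMax <- if (is.null(sc$root_max)) 10 else sc$root_max
  fw <- lapply(sc$fossil_windows, unlist)
  phy <- simulateTimeTree(sc$n_extant, tp, rootMax, fossilWindows = fw)
  counts <- unlist(sc$chars_per_level)
  if (is.null(counts)) counts <- c("1" = 100)
  mult <- unlist(sc$level_multipliers)
  if (is.null(mult)) mult <- setNames(rep(1, length(counts)), names(counts))
  model <- configModel(sc)
  f <- if (is.null(sc$burst_fraction)) 0 else sc$burst_fraction
  m <- simulatePunctuatedMatrix(phy, model, counts, mult,
    dependencies = isTRUE(sc$dependencies),
    categories = unlist(sc$categories), burstFraction = f)
  paths <- c(matrix = file.path(outputDir, "matrix.csv"),
    annotations = file.path(outputDir, "annotations.csv"),
    tree = file.path(outputDir, "true_tree.nwk"),
    params = file.path(outputDir, "params.json"))
  writeTraitMatrix(m, paths["matrix"], "csv",
    annotationPath = paths["annotations"])
  ape::write.tree(phy, paths["tree"])
  jsonlite::write_json(list(seed = cfg$seed, simulate = sc),
    paths["params"], auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = cfg$seed,
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
    auto_unbox = TRUE)
  invisible(manifest)
}

#' Run a configured inference and write its artefacts
#'
#' Reads the data matrix, assembles the model from the config (covarion
#' parameters, strict/relaxed clock, optional level- or category-based
#' partition, level weights, tree prior, CE/BP calibrations) and runs the
#' MCMC. Writes a tab-separated trace, a NEXUS tree log, the majority-rule
#' consensus (newick with percentage supports), an MRCA age-summary CSV for
#' any configured clades, and a JSON run log (seed, runtime, ESS with
#' low-ESS warnings).
#'
#' @param config YAML path or list with blocks \code{seed} and \code{infer}.
#' @param outputDir output directory.
#' @return Invisibly, the \linkS4class{PhyloPosterior}.
#' @export
pipelineInfer <- function(config, outputDir) {
  cfg <- readPipelineConfig(config)
  ic <- cfg$infer
  if (is.null(ic)) stop("config lacks an infer block")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  m <- readTraitMatrix(ic$data, annotations = ic$annotations)
  if (!is.null(ic$weights_by_level))
    m <- applyLevelWeights(m, setNames(unlist(ic$weights_by_level),
      names(ic$weights_by_level)))
  part <- switch(if (is.null(ic$partition_by)) "none" else ic$partition_by,
    none = NULL, level = levelPartition(m),
    stop("unknown partition_by: ", ic$partition_by))
  clock <- if (!is.null(ic$clock) && identical(ic$clock$kind, "relaxed"))
    ClockModel("relaxed", stdevLog = 0.3) else ClockModel()
  calibs <- configCalibrations(ic$calibrations)
  mc <- ic$mcmc
  hyper <- list()
  if (!is.null(ic$tree_prior$root_max)) hyper$rootMax <- ic$tree_prior$root_max
  t0 <- Sys.time()
  ps <- runMcmc(m, model = configModel(ic$model), clock = clock,
    partition = part, treePrior = configTreePrior(ic$tree_prior),
    calibrations = calibs,
    chainLength = if (is.null(mc$chain_length)) 10000 else mc$chain_length,
    sampleEvery = if (is.null(mc$sample_every)) 10 else mc$sample_every,
    seed = cfg$seed, hyper = hyper)
  runtime <- as.numeric(Sys.time() - t0, units = "secs")
  utils::write.table(ps@trace, file.path(outputDir, "trace.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  trees <- ps@trees
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = file.path(outputDir, "trees.nex"))
  cons <- majorityConsensus(ps@trees)
  ape::write.tree(cons, file.path(outputDir, "consensus.nwk"))
  if (!is.null(ic$clades)) {
    ag <- summariseAges(ps, lapply(ic$clades, unlist))
    df <- data.frame(clade = names(ag),
      median = vapply(ag, `[[`, 0, "median"),
      hpd_lower = vapply(ag, function(a) a$hpd[["lower"]], 0),
      hpd_upper = vapply(ag, function(a) a$hpd[["upper"]], 0))
    write.csv(df, file.path(outputDir, "ages.csv"), row.names = FALSE)
  }
  ess <- vapply(ps@trace[c("logLik", "rootAge", "rate")],
    effectiveSampleSize, 0)
  jsonlite::write_json(list(seed = cfg$seed, runtime_seconds = runtime,
    calibrations_bp = lapply(calibs, function(cc)
      list(taxa = cc@taxa, lower = cc@lower, upper = cc@upper)),
    ess = as.list(ess),
    warnings = if (any(ess < 200))
      paste("low ESS (<200) for:",
        paste(names(ess)[ess < 200], collapse = ", ")) else character(0)),
    file.path(outputDir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(ps)
}

readTreeLog <- function(path) {
  trees <- if (grepl("\\.(nex|nexus|trees)$", path, ignore.case = TRUE))
    ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(seq_along(trees), function(i) trees[[i]])  # uncompress tip labels
}

#' Cross-phylogeny congruence report
#'
#' Takes two posterior tree logs plus the two matrices and a taxon map, and
#' writes a JSON report with: the consensus-tree Mantel test, the
#' posterior-averaged Mantel test (n subsampled trees, depth-normalised),
#' and both Blomberg's K cross-mappings (PC1 of each dataset mapped onto the
#' other's posterior trees).
#'
#' @param config YAML path or list with blocks \code{seed} and
#'   \code{compare} (a_trees, b_trees, a_data, b_data, taxon_map,
#'   permutations, n_trees, normalise).
#' @param outputDir output directory.
#' @return Invisibly, the report list.
#' @export
pipelineCompare <- function(config, outputDir) {
  cfg <- readPipelineConfig(config)
  cc <- cfg$compare
  if (is.null(cc)) stop("config lacks a compare block")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  treesA <- readTreeLog(cc$a_trees)
  treesB <- readTreeLog(cc$b_trees)
  a <- readTraitMatrix(cc$a_data)
  b <- readTraitMatrix(cc$b_data)
  tm <- read.csv(cc$taxon_map)
  if (nrow(tm) < 4) stop("fewer than 4 shared taxa: congruence tests ",
    "are meaningless")
  mm <- matchSharedTaxa(a, b, tm)
  perms <- if (is.null(cc$permutations)) 999L else cc$permutations
  nTrees <- if (is.null(cc$n_trees)) min(1000L, length(treesA),
    length(treesB)) else cc$n_trees
  norm <- if (is.null(cc$normalise)) TRUE else isTRUE(cc$normalise)
  seed <- as.integer(cfg$seed)
  labA <- as.character(tm[[1]]); labB <- as.character(tm[[2]])
  consA <- majorityConsensus(treesA)
  consB <- majorityConsensus(treesB)
  DaC <- patristicMatrix(pruneTips(consA, labA), labA)
  DbC <- patristicMatrix(pruneTips(consB, labB), labB)
  mantelCons <- mantelTest(DaC, DbC, perms, seed)
  Da <- posteriorMeanDistances(treesA, labA, nTrees, norm, seed)
  Db <- posteriorMeanDistances(treesB, labB, nTrees, norm, seed + 1L)
  mantelPost <- mantelTest(Da, Db, perms, seed + 2L)
  pcA <- firstPrincipalComponent(mm$a)
  pcB <- firstPrincipalComponent(mm$b)
  # map each dataset's PC1 onto the other side's trees (shared taxa only)
  xbOnA <- setNames(as.numeric(pcB), labA)
  xaOnB <- setNames(as.numeric(pcA), labB)
  kBonA <- kOverPosterior(lapply(treesA, pruneTips, keep = labA), xbOnA,
    perms, seed + 3L, provenance = "PC1 of b on a-side trees")
  kAonB <- kOverPosterior(lapply(treesB, pruneTips, keep = labB), xaOnB,
    perms, seed + 4L, provenance = "PC1 of a on b-side trees")
  asM <- function(x) list(z = x@z, r = x@r, p = x@p,
    permutations = x@permutations, seed = x@seed)
  report <- list(seed = seed, shared_taxa = nrow(tm),
    mantel_consensus = asM(mantelCons),
    mantel_posterior = c(asM(mantelPost),
      list(n_trees = nTrees, normalised = norm)),
    k_b_on_a_trees = list(k_mean = kBonA@kMean, p = kBonA@p,
      n_trees = kBonA@nTrees, permutations = perms),
    k_a_on_b_trees = list(k_mean = kAonB@kMean, p = kAonB@p,
      n_trees = kAonB@nTrees, permutations = perms))
  jsonlite::write_json(report, file.path(outputDir, "congruence.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Shared-vs-separate phylogeny Bayes factor report
#'
#' Runs the three stepping-stone analyses (merged matrix; each matrix alone)
#' under identical settings and writes the marginal likelihoods with
#' standard errors, the log Bayes factor and its Kass-Raftery
#' interpretation.
#'
#' @param config YAML path or list with blocks \code{seed} and \code{bf}
#'   (a_data, b_data, taxon_map, model, tree_prior, calibrations, steps,
#'   chain_length).
#' @param outputDir output directory.
#' @return Invisibly, the \linkS4class{BayesFactorResult}.
#' @export
pipelineBayesFactor <- function(config, outputDir) {
  cfg <- readPipelineConfig(config)
  bc <- cfg$bf
  if (is.null(bc)) stop("config lacks a bf block")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  a <- readTraitMatrix(bc$a_data)
  b <- readTraitMatrix(bc$b_data)
  tm <- read.csv(bc$taxon_map)
  hyper <- list()
  if (!is.null(bc$tree_prior$root_max)) hyper$rootMax <- bc$tree_prior$root_max
  bf <- sharedTreeBayesFactor(a, b, tm, model = configModel(bc$model),
    clock = ClockModel(), treePrior = configTreePrior(bc$tree_prior),
    calibrations = configCalibrations(bc$calibrations),
    steps = if (is.null(bc$steps)) 16 else bc$steps,
    chainLength = if (is.null(bc$chain_length)) 2000 else bc$chain_length,
    seed = as.integer(cfg$seed), hyper = hyper)
  report <- list(seed = cfg$seed,
    model = "binary covarion, strict clock, homogeneous rate",
    log_ml_shared_A = bf@logMLA, sd_A = bf@sdA,
    log_ml_separate_B = bf@logMLB, sd_B = bf@sdB,
    log_ml_a = bf@logMLa, log_ml_b = bf@logMLb,
    log_bf = bf@logBF, interpretation = bf@interpretation)
  jsonlite::write_json(report, file.path(outputDir, "bayes_factor.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(bf)
}
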
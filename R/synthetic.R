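# Synthetic multitask benchmark generator. Emulates the structure of
# multi-source toxicity panels: several dataset pools, each with its own
# region of fingerprint bit-space and its own chemical list; tasks drawn
# from the same pool share chemicals (as endpoints assayed on one chemical
# list do), tasks from different pools share none. Labels derive from a
# latent projection of the bits shared by all tasks, so cross-task signal
# exists even when the pools are disjoint -- the regime stacked multitask
# learning targets.

#' Configuration for the synthetic multitask generator
#'
#' @param nTasks number of tasks.
#' @param chemicalsPerTask chemicals per task (chemicals are shared by all
#'   tasks of a pool).
#' @param featureLength fingerprint width.
#' @param poolStructure \code{"shared"} (one pool, all tasks on one
#'   chemical list), \code{"disjoint"} (\code{nPools} pools with disjoint
#'   chemical lists and distinct prototype bit regions), or \code{"mixed"}
#'   (a fraction of each task's chemicals drawn from a common pool).
#' @param nPools number of pools for \code{"disjoint"} (tasks are assigned
#'   round-robin; defaults to one pool per task).
#' @param overlapFraction for \code{"mixed"}: fraction of each task's
#'   chemicals shared by all tasks.
#' @param latentDim dimension of the latent projection the labels derive
#'   from.
#' @param rho task relatedness in [0, 1]: each task's latent weight vector
#'   is the unit-normalized \code{rho * wShared + (1 - rho) * wPrivate},
#'   so 1 means one shared labeling rule and 0 means independent rules.
#' @param labelNoise Bernoulli label-flip probability in [0, 0.5).
#' @param positiveFraction target positive fraction per task (scalar or
#'   length-\code{nTasks} vector); realized within one chemical of the
#'   target by quantile thresholding.
#' @param prototypeDensity density of set bits in a pool's prototype
#'   pattern.
#' @param bitFlip per-bit flip probability applied to the prototype to
#'   make each chemical.
#' @param epsilonSd sd of the Gaussian margin noise, relative to the
#'   within-task sd of the noiseless margin.
#' @param seed integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return a validated \code{generatorConfig} list.
#' @export
generatorConfig <- function(nTasks, chemicalsPerTask, featureLength = 1024L,
                            poolStructure = c("shared", "disjoint", "mixed"),
                            nPools = NULL, overlapFraction = 0.5,
                            latentDim = 16L, rho = 0.5, labelNoise = 0.1,
                            positiveFraction = 0.5,
                            prototypeDensity = 0.15, bitFlip = 0.1,
                            epsilonSd = 0.1, seed = 1L) {
  poolStructure <- match.arg(poolStructure)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (labelNoise < 0 || labelNoise >= 0.5)
    stop("labelNoise must lie in [0, 0.5)")
  pf <- rep_len(positiveFraction, nTasks)
  if (any(pf <= 0 | pf >= 1)) stop("positiveFraction must lie in (0, 1)")
  if (any(pmin(pf, 1 - pf) * chemicalsPerTask < 2))
    stop("infeasible positive fraction: fewer than 2 chemicals per class")
  if (is.null(nPools))
    nPools <- if (poolStructure == "disjoint") nTasks else 1L
  if (poolStructure == "disjoint" && nTasks %% nPools != 0L)
    stop("nTasks must be a multiple of nPools")
  list(nTasks = as.integer(nTasks),
       chemicalsPerTask = as.integer(chemicalsPerTask),
       featureLength = as.integer(featureLength),
       poolStructure = poolStructure, nPools = as.integer(nPools),
       overlapFraction = overlapFraction, latentDim = as.integer(latentDim),
       rho = rho, labelNoise = labelNoise, positiveFraction = pf,
       prototypeDensity = prototypeDensity, bitFlip = bitFlip,
       epsilonSd = epsilonSd, seed = as.integer(seed))
}

#' The canonical transfer benchmark configuration
#'
#' Eight tasks of 400 chemicals drawn from four disjoint pools (two tasks
#' per pool, sharing that pool's chemical list), 1024-bit fingerprints,
#' a 16-dimensional latent labeling rule, label-flip noise 0.1. \code{rho}
#' controls how much labeling rule the tasks share: 0.9 gives the transfer
#' regime, 0 the null control with independent task labels.
#'
#' @param rho task relatedness.
#' @param seed generator seed.
#' @return a \code{\link{generatorConfig}}.
#' @export
transferBenchmarkConfig <- function(rho = 0.9, seed = 7L) {
  generatorConfig(nTasks = 8L, chemicalsPerTask = 400L,
                  featureLength = 1024L, poolStructure = "disjoint",
                  nPools = 4L, latentDim = 16L, rho = rho,
                  labelNoise = 0.1, positiveFraction = 0.5, seed = seed)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic multitask benchmark
#'
#' Chemicals are binary fingerprint vectors built by flipping bits of a
#' per-pool prototype pattern, giving tunable Tanimoto separation between
#' pools. Each chemical's latent projection is \code{z = P x} for a fixed
#' sparse random matrix \code{P}; task t labels chemical i positive iff
#' \code{w_t . z_i + eps > tau_t}, where \code{w_t} blends a shared and a
#' private unit vector by \code{rho}, \code{eps} is Gaussian, and
#' \code{tau_t} is the margin quantile hitting the target positive
#' fraction. Finally labels flip independently with probability
#' \code{labelNoise}. Everything drawn is recorded in the ground-truth
#' object.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list: \code{tasks} (list of unsplit
#'   \code{\link{TaskDataset-class}}, grouped by pool), \code{groundTruth}
#'   (pools, prototypes, projection, weight vectors, thresholds, flip
#'   masks, the config).
#' @export
generateTasks <- function(config) {
  cfg <- config
  withSeed(cfg$seed, {
    m <- cfg$featureLength
    poolOfTask <- switch(cfg$poolStructure,
      shared = rep(1L, cfg$nTasks),
      disjoint = rep(seq_len(cfg$nPools), length.out = cfg$nTasks),
      mixed = seq_len(cfg$nTasks))
    nPools <- max(poolOfTask)
    prototypes <- matrix(stats::rbinom(nPools * m, 1L, cfg$prototypeDensity),
                         nrow = nPools)
    makeChems <- function(proto, n, idPrefix) {
      flips <- matrix(stats::rbinom(n * m, 1L, cfg$bitFlip), nrow = n)
      X <- abs(matrix(proto, n, m, byrow = TRUE) - flips)
      colnames(X) <- paste0("F", seq_len(m))
      rownames(X) <- NULL
      list(ids = paste0(idPrefix, "_C", seq_len(n)), X = X)
    }
    pools <- vector("list", nPools)
    shared <- NULL
    if (cfg$poolStructure == "mixed") {
      nShared <- round(cfg$overlapFraction * cfg$chemicalsPerTask)
      sharedProto <- stats::rbinom(m, 1L, cfg$prototypeDensity)
      shared <- makeChems(sharedProto, nShared, "S")
      for (p in seq_len(nPools))
        pools[[p]] <- makeChems(prototypes[p, ],
                                cfg$chemicalsPerTask - nShared,
                                paste0("P", p))
    } else {
      for (p in seq_len(nPools))
        pools[[p]] <- makeChems(prototypes[p, ], cfg$chemicalsPerTask,
                                paste0("P", p))
    }
    # sparse latent projection shared by all pools and tasks
    dens <- min(1, 32 / m)
    P <- matrix(stats::rnorm(cfg$latentDim * m) *
                  stats::rbinom(cfg$latentDim * m, 1L, dens),
                nrow = cfg$latentDim)
    unit <- function(v) v / sqrt(sum(v^2))
    wShared <- unit(stats::rnorm(cfg$latentDim))
    wPrivate <- replicate(cfg$nTasks, unit(stats::rnorm(cfg$latentDim)))
    tau <- numeric(cfg$nTasks)
    flips <- vector("list", cfg$nTasks)
    tasks <- vector("list", cfg$nTasks)
    for (t in seq_len(cfg$nTasks)) {
      p <- poolOfTask[t]
      ids <- pools[[p]]$ids; X <- pools[[p]]$X
      if (!is.null(shared)) {
        ids <- c(shared$ids, ids); X <- rbind(shared$X, X)
      }
      z <- P %*% t(X)                       # latentDim x n
      w <- unit(cfg$rho * wShared + (1 - cfg$rho) * wPrivate[, t])
      margin <- drop(w %*% z)
      margin <- margin + stats::rnorm(length(margin),
                                      sd = cfg$epsilonSd * stats::sd(margin))
      tau[t] <- stats::quantile(margin, 1 - cfg$positiveFraction[t],
                                names = FALSE)
      y <- as.integer(margin > tau[t])
      fl <- stats::rbinom(length(y), 1L, cfg$labelNoise) == 1L
      y[fl] <- 1L - y[fl]
      flips[[t]] <- fl
      tasks[[t]] <- taskDataset(paste0("task", t), ids, X, y,
                                group = paste0("pool", p))
    }
    names(tasks) <- vapply(tasks, taskName, character(1))
    list(tasks = tasks,
         groundTruth = list(poolOfTask = poolOfTask, prototypes = prototypes,
                            projection = P, wShared = wShared,
                            wPrivate = wPrivate, tau = tau,
                            flipMasks = flips, config = cfg))
  })
}

#' Split every task of a generated benchmark
#'
#' Applies \code{\link{stratifiedSplit}} to each task with per-task seeds
#' derived from one base seed, so tasks are split independently but the
#' whole benchmark is reproducible.
#'
#' @param tasks list of \code{\link{TaskDataset-class}} objects.
#' @param fractions train/validation/test fractions.
#' @param seed base seed; task i uses \code{seed + i}.
#' @return the task list with split tags.
#' @export
splitAllTasks <- function(tasks, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  out <- lapply(seq_along(tasks), function(i)
    stratifiedSplit(tasks[[i]], fractions, seed = seed + i))
  names(out) <- vapply(out, taskName, character(1))
  out
}

# Fixed list of common drug-like structures for round-trip fixtures.
# The generated binary fingerprints elsewhere in this module are NOT
# claimed to correspond to these molecules.
DRUGLIKE_SMILES <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  nicotine = "CN1CCCC1c1cccnc1",
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1",
  ethanol = "CCO",
  glycerol = "OCC(O)CO",
  acetone = "CC(=O)C",
  pyridine = "c1ccncc1",
  furan = "c1ccoc1",
  thiophene = "c1ccsc1",
  imidazole = "c1cnc[nH]1",
  indole = "c1ccc2[nH]ccc2c1",
  naphthalene = "c1ccc2ccccc2c1",
  quinoline = "c1ccc2ncccc2c1",
  benzamide = "NC(=O)c1ccccc1",
  benzoate = "OC(=O)c1ccccc1",
  salicylate = "OC(=O)c1ccccc1O",
  vanillin = "COc1cc(C=O)ccc1O",
  coumarin = "O=c1ccc2ccccc2o1",
  warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
  diazepam = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
  lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
  procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
  atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
  propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
  metformin = "CN(C)C(=N)NC(=N)N",
  valproate = "CCCC(CCC)C(=O)O",
  gabapentin = "NCC1(CC(=O)O)CCCCC1",
  ketamine = "CNC1(c2ccccc2Cl)CCCCC1=O",
  morphine = "CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5",
  codeine = "CN1CCC23c4c5ccc(OC)c4OC2C(O)C=CC3C1C5",
  dopamine = "NCCc1ccc(O)c(O)c1",
  serotonin = "NCCc1c[nH]c2ccc(O)cc12",
  histamine = "NCCc1c[nH]cn1",
  melatonin = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
  tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  tyrosine = "NC(Cc1ccc(O)cc1)C(=O)O",
  phenylalanine = "NC(Cc1ccccc1)C(=O)O",
  glucose = "OCC1OC(O)C(O)C(O)C1O",
  citrate = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
  urea = "NC(N)=O",
  thiourea = "NC(N)=S",
  cholesterol = "CC(C)CCCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C",
  testosterone = "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O"
)

#' Drug-like SMILES fixture rows
#'
#' A fixed, versioned list of real drug-like structures for exercising the
#' import/featurization path (round-trips, canonicalization, duplicate
#' detection) without external downloads.
#'
#' @param n number of rows (up to the list length).
#' @return data.frame with \code{chem_id} and \code{smiles}.
#' @export
smilesFixture <- function(n = length(DRUGLIKE_SMILES)) {
  n <- min(n, length(DRUGLIKE_SMILES))
  data.frame(chem_id = names(DRUGLIKE_SMILES)[seq_len(n)],
             smiles = unname(DRUGLIKE_SMILES[seq_len(n)]),
             stringsAsFactors = FALSE)
}
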
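# Shared fixtures: small generated benchmarks and reduced forest settings
# keep the unit tests fast; the acceptance tests use the full-size
# configurations.

smallParams <- forestParams(nTrees = 50L)

makeTinyBenchmark <- function(nTasks = 4L, n = 120L, m = 128L, rho = 0.9,
                              nPools = 2L, seed = 3L, splitSeed = 11L,
                              labelNoise = 0.1) {
  if (nTasks %% nPools != 0L) nPools <- nTasks
  cfg <- generatorConfig(nTasks = nTasks, chemicalsPerTask = n,
                         featureLength = m, poolStructure = "disjoint",
                         nPools = nPools, latentDim = 8L, rho = rho,
                         labelNoise = labelNoise, seed = seed)
  sim <- generateTasks(cfg)
  list(tasks = splitAllTasks(sim$tasks, seed = splitSeed), sim = sim)
}

# Random binary fingerprint matrix with reproducible contents.
randomBits <- function(n, m, density = 0.2, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- matrix(rbinom(n * m, 1L, density), n, m)
  colnames(X) <- paste0("F", seq_len(m))
  X
}

# Brute-force pairwise AUC oracle: all positive-negative pairs, half
# credit for ties.
bruteForceAUC <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force Tanimoto from explicit set arithmetic.
bruteForceTanimoto <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  u <- length(union(A, B))
  if (u == 0) 0 else length(intersect(A, B)) / u
}
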
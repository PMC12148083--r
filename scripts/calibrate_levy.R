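#!/usr/bin/env Rscript
## Calibrates the default Lévy exponent mu.
##
## The model constant anchored here is the mean number of realized steps
## per Lévy walk on an open uniform plain: the study design this package
## implements runs 400,000 walks per scenario producing ~830,000 steps on
## average, i.e. ~2.075 steps/walk.  With every other parameter at its
## default (lMin = 1, lMax = 100, memoryHorizon = 10000, new-territory
## doubling at 5/8 unvisited, doubling factor 2), mu is the single free
## scalar; this script bisects it so the simulated mean matches the target,
## and the result is frozen as PALEOWALK_DEFAULT_MU.
##
## Usage: Rscript scripts/calibrate_levy.R [--quick]

suppressMessages(library(paleowalk))

args <- commandArgs(trailingOnly = TRUE)
quick <- "--quick" %in% args
nWalks <- if (quick) 4000 else 10000
seeds <- if (quick) 1:6 else 1:12
target <- 830000 / 400000  # = 2.075 steps per walk

meanSteps <- function(mu) {
  cs <- makeUniformPlain(400)
  m <- vapply(seeds, function(s) {
    tr <- runScenario(cs, nWalks = nWalks, seed = s,
                      levy = LevyParams(mu = mu))
    nSteps(tr) / nWalks
  }, 0)
  mean(m)
}

lo <- 1.5; hi <- 12           # mean steps/walk decreases in mu
for (i in 1:18) {
  mid <- (lo + hi) / 2
  m <- meanSteps(mid)
  cat(sprintf("mu = %.4f  mean steps/walk = %.4f\n", mid, m))
  if (m > target) lo <- mid else hi <- mid
  if (abs(m - target) < 0.005 || (hi - lo) < 0.005) break
}
cat(sprintf("calibrated mu = %.3f (target %.3f steps/walk)\n",
            (lo + hi) / 2, target))
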
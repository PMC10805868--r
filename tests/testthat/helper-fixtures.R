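# Shared fixtures, built in code.

# Small deterministic two-site table with a known additive shift on site B.
toyShiftTable <- function(n = 30, V = 4, shift = 0.5, seed = 42) {
  set.seed(seed)
  age <- runif(2 * n, 20, 80)
  Y <- matrix(rnorm(2 * n * V, 0, 0.2), 2 * n, V)
  Y <- Y + outer(-0.01 * age, rep(1, V))
  Y[seq_len(n) + n, ] <- Y[seq_len(n) + n, ] + shift
  colnames(Y) <- paste0("f", seq_len(V))
  MultiSiteFeatures(Y, site = rep(c("A", "B"), each = n), age = age,
                    sex = rep_len(c("F", "M"), 2 * n))
}

# Simulation config with no injected site effect: additive effects off and
# multiplicative factors pinned at 1 (degenerate inverse-gamma with mean
# scale/(shape-1) = 1 and vanishing variance).
noSiteEffectConfig <- function(k = 3, nPerSite = 25, V = 11, seed = NA) {
  simConfig(k = k, nPerSite = nPerSite, V = V, gammaSD = 0,
            invGammaShapes = rep(1e6, k), invGammaScale = 1e6 - 1,
            seed = seed)
}

ageSpec <- function() covariateSpec(smoothTerms = "age",
                                    linearTerms = character(0))
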
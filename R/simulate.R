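#' Default per-site inverse-gamma shapes
#'
#' The study-design shape lists controlling the per-site residual scaling
#' factors of the simulator: larger shapes give scale factors concentrated
#' nearer `scale/(shape-1)`; smaller shapes give noisier sites. Exact lists
#' are defined for k = 3, 10 and 36 sites; other k require explicit shapes.
#'
#' @param k number of sites (3, 10 or 36).
#' @return numeric vector of length `k`.
#' @examples
#' defaultShapes(3)   # 46 51 56
#' length(defaultShapes(36))
#' @export
defaultShapes <- function(k) {
  switch(as.character(k),
         "3" = c(46, 51, 56),
         "10" = seq(40, 58, by = 2),
         "36" = c(seq(10, 40, by = 2), 41:50, seq(52, 70, by = 2)),
         stop("no default shapes for k = ", k,
              "; supply 'invGammaShapes' explicitly"))
}

#' Simulate a multisite feature table with known site effects
#'
#' Generates per-subject features
#' `y_ijf = alpha_f + beta1 * x_ij + beta2 * x_ij^2 + gamma_if +
#' delta_if * eps_ijf` for site i, subject j, feature f, where ages `x_ij`
#' are uniform on the configured range, additive site effects
#' `gamma_if ~ N(0, gammaSD^2)` and multiplicative site effects
#' `delta_if ~ InvGamma(shape_i, scale)` are drawn independently per
#' site-feature pair, and residuals are `N(0, noiseSD^2)`. A two-level sex
#' label is drawn uniformly (it carries no effect; it is present so the
#' table is a complete [MultiSiteFeatures-class]). Deterministic given the
#' seed.
#'
#' @param config a [SimConfig-class].
#' @param seed optional integer overriding `config@seed`; `NA` uses the
#'   current RNG state.
#' @return a [MultiSiteFeatures-class] with `metadata` entries
#'   `sim_gamma` and `sim_delta` (the drawn k x V site effect matrices) for
#'   downstream checks.
#' @examples
#' tab <- simulateMultisite(simConfig(k = 3, nPerSite = 25, seed = 7))
#' tab
#' @export
simulateMultisite <- function(config, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (is.null(seed)) seed <- config@seed
  if (!is.na(seed)) set.seed(as.integer(seed))
  k <- config@k; n <- config@nPerSite; V <- config@V
  N <- k * n
  siteNames <- sprintf("site%02d", seq_len(k))
  site <- factor(rep(siteNames, each = n), levels = siteNames)
  age <- runif(N, config@ageRange[1], config@ageRange[2])
  sex <- factor(sample(c("F", "M"), N, replace = TRUE))
  gamma <- matrix(rnorm(k * V, 0, config@gammaSD), k, V,
                  dimnames = list(siteNames, NULL))
  # delta ~ InvGamma(shape_i, scale): reciprocal of Gamma(shape_i, rate=scale)
  delta <- matrix(0, k, V, dimnames = list(siteNames, NULL))
  for (i in seq_len(k))
    delta[i, ] <- 1 / rgamma(V, shape = config@invGammaShapes[i],
                             rate = config@invGammaScale)
  eps <- matrix(rnorm(N * V, 0, config@noiseSD), N, V)
  ageEff <- config@beta1 * age + config@beta2 * age^2
  idx <- as.integer(site)
  Y <- matrix(config@alpha, N, V, byrow = TRUE) +
    matrix(ageEff, N, V) +
    gamma[idx, , drop = FALSE] +
    delta[idx, , drop = FALSE] * eps
  colnames(Y) <- sprintf("%s_region%02d", config@featureType, seq_len(V))
  colnames(gamma) <- colnames(Y)
  colnames(delta) <- colnames(Y)
  out <- MultiSiteFeatures(Y, site = site, age = age, sex = sex,
                           featureGroup = config@featureType)
  metadata(out)$sim_gamma <- gamma
  metadata(out)$sim_delta <- delta
  metadata(out)$sim_config <- config
  out
}

#' Read a simulation configuration from YAML
#'
#' Mirror of [simConfig()] for file-driven runs: recognized keys are the
#' constructor arguments (`k`, `nPerSite`, `V`, `featureType`, `alpha`,
#' `beta1`, `beta2`, `ageRange`, `gammaSD`, `invGammaShapes`,
#' `invGammaScale`, `noiseSD`, `seed`); omitted keys keep their defaults.
#' Requires the yaml package.
#'
#' @param path YAML file path.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(simConfig, raw)
}
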
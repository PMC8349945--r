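# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Stack from per-b signal arrays (scalars are broadcast to `dm`).
makeStack <- function(s0, s50, s800, dm = c(2, 2, 1), extra = NULL) {
  bcast <- function(x) if (length(x) == 1L) array(x, dm) else array(x, dm)
  b <- c(0, 50, 800)
  vols <- list(bcast(s0), bcast(s50), bcast(s800))
  if (!is.null(extra)) {          # e.g. extra = list(`250` = vol)
    b <- c(b, as.numeric(names(extra)))
    vols <- c(vols, lapply(extra, bcast))
    o <- order(b)
    b <- b[o]; vols <- vols[o]
  }
  new("DWIStack", bValues = b, volumes = vols)
}

makeParamMap <- function(values, kind = "Dprime", valid = NULL,
                         dm = NULL) {
  if (is.null(dm)) dm <- if (is.null(dim(values))) c(length(values), 1, 1)
                         else dim(values)
  v <- array(values, dm)
  if (is.null(valid)) valid <- array(TRUE, dm)
  new("ParameterMap", kind = kind, values = v, valid = array(valid, dm))
}

# Uniform-parameter scene (single "liver" region) for noise-model tests.
constScene <- function(dm, S0 = 1000, D = 1e-3, f = 0.1, Dstar = 50e-3) {
  a <- function(x) array(x, dm)
  new("PhantomScene", labels = a(1L), S0 = a(S0), D = a(D), f = a(f),
      Dstar = a(Dstar),
      lesionTable = data.frame(lesion_id = character(), class = character(),
                               label = integer(), x = numeric(),
                               y = numeric(), z = numeric(),
                               radius = numeric(), n_voxels = integer(),
                               D = numeric(), f = numeric(),
                               Dstar = numeric(), malignant = logical(),
                               has_core = logical()),
      spacing = c(1, 1, 1))
}

# Independent AUC oracle: exhaustive pair enumeration of the
# Mann-Whitney statistic, ties counting 1/2.
aucByPairs <- function(values, labels, direction) {
  s <- if (direction == "lower_is_positive") -values else values
  pos <- s[labels]; neg <- s[!labels]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# Independent Youden oracle: brute-force J over every observed value +/- eps.
youdenByGrid <- function(values, labels, direction) {
  eps <- min(diff(sort(unique(values)))) / 4
  if (!is.finite(eps)) eps <- 1e-6
  cand <- sort(unique(c(values - eps, values + eps, -Inf, Inf)))
  callPos <- function(t) if (direction == "lower_is_positive")
    values < t else values > t
  best <- -Inf
  for (t in cand) {
    p <- callPos(t)
    J <- mean(p[labels]) + mean(!p[!labels]) - 1
    if (J > best) best <- J
  }
  best
}

separableConfig <- function(seed = 11) {
  cfg <- defaultRunConfig(seed)
  cfg$mode <- "fully_dephased"
  cfg$scene$dim <- c(48, 48, 12)
  cfg$scene$lesions <- list(
    list(class = "HCC", radius = 4),
    list(class = "metastasis_CRC", radius = 3),
    list(class = "haemangioma", radius = 4),
    list(class = "FNH", radius = 3))
  # zero-SD classes: every malignant lesion sits below both cutoffs,
  # every benign lesion violates exactly one
  cfg$scene$specs_overrides <- list(
    HCC = list(D_mean = 1000e-6, D_sd = 0, f_mean = 50e-3, f_sd = 0),
    metastasis_CRC = list(D_mean = 1100e-6, D_sd = 0,
                          f_mean = 60e-3, f_sd = 0),
    haemangioma = list(D_mean = 2000e-6, D_sd = 0,
                       f_mean = 50e-3, f_sd = 0),
    FNH = list(D_mean = 1000e-6, D_sd = 0, f_mean = 200e-3, f_sd = 0))
  cfg$scene$within_lesion_cv <- 0.02
  cfg
}
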
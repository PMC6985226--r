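#' Simulation configuration
#'
#' Generating conditions for synthetic item panels and volumes. Defaults
#' emulate a large three-occasion adolescent personality panel: 1808
#' participants at baseline thinning to 1414 and 1282 through three dropout
#' patterns (after baseline, after the second occasion, and intermittent
#' with return), a one-factor 12-item measurement model whose occasion-1
#' standardized loadings match the reference loading profile, five items
#' with drifted (non-invariant) intercepts, linear latent growth with a
#' negative intercept-slope correlation, covariate effects dominated by
#' sex, and small smoothed volumes with a spherical region coupled to the
#' individual latent slope.
#'
#' @param n baseline sample size.
#' @param occasionCounts observed participants per occasion (non-increasing).
#' @param intermittentReturn participants missing occasion 2 but returning
#'   at occasion 3 (resolves the dropout-pattern split).
#' @param loadingsT1 target occasion-1 standardized loadings (length =
#'   items); raw loadings are these rescaled to mean 1 (effects coding).
#' @param itemIntercepts item intercept deviations (sum 0).
#' @param driftItems item indices with non-invariant intercepts.
#' @param driftMagnitude intercept drift (response-scale units) applied at
#'   occasions 2 and 3 with alternating sign across the drifted items.
#' @param iceptMean,iceptSD,slopeMean,slopeSD,isCor growth-factor moments.
#' @param basis slope basis per occasion.
#' @param disturbanceSD occasion-specific latent disturbance SD.
#' @param covariates generate covariates (sex, age, site, puberty,
#'   depression)?
#' @param sexEffect,depressionEffect,pubertyEffect,ageEffect named
#'   `c(icept=, slope=)` raw effects on the growth factors.
#' @param pFemale probability of the female dummy.
#' @param nSites scanner sites (dummy-coded against site 1 downstream).
#' @param siteEffects matrix `nSites x 2` of per-site offsets (icept,
#'   slope); default zero.
#' @param discretize round responses onto the 1-5 Likert grid (default
#'   FALSE so continuous-data estimators are exactly correctly specified).
#' @param grid,voxelSizeMm,fwhmMm,backgroundMean,backgroundNoiseSD volume
#'   field parameters.
#' @param maskRadiusVox spherical mask radius (voxels).
#' @param effectCenter,effectRadiusVox,coupling,effectNoiseSD effect-region
#'   parameters; voxel values inside the region gain
#'   `coupling * slope + noise`.
#' @param seed integer seed.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n = 1808L,
                      occasionCounts = c(1808L, 1414L, 1282L),
                      intermittentReturn = 100L,
                      loadingsT1 = c(0.28, 0.59, 0.59, 0.50, 0.59, 0.71,
                                     0.49, 0.44, 0.59, 0.47, 0.62, 0.49),
                      itemIntercepts = NULL,
                      driftItems = c(2L, 4L, 7L, 8L, 12L),
                      driftMagnitude = 0.3,
                      iceptMean = 2.8, iceptSD = 0.8,
                      slopeMean = -0.21, slopeSD = 0.30, isCor = -0.2,
                      basis = c(0, 0.5, 1),
                      disturbanceSD = 0.25,
                      covariates = TRUE,
                      sexEffect = c(icept = 0.48, slope = 0.096),
                      depressionEffect = c(icept = 0.24, slope = -0.036),
                      pubertyEffect = c(icept = 0.016, slope = -0.018),
                      ageEffect = c(icept = 0, slope = 0),
                      pFemale = 0.511,
                      nSites = 9L,
                      siteEffects = NULL,
                      discretize = FALSE,
                      grid = c(20L, 20L, 20L),
                      voxelSizeMm = 2,
                      fwhmMm = 8,
                      backgroundMean = 0.4,
                      backgroundNoiseSD = 0.1,
                      maskRadiusVox = 8.5,
                      effectCenter = c(10.5, 10.5, 10.5),
                      effectRadiusVox = 4,
                      coupling = 0.5,
                      effectNoiseSD = 0.05,
                      seed = 1L) {
  p <- length(loadingsT1)
  if (is.null(itemIntercepts)) {
    itemIntercepts <- seq(-0.55, 0.55, length.out = p)
    itemIntercepts <- itemIntercepts - mean(itemIntercepts)
  }
  if (abs(sum(itemIntercepts)) > 1e-8) stop("itemIntercepts must sum to zero")
  if (is.null(siteEffects)) siteEffects <- matrix(0, nSites, 2)
  if (any(diff(occasionCounts) > 0))
    stop("occasionCounts must be non-increasing")
  if (any(c(iceptSD, slopeSD, disturbanceSD, backgroundNoiseSD) <= 0))
    stop("all SDs must be positive")
  if (effectRadiusVox < 0) stop("effect radius must be non-negative")
  cfg <- as.list(environment())
  cfg$nItems <- p
  cfg$nOccasions <- length(basis)
  structure(cfg, class = "SimConfig")
}

## dropout pattern sizes from the occasion counts
.dropoutSplit <- function(cfg) {
  n1 <- cfg$occasionCounts[1]; n2 <- cfg$occasionCounts[2]; n3 <- cfg$occasionCounts[3]
  i <- cfg$intermittentReturn
  completers <- n3 - i
  dropAfter2 <- n2 - completers
  dropAfter1 <- n1 - n2 - i
  sizes <- c(completers = completers, dropAfter1 = dropAfter1,
             dropAfter2 = dropAfter2, intermittent = i)
  if (any(sizes < 0) || sum(sizes) != n1)
    stop("infeasible dropout pattern for the given occasion counts")
  sizes
}

#' Generate a synthetic item panel
#'
#' Draws latent growth factors from a bivariate normal, adds covariate
#' effects, builds occasion factor scores through the slope basis plus
#' disturbances, and emits item responses `tau + drift + lambda * eta +
#' residual`. Residual SDs are chosen so each item's occasion-1
#' standardized loading equals the configured profile. Dropout is assigned
#' completely at random within the configured pattern sizes.
#'
#' @param cfg a [simConfig()].
#' @return an [ItemPanel-class]; `meta$truth` records every generating
#'   value, the per-participant latent factors and the dropout pattern.
#' @export
genItemPanel <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n; p <- cfg$nItems; noc <- cfg$nOccasions
  lam <- cfg$loadingsT1 / mean(cfg$loadingsT1)

  ## covariates
  cov <- NULL
  effI <- rep(0, n); effS <- rep(0, n)
  if (cfg$covariates) {
    sex <- rbinom(n, 1, cfg$pFemale)
    ageZ <- rnorm(n)
    site <- factor(paste0("site", sample.int(cfg$nSites, n, replace = TRUE)),
                   levels = paste0("site", seq_len(cfg$nSites)))
    puberty <- rnorm(n)
    depression <- rnorm(n)
    effI <- sex * cfg$sexEffect["icept"] + ageZ * cfg$ageEffect["icept"] +
      puberty * cfg$pubertyEffect["icept"] + depression * cfg$depressionEffect["icept"] +
      cfg$siteEffects[as.integer(site), 1]
    effS <- sex * cfg$sexEffect["slope"] + ageZ * cfg$ageEffect["slope"] +
      puberty * cfg$pubertyEffect["slope"] + depression * cfg$depressionEffect["slope"] +
      cfg$siteEffects[as.integer(site), 2]
    cov <- data.frame(sex = sex, age = ageZ, site = site,
                      puberty = puberty, depression = depression)
  }

  ## latent growth factors (residual part) + covariate contributions
  z1 <- rnorm(n); z2 <- rnorm(n)
  icept <- cfg$iceptMean + effI + cfg$iceptSD * z1
  slope <- cfg$slopeMean + effS +
    cfg$slopeSD * (cfg$isCor * z1 + sqrt(1 - cfg$isCor^2) * z2)

  eta <- sapply(seq_len(noc), function(t)
    icept + cfg$basis[t] * slope + rnorm(n, 0, cfg$disturbanceSD))

  ## residual SDs hit the target occasion-1 standardized loadings
  sdEta1 <- sqrt(cfg$iceptSD^2 + cfg$disturbanceSD^2 +
                   2 * cfg$basis[1] * cfg$isCor * cfg$iceptSD * cfg$slopeSD +
                   cfg$basis[1]^2 * cfg$slopeSD^2)
  residSD <- lam * sdEta1 * sqrt(1 / cfg$loadingsT1^2 - 1)

  drift <- matrix(0, p, noc)
  if (length(cfg$driftItems) && cfg$driftMagnitude != 0) {
    signs <- rep(c(1, -1), length.out = length(cfg$driftItems))
    for (k in seq_along(cfg$driftItems))
      drift[cfg$driftItems[k], -1] <- cfg$driftMagnitude * signs[k]
  }

  Y <- matrix(NA_real_, n, p * noc)
  for (t in seq_len(noc)) {
    E <- matrix(rnorm(n * p), n, p) * rep(residSD, each = n)
    Y[, (t - 1) * p + seq_len(p)] <-
      rep(cfg$itemIntercepts + drift[, t], each = n) +
      outer(eta[, t], lam) + E
  }
  if (cfg$discretize) Y <- pmin(pmax(round(Y), 1), 5)

  ## dropout assignment (MCAR within occasion-pattern sizes)
  sizes <- .dropoutSplit(cfg)
  perm <- sample.int(n)
  pattern <- rep(names(sizes), sizes)[order(perm)]
  occCols <- function(t) (t - 1) * p + seq_len(p)
  if (noc >= 2) {
    Y[pattern %in% c("dropAfter1", "intermittent"), occCols(2)] <- NA
    if (noc >= 3)
      Y[pattern %in% c("dropAfter1", "dropAfter2"), occCols(3)] <- NA
  }

  truth <- list(config = unclass(cfg), lambda = lam, residSD = residSD,
                drift = drift, icept = icept, slope = slope, eta = eta,
                pattern = pattern)
  ItemPanel(Y, covariates = cov, nItems = p, nOccasions = noc,
            meta = list(truth = truth))
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Normalized separable Gaussian kernel (`sigma = FWHM / 2.3548 /
#' voxelSize`), half-sample reflective boundary; preserves the volume sum.
#' `fwhmMm = 0` returns the input unchanged.
#'
#' @param vol 3D numeric array.
#' @param fwhmMm smoothing kernel FWHM in mm.
#' @param voxelSizeMm isotropic voxel size in mm.
#' @return smoothed array of the same dimension.
#' @export
gaussianSmooth3d <- function(vol, fwhmMm, voxelSizeMm = 2) {
  if (fwhmMm == 0) return(vol)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-0.5 * ((-r:r) / sigma)^2)
  kern <- kern / sum(kern)
  dm <- dim(vol)
  if (any(r >= dm)) stop("smoothing kernel larger than the grid")
  smooth1 <- function(x, axis) {
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(x, perm)
    d <- dim(a)
    mat <- matrix(a, d[1], d[2] * d[3])
    n <- d[1]
    padded <- rbind(mat[r:1, , drop = FALSE], mat, mat[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (k in seq_len(2 * r + 1))
      out <- out + kern[k] * padded[(k - 1) + seq_len(n), , drop = FALSE]
    aperm(array(out, d), order(perm))
  }
  for (ax in 1:3) vol <- smooth1(vol, ax)
  vol
}

#' Generate synthetic volumes
#'
#' Per participant: a smooth random background field (Gaussian smoothing at
#' the configured FWHM) within a spherical mask, plus, inside the effect
#' region, `coupling * slope + local noise`.
#'
#' @param cfg a [simConfig()].
#' @param slopes per-participant latent slopes (ground truth from
#'   [genItemPanel()], or any numeric vector).
#' @param seed seed (default derived from the config seed).
#' @return list: `volumes` (4D array, participants last), `mask` (3D
#'   logical), `affine` (1-based voxel-to-world, grid-centred), `truth`
#'   (3D logical effect-region membership), `config`.
#' @export
genVolumes <- function(cfg, slopes, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(seed)
  dm <- cfg$grid
  n <- length(slopes)
  ctr <- (dm + 1) / 2
  coords <- arrayInd(seq_len(prod(dm)), dm)
  distCtr <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  mask <- array(distCtr <= cfg$maskRadiusVox, dm)
  distEff <- sqrt(rowSums(sweep(coords, 2, cfg$effectCenter)^2))
  region <- array(distEff <= cfg$effectRadiusVox, dm)
  if (!any(region & mask) && cfg$effectRadiusVox > 0)
    stop("effect region lies outside the grid/mask")
  vols <- array(0, c(dm, n))
  regIdx <- which(region)
  for (i in seq_len(n)) {
    field <- cfg$backgroundMean +
      gaussianSmooth3d(array(rnorm(prod(dm), 0, cfg$backgroundNoiseSD), dm),
                       cfg$fwhmMm, cfg$voxelSizeMm)
    if (length(regIdx) && cfg$coupling != 0)
      field[regIdx] <- field[regIdx] + cfg$coupling * slopes[i]
    if (length(regIdx) && cfg$effectNoiseSD > 0)
      field[regIdx] <- field[regIdx] + rnorm(length(regIdx), 0, cfg$effectNoiseSD)
    vols[, , , i] <- field
  }
  affine <- diag(c(rep(cfg$voxelSizeMm, 3), 1))
  affine[1:3, 4] <- -cfg$voxelSizeMm * ctr
  list(volumes = vols, mask = mask, affine = affine, truth = region,
       config = cfg)
}

#' Write synthetic volumes to NIfTI
#'
#' One 4D volume file, a mask, and a participant-order sidecar TSV.
#'
#' @param gen result of [genVolumes()].
#' @param dir output directory.
#' @param ids participant identifiers for the sidecar.
#' @return invisibly, the written paths.
#' @export
writeVolumes <- function(gen, dir, ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff0 <- gen$affine
  aff0[1:3, 4] <- aff0[1:3, 4] + aff0[1:3, 1:3] %*% rep(1, 3)
  wr <- function(arr, nm) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(aff0, code = 2L))
    pth <- file.path(dir, nm)
    RNifti::writeNifti(img, pth)
    pth
  }
  p1 <- wr(gen$volumes, "volumes4d.nii")
  p2 <- wr(gen$mask + 0, "mask.nii")
  if (is.null(ids)) ids <- as.character(seq_len(dim(gen$volumes)[4]))
  p3 <- file.path(dir, "participants.tsv")
  utils::write.table(data.frame(order = seq_along(ids), id = ids),
                     p3, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a 4D volume stack and mask written by [writeVolumes()]
#'
#' @param dir directory containing `volumes4d.nii`, `mask.nii`,
#'   `participants.tsv`.
#' @return list `volumes`, `mask`, `affine` (1-based convention), `ids`.
#' @export
readVolumes <- function(dir) {
  img <- RNifti::readNifti(file.path(dir, "volumes4d.nii"))
  msk <- RNifti::readNifti(file.path(dir, "mask.nii"))
  aff0 <- RNifti::xform(img)
  aff <- unclass(aff0)
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  ids <- utils::read.delim(file.path(dir, "participants.tsv"))$id
  list(volumes = unclass(as.array(img)), mask = array(as.array(msk) > 0.5, dim(msk)),
       affine = unname(aff), ids = as.character(ids))
}
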
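#' @rdname StatMap-class
#' @export
setMethod("maskArray", "StatMap", function(object) object@mask)

setMethod("show", "StatMap", function(object) {
  nm <- sum(object@mask)
  cat(sprintf("StatMap (%s): grid %s, %d in-mask voxels\n",
              object@meta$target %||% "?",
              paste(dim(object@mask), collapse = "x"), nm))
  cat(sprintf("  convergence rate: %.3f; mode: %s\n",
              object@meta$convergenceRate %||% NA,
              object@meta$mode %||% "?"))
  if (!is.null(object@meta$multiplicity))
    cat(" ", object@meta$multiplicity, "\n")
  invisible(object)
})

#' Voxel index to world coordinates
#'
#' Applies the affine to homogeneous 1-based voxel indices.
#'
#' @param index numeric length-3 vector or 3-column matrix of voxel indices.
#' @param affine 4x4 matrix (must be invertible).
#' @return world mm coordinates (vector or matrix matching the input).
#' @export
voxelToWorld <- function(index, affine) {
  if (abs(det(affine)) < 1e-12) stop("singular affine")
  single <- is.null(dim(index))
  idx <- if (single) matrix(index, 1) else as.matrix(index)
  out <- t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  if (single) drop(out) else out
}

#' @rdname voxelToWorld
#' @param world world-mm coordinates.
#' @export
worldToVoxel <- function(world, affine) {
  voxelToWorld(world, solve(affine))
}

## Rebuild the measurement spec recorded in an LGCM's metadata.
.rebuildMI <- function(meta) {
  ms <- meta$measurement; g <- meta$geometry
  if (ms$intercepts == "partial" && length(ms$freedItems)) {
    partialStrongSpec(ms$freedItems, g$nItems, g$nOccasions, ms$residualLagCov)
  } else {
    .buildMeasurementSpec(g$nItems, g$nOccasions, "shared", "shared",
                          residualLagCov = ms$residualLagCov)
  }
}

#' Map a voxel-wise predictor of latent growth
#'
#' For every in-mask voxel, inserts the (per-voxel standardized) voxel
#' values as an exogenous predictor of the latent slope (or intercept) in
#' the base growth model, refits by FIML warm-started from the base fit,
#' and collects the path coefficient, Wald z and two-sided p into 3D maps.
#' `fixed_measurement` freezes loadings, intercepts and residual structure
#' at the base solution and refits only the structural block (fast,
#' approximation contract: agrees with `full_refit` on sign and closely on
#' z for well-separated effects); `full_refit` frees all parameters.
#' No multiple-comparison correction is applied; this is recorded loudly in
#' the map metadata.
#'
#' @param panel an [ItemPanel-class].
#' @param volumes 4D numeric array, last dimension participants (aligned
#'   with `panel`; see `participantIds`).
#' @param mask 3D logical array.
#' @param baseSpec LGCM specification from [buildLGCM()] (without the voxel).
#' @param target `"slope"` or `"intercept"`.
#' @param mode `"fixed_measurement"` or `"full_refit"`.
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @param participantIds optional ids for the 4th dimension; must equal
#'   `panel@ids` (hard error otherwise).
#' @param standardizeVoxels standardize each voxel across participants
#'   before insertion (default TRUE; scale-comparable betas).
#' @param pReference reference distribution for the two-sided p values:
#'   `"t"` (default; Student t with `N - q` degrees of freedom, `q` the
#'   number of free parameters -- finite-sample Wald calibration) or
#'   `"normal"`.
#' @param seed recorded in metadata; used for optimizer restarts.
#' @return a [StatMap-class].
#' @export
mapVoxelPredictor <- function(panel, volumes, mask, baseSpec,
                              target = c("slope", "intercept"),
                              mode = c("fixed_measurement", "full_refit"),
                              affine = diag(4), participantIds = NULL,
                              standardizeVoxels = TRUE,
                              pReference = c("t", "normal"), seed = 1L) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  pReference <- match.arg(pReference)
  dm <- dim(volumes)
  if (length(dm) != 4) stop("volumes must be a 4D array")
  N <- nrow(responses(panel))
  if (dm[4] != N)
    stop(sprintf("ID mismatch: volumes carry %d participants, panel has %d", dm[4], N))
  if (!is.null(participantIds) && !identical(as.character(participantIds), panel@ids))
    stop("ID mismatch: participant order of volumes does not match the panel")
  if (!any(mask)) stop("mask is empty")
  meta <- baseSpec@meta
  if (is.null(meta$growth)) stop("baseSpec must come from buildLGCM()")

  ## base fit (no voxel)
  baseFit <- fitML(baseSpec, panel, se = "none", seed = seed)
  if (!baseFit@converged) stop("base model did not converge")

  ## voxel-augmented spec, with placeholder voxel moments
  covs <- meta$covariates %||% character()
  panelV <- panel
  vcolName <- ".voxel"
  panelV@covariates[[vcolName]] <- rep(0, N)
  mi <- .rebuildMI(meta)
  specV <- buildLGCM(mi, meta$growth, covariates = covs, panel = panelV,
                     predictor = vcolName, predictorTarget = target)
  thetaV <- .embedTheta(specV, baseSpec, baseFit@theta)
  pathLab <- sprintf("b_%s_%s", vcolName, if (target == "slope") "slope" else "icept")
  pathIdx <- match(pathLab, specV@labels)
  if (is.na(pathIdx)) stop("internal: voxel path label not found")

  if (mode == "fixed_measurement") {
    fixedMats <- c("Lambda", "Tau", "Theta")
    builtV <- .buildMats(specV, thetaV)
    keep <- !(specV@assign$mat %in% fixedMats)
    keepLabs <- sort(unique(specV@assign$lab[keep]))
    specF <- specV
    for (mname in fixedMats) specF@mats[[mname]] <- .unsym(builtV[[mname]], mname)
    specF@assign <- specV@assign[keep, , drop = FALSE]
    specF@assign$lab <- match(specV@assign$lab[keep], keepLabs)
    specF@labels <- specV@labels[keepLabs]
    specF@start <- specV@start[keepLabs]
    thetaF <- thetaV[keepLabs]
    specV <- specF
    thetaV <- thetaF
    pathIdx <- match(pathLab, specV@labels)
  }
  ix <- .specIndex(specV)

  ## data prep shared across voxels (voxel column appended per voxel)
  Yitems <- .panelData(panel, setdiff(specV@obsNames, vcolName))
  prep0 <- .fimlPrep(Yitems)
  pv <- ncol(Yitems) + 1L
  ## voxel moment cells to patch (all Psi/Alpha constants involving the
  ## voxel latent vs the other exogenous latents)
  latV <- match(vcolName, specV@latNames)
  exoLat <- match(covs, specV@latNames)

  idxMask <- which(mask)
  nvox <- length(idxMask)
  beta <- z <- pval <- array(NA_real_, dm[1:3])
  conv <- array(NA, dm[1:3])
  covX <- if (length(covs)) .panelData(panel, covs) else NULL

  voxMat <- matrix(volumes, prod(dm[1:3]), dm[4])
  for (ii in seq_len(nvox)) {
    vi <- idxMask[ii]
    x <- voxMat[vi, ]
    if (standardizeVoxels) {
      sdx <- sqrt(mean((x - mean(x))^2))
      if (!is.finite(sdx) || sdx == 0) { conv[vi] <- FALSE; next }
      x <- (x - mean(x)) / sdx
    }
    ## patch voxel moments into constants
    mx <- mean(x)
    vx <- mean((x - mx)^2)
    specV@mats$Alpha[latV, 1] <- mx
    specV@mats$Psi[latV, latV] <- vx
    if (length(exoLat)) {
      cc <- as.vector(crossprod(covX - rep(colMeans(covX), each = N), x - mx)) / N
      for (k in seq_along(exoLat)) {
        i1 <- max(latV, exoLat[k]); j1 <- min(latV, exoLat[k])
        specV@mats$Psi[i1, j1] <- cc[k]
        specV@mats$Psi[j1, i1] <- cc[k]
      }
    }
    ## extend pattern statistics with the voxel column
    prep <- prep0
    for (kk in seq_along(prep$patterns)) {
      pt <- prep$patterns[[kk]]
      w <- x[pt$rows]
      tv <- as.vector(crossprod(pt$X, w))
      pt$obs <- c(pt$obs, pv)
      pt$Sx <- c(pt$Sx, sum(w))
      pt$Sxx <- rbind(cbind(pt$Sxx, tv), c(tv, sum(w * w)))
      pt$X <- cbind(pt$X, w)
      prep$patterns[[kk]] <- pt
    }
    prep$p <- pv
    eng <- .makeObjective(specV, prep)
    opt <- nlminb(thetaV, eng$obj, eng$gr,
                  control = list(iter.max = 300L, eval.max = 1000L, rel.tol = 1e-10))
    okFit <- is.finite(opt$objective) && opt$objective < 1e9 &&
      opt$convergence %in% c(0L, 1L)
    conv[vi] <- okFit
    if (!okFit) next
    th <- opt$par
    info <- .numInfo(eng$grad, th)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    bb <- th[pathIdx]
    beta[vi] <- bb
    if (!is.null(vc) && vc[pathIdx, pathIdx] > 0) {
      zz <- bb / sqrt(vc[pathIdx, pathIdx])
      z[vi] <- zz
      pval[vi] <- if (pReference == "t")
        2 * stats::pt(-abs(zz), df = max(N - length(thetaV), 1))
      else 2 * pnorm(-abs(zz))
    } else {
      conv[vi] <- FALSE
    }
  }
  convRate <- mean(conv[idxMask], na.rm = TRUE)
  metaOut <- list(target = target, mode = mode, seed = seed,
                  pReference = pReference,
                  convergenceRate = convRate,
                  standardizedVoxels = standardizeVoxels,
                  multiplicity = "NOTE: uncorrected voxel-wise p values; no multiple-comparison correction applied")
  if (is.finite(convRate) && convRate < 0.95)
    warning(sprintf("%.1f%% of in-mask voxel models failed to converge",
                    100 * (1 - convRate)))
  new("StatMap", beta = beta, z = z, p = pval, converged = conv,
      mask = mask, affine = affine, meta = metaOut)
}

## store only the canonical (lower) triangle for symmetric constants
.unsym <- function(M, name) {
  if (name %in% .symMats) M[upper.tri(M)] <- 0
  M
}

## Connected-component labelling of a 3D logical array by two-pass
## union-find over backward neighbour offsets.
.connectivityOffsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(connectivity,
                 faces = ord == 1,
                 faces_edges = ord <= 2,
                 faces_edges_corners = ord <= 3,
                 stop("unknown connectivity: ", connectivity))
  offs <- offs[keep, ]
  ## backward half only (lexicographic): ensures each undirected pair once
  half <- offs$dz < 0 | (offs$dz == 0 & (offs$dy < 0 | (offs$dy == 0 & offs$dx < 0)))
  as.matrix(offs[half, ])
}

.labelComponents <- function(binary, connectivity = "faces_edges") {
  dm <- dim(binary)
  idx <- which(binary)
  lab <- array(0L, dm)
  if (!length(idx)) return(lab)
  k <- length(idx)
  comp <- integer(prod(dm))
  comp[idx] <- seq_len(k)
  coords <- arrayInd(idx, dm)
  parent <- seq_len(k)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- .connectivityOffsets(connectivity)
  for (r in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[r, ], k, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nbIdx <- (nb[ok, 3] - 1L) * dm[1] * dm[2] + (nb[ok, 2] - 1L) * dm[1] + nb[ok, 1]
    self <- comp[idx[ok]]
    other <- comp[nbIdx]
    both <- other > 0L
    for (e in which(both)) {
      ra <- findRoot(self[e]); rb <- findRoot(other[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), findRoot, 0L)
  lab[idx] <- match(roots, sort(unique(roots)))
  lab
}

#' Cluster-extent thresholding of a statistic map
#'
#' Binarizes `p < pThresh` within the mask (non-converged voxels excluded),
#' labels connected components under the requested connectivity, and keeps
#' components strictly larger than `minExtent` voxels. Peaks are the member
#' voxels with the largest absolute z, reported in world mm via the map's
#' affine.
#'
#' @param map a [StatMap-class].
#' @param pThresh voxel-level threshold (default 0.001, uncorrected).
#' @param minExtent cluster-extent threshold; components with
#'   `size <= minExtent` are dropped (default 50).
#' @param connectivity `"faces"` (6), `"faces_edges"` (18, default) or
#'   `"faces_edges_corners"` (26).
#' @return data.frame with one row per surviving cluster: `cluster`,
#'   `size`, `peakZ`, `peakX/Y/Z` (mm), plus a `members` attribute (list of
#'   voxel-index matrices) and `meta` attribute echoing the thresholds.
#'   Empty (zero-row) when nothing survives.
#' @export
thresholdCluster <- function(map, pThresh = 0.001, minExtent = 50,
                             connectivity = c("faces_edges", "faces",
                                              "faces_edges_corners")) {
  connectivity <- match.arg(connectivity)
  supra <- !is.na(map@p) & map@p < pThresh & map@mask
  supra[is.na(supra)] <- FALSE
  supra <- supra & !is.na(map@converged) & map@converged
  lab <- .labelComponents(supra, connectivity)
  metaOut <- list(pThresh = pThresh, minExtent = minExtent,
                  connectivity = connectivity,
                  note = map@meta$multiplicity)
  empty <- data.frame(cluster = integer(), size = integer(), peakZ = numeric(),
                      peakX = numeric(), peakY = numeric(), peakZ.mm = numeric())
  if (!any(lab > 0)) {
    out <- data.frame(cluster = integer(), size = integer(), peakZ = numeric(),
                      peakX = numeric(), peakY = numeric(), peakZmm = numeric())
    names(out) <- c("cluster", "size", "peakZ", "peakX", "peakY", "peakZ.mm")
    attr(out, "members") <- list()
    attr(out, "meta") <- metaOut
    return(out)
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > minExtent)
  rows <- list(); members <- list()
  for (ci in seq_along(keep)) {
    cl <- keep[ci]
    vox <- which(lab == cl)
    coords <- arrayInd(vox, dim(lab))
    zs <- map@z[vox]
    pk <- which.max(abs(zs))
    world <- voxelToWorld(coords[pk, ], map@affine)
    rows[[ci]] <- data.frame(cluster = ci, size = length(vox), peakZ = zs[pk],
                             peakX = world[1], peakY = world[2], peakZ.mm = world[3])
    members[[ci]] <- coords
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(cluster = integer(), size = integer(), peakZ = numeric(),
                     peakX = numeric(), peakY = numeric(), peakZ.mm = numeric())
    df
  }
  out <- out[order(-out$size), , drop = FALSE]
  if (nrow(out)) {
    members <- members[out$cluster]
    out$cluster <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "members") <- members
  attr(out, "meta") <- metaOut
  out
}

#' Write statistic maps as NIfTI
#'
#' Writes beta, z and -log10(p) volumes plus the mask. The map's 1-based
#' affine is converted to the NIfTI 0-based convention.
#'
#' @param map a [StatMap-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeStatMap <- function(map, dir, prefix = "statmap") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff0 <- map@affine
  aff0[1:3, 4] <- aff0[1:3, 4] + aff0[1:3, 1:3] %*% rep(1, 3)
  paths <- character()
  writeOne <- function(arr, nm) {
    arr[is.na(arr)] <- 0
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(aff0, code = 2L))
    pth <- file.path(dir, sprintf("%s_%s.nii", prefix, nm))
    RNifti::writeNifti(img, pth)
    pth
  }
  paths <- c(paths, writeOne(map@beta, "beta"), writeOne(map@z, "z"),
             writeOne(-log10(pmax(map@p, 1e-300)), "neglog10p"),
             writeOne(map@mask + 0, "mask"))
  invisible(paths)
}

#' Write a cluster table as TSV
#'
#' @param clusters result of [thresholdCluster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClusterTSV <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
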
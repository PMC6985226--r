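#' @import methods
#' @importFrom stats pchisq qnorm rnorm rbinom runif var sd cov complete.cases
#'   nlminb uniroot setNames pnorm
#' @importFrom utils head read.csv write.csv
NULL

#' Longitudinal item panel
#'
#' Container for a wide-format longitudinal item panel: one row per
#' participant, one column per item-by-occasion response (Likert responses
#' treated as continuous), plus time-invariant covariates. Missing responses
#' (dropout, intermittent missingness) are `NA`; covariates must be complete
#' (rows with missing covariates are dropped at construction with a logged
#' count).
#'
#' @slot responses numeric matrix, participants x (items x occasions);
#'   column order is item-fastest within occasion, named `item<i>_t<j>`.
#' @slot covariates data.frame of time-invariant covariates (may have zero
#'   columns); numeric or factor.
#' @slot itemLabels character, item names.
#' @slot occasionLabels character, occasion names.
#' @slot ids character participant identifiers.
#' @slot meta list of provenance (generator truth, drop counts, ...).
#' @export
setClass("ItemPanel",
  representation(
    responses = "matrix",
    covariates = "data.frame",
    itemLabels = "character",
    occasionLabels = "character",
    ids = "character",
    meta = "list"
  )
)

setValidity("ItemPanel", function(object) {
  p <- length(object@itemLabels)
  m <- length(object@occasionLabels)
  msgs <- character()
  if (ncol(object@responses) != p * m)
    msgs <- c(msgs, sprintf("responses has %d columns, expected %d (items x occasions)",
                            ncol(object@responses), p * m))
  if (nrow(object@responses) != length(object@ids))
    msgs <- c(msgs, "ids length must equal number of rows")
  if (nrow(object@covariates) > 0 && nrow(object@covariates) != nrow(object@responses))
    msgs <- c(msgs, "covariates must have one row per participant")
  if (nrow(object@responses) > 0) {
    occIdx <- rep(seq_len(m), each = p)
    obsOcc <- matrix(vapply(seq_len(m), function(j)
      rowSums(!is.na(object@responses[, occIdx == j, drop = FALSE])) > 0,
      logical(nrow(object@responses))), nrow = nrow(object@responses))
    if (any(rowSums(obsOcc) == 0))
      msgs <- c(msgs, "every participant must have at least one observed occasion")
  }
  if (nrow(object@covariates) > 0 && anyNA(object@covariates))
    msgs <- c(msgs, "covariates must not contain missing values")
  if (length(msgs)) msgs else TRUE
})

#' SEM model specification
#'
#' Parameter-matrix representation of a mean-and-covariance-structure model
#' with latent variables (all-y LISREL form): loadings `Lambda` (p x m),
#' item intercepts `Tau` (p), residual covariance `Theta` (p x p), latent
#' regressions `B` (m x m), latent intercepts `Alpha` (m) and latent
#' disturbance covariance `Psi` (m x m). Every matrix cell is an affine
#' function of the free-parameter vector: `cell = const + sum(coef * theta)`.
#' Equality constraints are shared labels; linear constraints (the
#' effects-coding identification: per-factor loadings summing to the number
#' of indicators, per-factor intercepts summing to zero) are encoded as
#' dependent cells with coefficient -1/+1 entries.
#'
#' @slot obsNames character, observed variable names (order of `Lambda` rows).
#' @slot latNames character, latent variable names.
#' @slot mats list of numeric constant matrices `Lambda`, `Tau`, `Theta`,
#'   `B`, `Alpha`, `Psi` (symmetric matrices store their lower triangle as
#'   the canonical part and are mirrored on build).
#' @slot assign data.frame with columns `mat`, `idx` (flat cell index),
#'   `lab` (free parameter label index), `coef`.
#' @slot labels character free-parameter labels; `theta` follows this order.
#' @slot start numeric default starting values per label.
#' @slot exoNames character, observed variables whose (saturated) moments are
#'   fixed at sample values rather than estimated; excluded from the free
#'   count and from the sample-moment count symmetrically.
#' @slot meta list (model description, builder provenance).
#' @export
setClass("ModelSpec",
  representation(
    obsNames = "character",
    latNames = "character",
    mats = "list",
    assign = "data.frame",
    labels = "character",
    start = "numeric",
    exoNames = "character",
    meta = "list"
  )
)

setValidity("ModelSpec", function(object) {
  msgs <- character()
  p <- length(object@obsNames)
  m <- length(object@latNames)
  need <- c("Lambda", "Tau", "Theta", "B", "Alpha", "Psi")
  if (!all(need %in% names(object@mats)))
    return(paste("mats must contain", paste(need, collapse = ", ")))
  dims <- list(Lambda = c(p, m), Tau = c(p, 1), Theta = c(p, p),
               B = c(m, m), Alpha = c(m, 1), Psi = c(m, m))
  for (nm in need) {
    d <- dim(as.matrix(object@mats[[nm]]))
    if (!all(d == dims[[nm]]))
      msgs <- c(msgs, sprintf("%s has dimension %dx%d, expected %dx%d",
                              nm, d[1], d[2], dims[[nm]][1], dims[[nm]][2]))
  }
  if (length(object@start) != length(object@labels))
    msgs <- c(msgs, "start must align with labels")
  if (nrow(object@assign) > 0) {
    if (!all(object@assign$mat %in% need))
      msgs <- c(msgs, "assignments refer to unknown matrices")
    if (any(object@assign$lab < 1 | object@assign$lab > length(object@labels)))
      msgs <- c(msgs, "assignment label index out of range")
  }
  if (length(object@labels) &&
      !all(seq_along(object@labels) %in% unique(object@assign$lab)))
    msgs <- c(msgs, "every free parameter must appear in at least one matrix cell")
  if (!all(object@exoNames %in% object@obsNames))
    msgs <- c(msgs, "exoNames must be observed variables")
  if (length(msgs)) msgs else TRUE
})

#' Fitted SEM result
#'
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot theta numeric named estimates.
#' @slot vcov asymptotic covariance of `theta` (observed-information based,
#'   or sandwich when robust machinery was requested); `NA` entries when the
#'   information was singular.
#' @slot loglik numeric log-likelihood at the optimum.
#' @slot loglikSaturated saturated-model log-likelihood on the same panel.
#' @slot T likelihood-ratio statistic `2 * (loglikSaturated - loglik)`.
#' @slot df model degrees of freedom (sample moments minus free parameters).
#' @slot scaling scaling factor `c` (1 for plain ML).
#' @slot N integer, participants used.
#' @slot converged logical.
#' @slot flags character vector of diagnostic flags (`"heywood"`,
#'   `"singular_information"`, `"nonconverged"`, ...).
#' @slot details list (optimizer diagnostics, seeds, baseline stats, timing).
#' @export
setClass("SemFit",
  representation(
    spec = "ModelSpec",
    theta = "numeric",
    vcov = "matrix",
    loglik = "numeric",
    loglikSaturated = "numeric",
    T = "numeric",
    df = "numeric",
    scaling = "numeric",
    N = "integer",
    converged = "logical",
    flags = "character",
    details = "list"
  )
)

setValidity("SemFit", function(object) {
  msgs <- character()
  if (length(object@theta) != length(object@spec@labels))
    msgs <- c(msgs, "theta must align with spec labels")
  if (isTRUE(object@converged) && is.finite(object@T) && object@T < -1e-6)
    msgs <- c(msgs, "T statistic must be non-negative up to tolerance")
  if (length(msgs)) msgs else TRUE
})

#' Voxel-wise statistic map
#'
#' 3D per-voxel outputs of the massively univariate stage on a common grid:
#' raw path coefficient, Wald z, two-sided p, and a convergence mask.
#' Out-of-mask voxels are `NA` in all arrays.
#'
#' @slot beta,z,p 3D numeric arrays.
#' @slot converged 3D logical array (`NA` outside the mask).
#' @slot mask 3D logical array.
#' @slot affine 4x4 voxel-index (1-based) to world-mm matrix.
#' @slot meta list: target (slope/intercept), mode, convergence rate, seed,
#'   thresholds used downstream, and a loud note that no multiplicity
#'   correction is applied by the mapping itself.
#' @export
setClass("StatMap",
  representation(
    beta = "array", z = "array", p = "array",
    converged = "array", mask = "array",
    affine = "matrix", meta = "list"
  )
)

setValidity("StatMap", function(object) {
  msgs <- character()
  dm <- dim(object@mask)
  for (nm in c("beta", "z", "p", "converged"))
    if (!identical(dim(slot(object, nm)), dm))
      msgs <- c(msgs, sprintf("%s must share the mask's dimensions", nm))
  if (!identical(dim(object@affine), c(4L, 4L)))
    msgs <- c(msgs, "affine must be 4x4")
  pv <- object@p[object@mask & !is.na(object@p)]
  if (length(pv) && (min(pv) < 0 || max(pv) > 1))
    msgs <- c(msgs, "p values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
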
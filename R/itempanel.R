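#' Construct an ItemPanel
#'
#' Wide-format longitudinal item panel: `responses` holds one column per
#' item-by-occasion combination (item varies fastest), Likert responses
#' treated as continuous, `NA` for unobserved. Participants with any missing
#' covariate are removed with a message and the dropped count is recorded in
#' `meta$droppedCovariateRows`.
#'
#' @param responses numeric matrix or data.frame, participants x
#'   (items x occasions).
#' @param covariates optional data.frame of time-invariant covariates.
#' @param nItems,nOccasions panel dimensions; defaults 12 items, 3 occasions.
#' @param itemLabels,occasionLabels optional names.
#' @param ids optional participant identifiers (default row numbers).
#' @param meta optional provenance list.
#' @return an [ItemPanel-class] object.
#' @export
ItemPanel <- function(responses, covariates = NULL,
                      nItems = 12L, nOccasions = 3L,
                      itemLabels = NULL, occasionLabels = NULL,
                      ids = NULL, meta = list()) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  if (is.null(itemLabels)) itemLabels <- paste0("item", seq_len(nItems))
  if (is.null(occasionLabels)) occasionLabels <- paste0("t", seq_len(nOccasions))
  if (ncol(responses) != nItems * nOccasions)
    stop("responses must have nItems * nOccasions columns")
  colnames(responses) <- panelColumnNames(nItems, nOccasions)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(responses)))
  ids <- as.character(ids)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(nrow(responses)))
  covariates <- as.data.frame(covariates)
  dropped <- 0L
  if (ncol(covariates) > 0) {
    keep <- complete.cases(covariates)
    dropped <- sum(!keep)
    if (dropped > 0) {
      message(sprintf("dropping %d participant(s) with missing covariates", dropped))
      responses <- responses[keep, , drop = FALSE]
      covariates <- covariates[keep, , drop = FALSE]
      ids <- ids[keep]
    }
  }
  meta$droppedCovariateRows <- dropped
  new("ItemPanel", responses = responses, covariates = covariates,
      itemLabels = itemLabels, occasionLabels = occasionLabels,
      ids = ids, meta = meta)
}

#' Column-name convention for panel files
#' @param nItems,nOccasions panel dimensions.
#' @return character vector `item<i>_t<j>`, item varying fastest.
#' @export
panelColumnNames <- function(nItems, nOccasions) {
  as.vector(outer(seq_len(nItems), seq_len(nOccasions),
                  function(i, j) sprintf("item%d_t%d", i, j)))
}

#' @rdname ItemPanel-class
#' @export
setMethod("responses", "ItemPanel", function(object) object@responses)

#' @rdname ItemPanel-class
#' @export
setMethod("covariates", "ItemPanel", function(object) object@covariates)

#' @rdname ItemPanel-class
#' @export
setMethod("nItems", "ItemPanel", function(object) length(object@itemLabels))

#' @rdname ItemPanel-class
#' @export
setMethod("nOccasions", "ItemPanel", function(object) length(object@occasionLabels))

#' @rdname ItemPanel-class
#' @export
setMethod("occasionCounts", "ItemPanel", function(object) {
  p <- nItems(object); m <- nOccasions(object)
  occIdx <- rep(seq_len(m), each = p)
  counts <- vapply(seq_len(m), function(j)
    sum(rowSums(!is.na(object@responses[, occIdx == j, drop = FALSE])) > 0), 0L)
  setNames(counts, object@occasionLabels)
})

setMethod("show", "ItemPanel", function(object) {
  cat(sprintf("ItemPanel: %d participants, %d items x %d occasions\n",
              nrow(object@responses), nItems(object), nOccasions(object)))
  cat("  observed per occasion:",
      paste(sprintf("%s=%d", names(occasionCounts(object)), occasionCounts(object)),
            collapse = ", "), "\n")
  if (ncol(object@covariates) > 0)
    cat("  covariates:", paste(colnames(object@covariates), collapse = ", "), "\n")
  invisible(object)
})

#' Read / write an item panel as CSV
#'
#' The file holds one row per participant with an `id` column, response
#' columns named `item<i>_t<j>` and any remaining columns taken as
#' covariates. Missing cells are empty or `NA`.
#'
#' @param path file path.
#' @param nItems,nOccasions expected panel dimensions.
#' @return [readItemPanel()] returns an [ItemPanel-class];
#'   [writeItemPanel()] returns `path` invisibly.
#' @export
readItemPanel <- function(path, nItems = 12L, nOccasions = 3L) {
  df <- read.csv(path, stringsAsFactors = TRUE)
  respCols <- panelColumnNames(nItems, nOccasions)
  missingCols <- setdiff(respCols, colnames(df))
  if (length(missingCols))
    stop("panel file lacks response column(s): ", paste(head(missingCols, 4), collapse = ", "))
  ids <- if ("id" %in% colnames(df)) as.character(df$id) else NULL
  covCols <- setdiff(colnames(df), c("id", respCols))
  ItemPanel(df[, respCols, drop = FALSE],
            covariates = if (length(covCols)) df[, covCols, drop = FALSE] else NULL,
            nItems = nItems, nOccasions = nOccasions, ids = ids)
}

#' @rdname readItemPanel
#' @param panel an [ItemPanel-class].
#' @export
writeItemPanel <- function(panel, path) {
  df <- data.frame(id = panel@ids, panel@responses, check.names = FALSE)
  if (ncol(panel@covariates) > 0) df <- cbind(df, panel@covariates)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

## Observed-variable data matrix a ModelSpec sees: responses plus the
## numerically coded covariate columns named in the spec (if any).
.panelData <- function(panel, obsNames) {
  resp <- panel@responses
  extra <- setdiff(obsNames, colnames(resp))
  if (length(extra)) {
    cov <- covariateDesign(panel)
    bad <- setdiff(extra, colnames(cov))
    if (length(bad))
      stop("model refers to unknown observed variables: ", paste(bad, collapse = ", "))
    resp <- cbind(resp, as.matrix(cov[, extra, drop = FALSE]))
  }
  resp[, obsNames, drop = FALSE]
}

#' Numeric covariate design matrix
#'
#' Expands the covariate table into numeric columns: numeric covariates pass
#' through, factors are dummy-coded against their first (reference) level,
#' producing columns `<name>_<level>`.
#'
#' @param panel an [ItemPanel-class].
#' @return numeric matrix with one row per participant.
#' @export
covariateDesign <- function(panel) {
  cov <- panel@covariates
  if (ncol(cov) == 0) return(matrix(0, nrow(panel@responses), 0))
  cols <- list()
  for (nm in colnames(cov)) {
    x <- cov[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      f <- as.factor(x)
      for (lev in levels(f)[-1])
        cols[[paste0(nm, "_", lev)]] <- as.numeric(f == lev)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}
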
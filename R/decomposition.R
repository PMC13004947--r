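## Subtraction-based decomposition of the chromatin-bound fraction and
## compositional statistics of kinetic fractions.
##
## The bound fraction measured after initiation inhibition (triptolide)
## is interpreted as non-specific binding; the extra binding surviving
## elongation inhibition (alpha-amanitin) as initiating molecules; the
## remainder of the vehicle bound fraction as elongating molecules.

#' Decompose a bound fraction into non-specific, initiating and
#' elongating components
#'
#' `nonspecific = b_triptolide`, `initiating = b_amanitin - b_triptolide`,
#' `elongating = b_vehicle - b_amanitin`. Standard errors of differences
#' are propagated as `sqrt(sd1^2 + sd2^2)`. The three components always
#' reassemble exactly to the vehicle bound fraction. A negative component
#' (possible when drug-condition fractions cross) is returned as-is and
#' flagged with a warning, never clipped.
#'
#' @param bVehicle,bAmanitin,bTriptolide bound fractions in \[0, 1\]
#'   for vehicle-, alpha-amanitin- and triptolide-injected embryos.
#' @param sdVehicle,sdAmanitin,sdTriptolide their standard deviations.
#' @return data.frame with one row per component (`nonspecific`,
#'   `initiating`, `elongating`): `fraction`, `sd`, `flagged`.
#' @examples
#' # printed nc14 inputs: vehicle 0.51, 2.3-fold and 3.6-fold decreases
#' decomposeBoundFraction(0.51, 0.51 / 2.3, 0.51 / 3.6)
#' @export
decomposeBoundFraction <- function(bVehicle, bAmanitin, bTriptolide,
                                   sdVehicle = 0, sdAmanitin = 0,
                                   sdTriptolide = 0) {
  b <- c(bVehicle, bAmanitin, bTriptolide)
  if (any(b < 0 | b > 1)) stop("bound fractions must lie in [0, 1]")
  comp <- c(nonspecific = bTriptolide,
            initiating = bAmanitin - bTriptolide,
            elongating = bVehicle - bAmanitin)
  sds <- c(nonspecific = sdTriptolide,
           initiating = sqrt(sdAmanitin^2 + sdTriptolide^2),
           elongating = sqrt(sdVehicle^2 + sdAmanitin^2))
  flagged <- comp < 0
  if (any(flagged))
    warning("negative component(s): ",
            paste(names(comp)[flagged], collapse = ", "))
  data.frame(component = names(comp), fraction = unname(comp),
             sd = unname(sds), flagged = unname(flagged))
}

#' Ratio of two uncertain quantities with propagated error
#'
#' `r = a / b` with `sd_r = r * sqrt((sd_a/a)^2 + (sd_b/b)^2)`
#' (relative-error propagation).
#'
#' @param a,b numerator and denominator.
#' @param sdA,sdB their standard deviations.
#' @return list with `estimate` and `sd`.
#' @examples
#' foldChange(0.51, 0.37, 0.08, 0.05)  # ~1.4 +- 0.3
#' @export
foldChange <- function(a, b, sdA = 0, sdB = 0) {
  if (b == 0) stop("division by zero")
  r <- a / b
  relA <- if (a == 0) 0 else sdA / a
  sdR <- abs(r) * sqrt(relA^2 + (sdB / b)^2)
  list(estimate = r, sd = sdR)
}

#' Centered log-ratio transformation
#'
#' `clr_i = log(x_i / g(x))` with `g` the geometric mean of the parts.
#' Transformed values sum to zero and are invariant to rescaling the
#' composition. Zero parts are only admitted with
#' `zeroReplace = TRUE`, which applies multiplicative replacement with
#' half the smallest observed nonzero part.
#'
#' @param x composition (vector of parts) or a matrix/data.frame with
#'   one composition per row.
#' @param zeroReplace replace zero parts before transforming.
#' @return transformed values, same shape as `x`.
#' @examples
#' clrTransform(c(0.5, 0.25, 0.25))
#' @export
clrTransform <- function(x, zeroReplace = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x))
    return(t(apply(x, 1, clrTransform, zeroReplace = zeroReplace)))
  if (any(x < 0)) stop("negative part in composition")
  if (any(x == 0)) {
    if (!zeroReplace) stop("zero part in composition; set zeroReplace = TRUE")
    delta <- 0.5 * min(x[x > 0])
    k <- sum(x == 0)
    tot <- sum(x)
    x[x > 0] <- x[x > 0] * (1 - k * delta / tot)
    x[x == 0] <- delta
  }
  lx <- log(x)
  lx - mean(lx)
}

## exact two-sided rank-sum p-value by full enumeration of group
## assignments, valid with ties (average ranks); used for small groups
exactRankSumP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(nx + ny, nx)
  sums <- colSums(matrix(r[idx], nrow = nx))
  dev <- abs(sums - nx * (nx + ny + 1) / 2)
  mean(dev >= abs(obs - nx * (nx + ny + 1) / 2) - 1e-9)
}

#' Compare kinetic fractions between two groups of fields
#'
#' Two-sided rank-sum tests per component, either on centered log-ratio
#' transformed compositions (`mode = "coda"`, appropriate for the joint
#' bound/intermediate/fast simplex) or on the raw fractions
#' (`mode = "raw"`, for a single independent component). Groups of up to
#' 10 fields are tested exactly by enumerating all group assignments
#' (valid under ties); larger groups use the normal approximation with
#' tie correction.
#'
#' @param groupA,groupB matrices/data.frames of per-field fractions
#'   (columns = components), or numeric vectors for a single component.
#' @param mode `"coda"` or `"raw"`.
#' @param zeroReplace passed to [clrTransform()].
#' @return named vector of p-values, one per component.
#' @export
compareFractions <- function(groupA, groupB, mode = c("coda", "raw"),
                             zeroReplace = TRUE) {
  mode <- match.arg(mode)
  if (is.null(dim(groupA))) groupA <- matrix(groupA, ncol = 1)
  if (is.null(dim(groupB))) groupB <- matrix(groupB, ncol = 1)
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 3 || nrow(groupB) < 3)
    stop("need at least 3 fields per group")
  if (mode == "coda") {
    if (ncol(groupA) < 2) stop("coda mode needs a full composition")
    groupA <- clrTransform(groupA, zeroReplace = zeroReplace)
    groupB <- clrTransform(groupB, zeroReplace = zeroReplace)
  }
  p <- vapply(seq_len(ncol(groupA)), function(j) {
    x <- groupA[, j]; y <- groupB[, j]
    if (length(x) <= 10 && length(y) <= 10) {
      exactRankSumP(x, y)
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    }
  }, numeric(1))
  names(p) <- colnames(groupA)
  if (is.null(names(p)) || all(names(p) == ""))
    names(p) <- paste0("component", seq_along(p))
  p
}
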
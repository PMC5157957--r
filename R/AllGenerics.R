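#' Number of realizations in an ensemble-like object
#' @param object a [TrajectoryEnsemble-class] or [LysisStatistics-class].
#' @return integer count of realizations.
#' @export
setGeneric("nRealizations", function(object) standardGeneric("nRealizations"))

#' Extract the abundance series of one species
#' @param object a [Trajectory-class] or [TrajectoryEnsemble-class].
#' @param species species name.
#' @return numeric vector (trajectory) or matrix time x realization
#'   (ensemble).
#' @export
setGeneric("speciesCounts",
           function(object, species) standardGeneric("speciesCounts"))

#' Ensemble mean time course
#' @param object a [TrajectoryEnsemble-class].
#' @param species optional species name; default all.
#' @return matrix time x species (or vector for one species).
#' @export
setGeneric("ensembleMean",
           function(object, species = NULL) standardGeneric("ensembleMean"))

#' Ensemble variance time course
#' @param object a [TrajectoryEnsemble-class].
#' @param species optional species name; default all.
#' @return matrix time x species (or vector for one species).
#' @export
setGeneric("ensembleVar",
           function(object, species = NULL) standardGeneric("ensembleVar"))

#' Stationary abundances as a named vector
#' @param object a [SteadyState-class].
#' @return named numeric vector c(M, A, S).
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))

#' Empirical survival function (fraction of cells without a peak)
#' @param object a [LysisStatistics-class].
#' @param times optional evaluation grid (min); defaults to a 1-min grid
#'   spanning the observed peak times.
#' @return data.frame with columns \code{time} and \code{survival};
#'   \code{survival} starts at 1 and is non-increasing.
#' @export
setGeneric("survivalFunction",
           function(object, times = NULL) standardGeneric("survivalFunction"))
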
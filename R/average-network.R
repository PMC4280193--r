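#' Build the group-average network of a cohort
#'
#' An edge enters the average network when it is present (weight > 0) in
#' at least a fraction \code{presenceThreshold} of the selected subject
#' networks — the consensus rule commonly used for structural connectomes
#' with a 75\% default. Its weight is the mean weight over the subjects in
#' which the edge is present (\code{weightMean = "present"}), or over all
#' selected subjects including absent-as-zero
#' (\code{weightMean = "all"}).
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param presenceThreshold fraction in \code{(0, 1]}; default 0.75.
#' @param scanSelector which scans enter the average: \code{"a"},
#'   \code{"b"}, or \code{"both"} (each scan counts as one network).
#' @param weightMean \code{"present"} (default) or \code{"all"}; see above.
#' @return A \linkS4class{Connectome} with the metadata of the first scan.
#' @examples
#' ## an edge seen in 3 of 4 subjects with weights 2, 4, 6 gets weight 4
#' @export
buildAverageNetwork <- function(cohort, presenceThreshold = 0.75,
                                scanSelector = c("both", "a", "b"),
                                weightMean = c("present", "all")) {
  stopifnot(is(cohort, "Cohort"))
  if (nSubjects(cohort) == 0) stop("empty cohort")
  if (presenceThreshold <= 0 || presenceThreshold > 1) {
    stop("presenceThreshold must lie in (0, 1]")
  }
  scanSelector <- match.arg(scanSelector)
  weightMean <- match.arg(weightMean)
  nets <- switch(scanSelector,
                 a = cohort@scanA,
                 b = cohort@scanB,
                 both = c(cohort@scanA, cohort@scanB))
  ref <- nets[[1]]
  n <- nNodes(ref)
  presence <- matrix(0, n, n)
  wsum <- matrix(0, n, n)
  for (net in nets) {
    W <- weightMatrix(net)
    presence <- presence + (W > 0)
    wsum <- wsum + W
  }
  frac <- presence / length(nets)
  keep <- frac >= presenceThreshold & presence > 0
  W_avg <- matrix(0, n, n)
  if (weightMean == "present") {
    W_avg[keep] <- wsum[keep] / presence[keep]
  } else {
    W_avg[keep] <- wsum[keep] / length(nets)
  }
  Connectome(W_avg, labels = ref@labels, hemisphere = ref@hemisphere,
             coords = nodeCoords(ref), nodeSize = nodeSizes(ref))
}
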
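## File formats
## ------------
## Adjacency: dense numeric TSV (tab) or CSV (by .csv extension), optional
## header row auto-detected. Node table: TSV with mandatory header and
## columns label, hemisphere, optional x, y, z, size (an index column is
## written on output and ignored on input). Cohort manifest: JSON mapping
## subject_id -> scan_a/scan_b file paths.

.matrixSep <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

.readMatrixFile <- function(path) {
  sep <- .matrixSep(path)
  first <- readLines(path, n = 1)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  d <- utils::read.table(path, sep = sep, header = has_header,
                         check.names = FALSE)
  ## a leading label column (non-numeric) is dropped
  if (ncol(d) > 0 && !is.numeric(d[[1]]) && ncol(d) == nrow(d) + 1) {
    d <- d[, -1, drop = FALSE]
  }
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("matrix file contains non-numeric entries: ", path)
  dimnames(m) <- NULL
  m
}

#' Load a connectome from an adjacency matrix file and a node table
#'
#' The adjacency file is a dense numeric table (TSV, or CSV by file
#' extension; header auto-detected). The node table is a TSV with a header
#' and columns \code{label}, \code{hemisphere}, optional \code{x},
#' \code{y}, \code{z} coordinates and optional \code{size}. Asymmetries up
#' to a relative \code{symTol} are averaged away; anything larger is an
#' error, as are negative weights and dimension mismatches.
#'
#' @param matrixPath path to the adjacency matrix file.
#' @param nodeTablePath path to the node table TSV.
#' @param symTol relative symmetrization tolerance.
#' @return A \linkS4class{Connectome}.
#' @seealso \code{\link{saveConnectome}} for the inverse operation.
#' @export
loadConnectome <- function(matrixPath, nodeTablePath, symTol = 1e-8) {
  W <- .readMatrixFile(matrixPath)
  nt <- utils::read.table(nodeTablePath, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("label", "hemisphere") %in% names(nt))) {
    stop("node table must have columns 'label' and 'hemisphere'")
  }
  if (nrow(nt) != nrow(W)) {
    stop(sprintf("dimension mismatch: matrix is %d x %d but node table has %d rows",
                 nrow(W), ncol(W), nrow(nt)))
  }
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(nt))) {
    coords <- as.matrix(nt[, c("x", "y", "z")])
  }
  nodeSize <- if ("size" %in% names(nt)) nt$size else NULL
  Connectome(W, labels = nt$label, hemisphere = nt$hemisphere,
             coords = coords, nodeSize = nodeSize, symTol = symTol)
}

#' Save a connectome to an adjacency matrix file and a node table
#'
#' Weights are written with 16 significant digits so that
#' \code{loadConnectome(saveConnectome(x))} round-trips exactly at the
#' written precision. The node table carries 1-based node indices next to
#' the labels; coordinate and size columns are only written when present.
#'
#' @param x a \linkS4class{Connectome}.
#' @param matrixPath output path for the adjacency matrix (TSV, or CSV by
#'   extension).
#' @param nodeTablePath output path for the node table TSV.
#' @return Invisibly, \code{x}.
#' @export
saveConnectome <- function(x, matrixPath, nodeTablePath) {
  stopifnot(is(x, "Connectome"))
  sep <- .matrixSep(matrixPath)
  m <- formatC(x@W, format = "g", digits = 16)
  utils::write.table(m, matrixPath, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nt <- data.frame(index = seq_len(nNodes(x)), label = x@labels,
                   hemisphere = x@hemisphere, stringsAsFactors = FALSE)
  if (!is.null(nodeCoords(x))) {
    nt$x <- x@coords[, 1]; nt$y <- x@coords[, 2]; nt$z <- x@coords[, 3]
  }
  if (!is.null(nodeSizes(x))) nt$size <- x@nodeSize
  .writeTSV(nt, nodeTablePath)
  invisible(x)
}

#' Correct edge weights for region size
#'
#' Probabilistic-tractography connectivity indices scale with the number
#' of seed and target voxels, so larger parcels accrue spuriously heavy
#' edges. This divides each weight by a symmetric function of the two
#' endpoint sizes, by default their sum:
#' \code{W'[i, j] = W[i, j] / (size_i + size_j)}. The divisor is a hook so
#' other symmetric penalties (e.g. the product or geometric mean) can be
#' swapped in.
#'
#' @param x a \linkS4class{Connectome} with node sizes present.
#' @param divisor function of two size vectors returning the positive
#'   divisor for each edge; default \code{function(si, sj) si + sj}.
#' @return A \linkS4class{Connectome} with corrected weights.
#' @export
applyNodeSizeCorrection <- function(x, divisor = function(si, sj) si + sj) {
  sz <- nodeSizes(x)
  if (is.null(sz)) stop("node sizes are missing")
  n <- nNodes(x)
  D <- divisor(matrix(sz, n, n), matrix(sz, n, n, byrow = TRUE))
  if (any(!is.finite(D)) || any(D <= 0)) stop("divisor must be positive and finite")
  setWeights(x, x@W / D)
}

#' Read a cohort from a JSON manifest
#'
#' The manifest maps each subject id to the matrix and node-table paths of
#' its two scans:
#' \preformatted{{"atlas": "...", "subjects": {"s1": {"scan_a":
#'   {"matrix": "...", "nodes": "..."}, "scan_b": {...}}, ...}}}
#' Relative paths are resolved against the manifest's directory.
#'
#' @param manifestPath path to the JSON manifest.
#' @param symTol symmetrization tolerance passed to
#'   \code{\link{loadConnectome}}.
#' @return A \linkS4class{Cohort}.
#' @export
readCohort <- function(manifestPath, symTol = 1e-8) {
  man <- jsonlite::read_json(manifestPath)
  base <- dirname(manifestPath)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  ids <- names(man$subjects)
  loadScan <- function(entry) {
    loadConnectome(resolve(entry$matrix), resolve(entry$nodes), symTol = symTol)
  }
  a <- lapply(ids, function(id) loadScan(man$subjects[[id]]$scan_a))
  b <- lapply(ids, function(id) loadScan(man$subjects[[id]]$scan_b))
  Cohort(ids, a, b,
         atlasName = if (is.null(man$atlas)) "unspecified" else man$atlas)
}

#' Write a cohort to a directory with a JSON manifest
#'
#' @param x a \linkS4class{Cohort}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(x, dir) {
  stopifnot(is(x, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  for (k in seq_len(nSubjects(x))) {
    id <- x@subjectIds[k]
    entry <- list()
    for (scan in c("a", "b")) {
      con <- if (scan == "a") x@scanA[[k]] else x@scanB[[k]]
      mp <- sprintf("%s_scan_%s_matrix.tsv", id, scan)
      np <- sprintf("%s_scan_%s_nodes.tsv", id, scan)
      saveConnectome(con, file.path(dir, mp), file.path(dir, np))
      entry[[paste0("scan_", scan)]] <- list(matrix = mp, nodes = np)
    }
    subjects[[id]] <- entry
  }
  manifest <- list(atlas = x@atlasName, subjects = subjects)
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
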
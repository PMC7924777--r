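#' @include AllClasses.R AllGenerics.R
NULL

# neighbor offsets per topology; hex2d uses axial coordinates (q, r)
.latticeOffsets <- list(
  square2d = rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)),
  hex2d    = rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                   c(1L, -1L), c(-1L, 1L)),
  cubic3d  = rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
)

.latticeDefaultD <- c(square2d = 4L, hex2d = 6L, cubic3d = 6L)

#' Build a regular lattice
#'
#' Constructs the site graph of a square planar (von Neumann
#' 4-neighborhood), hexagonal planar (axial coordinates, 6 neighbors) or
#' simple cubic (6 face neighbors) lattice, with closed or periodic
#' boundaries.  Under closed boundaries, edge and corner sites simply have
#' shorter neighbor lists; no padding pseudo-species is used.
#'
#' The nominal neighborhood size `D` defaults to 4 (square), 6 (hexagonal)
#' and 6 (cubic, face neighbors) and controls how many reaction channels a
#' pairwise reaction expands into.  It may be overridden (e.g. `D = 8` for
#' a cubic lattice with a wider neighborhood convention); the channel and
#' class machinery uses actual neighbor counts, so sites never reach channel
#' index `j` beyond their degree.
#'
#' Sites are indexed row-major in coordinate order; coordinates are
#' returned by [siteCoords()].
#'
#' @param topology `"square2d"`, `"hex2d"` or `"cubic3d"`.
#' @param extent positive integer vector of per-dimension sizes (length 2
#'   for planar, 3 for cubic lattices).
#' @param boundary `"closed"` (default) or `"periodic"`.
#' @param D optional nominal neighborhood size override.
#' @return a [SiteGraph-class].
#' @examples
#' g <- buildLattice("square2d", c(10, 10))
#' range(siteDegrees(g))   # 2 (corners) .. 4 (interior)
#' @export
buildLattice <- function(topology = c("square2d", "hex2d", "cubic3d"),
                         extent, boundary = c("closed", "periodic"),
                         D = NULL) {
  topology <- match.arg(topology)
  boundary <- match.arg(boundary)
  offsets <- .latticeOffsets[[topology]]
  ndim <- ncol(offsets)
  extent <- as.integer(extent)
  if (length(extent) != ndim)
    stop(sprintf("'%s' needs an extent of length %d", topology, ndim))
  if (any(extent < 1L)) stop("extent dimensions must be >= 1")
  if (boundary == "periodic" && any(extent < 3L))
    stop("periodic boundaries need every dimension >= 3 (no wrap-around duplicates)")
  if (is.null(D)) D <- .latticeDefaultD[[topology]]
  D <- as.integer(D)
  if (D < 1L) stop("D must be a positive integer")
  if (D < nrow(offsets))
    stop("D cannot be smaller than the lattice coordination number")

  n <- prod(extent)
  coords <- as.matrix(expand.grid(lapply(extent, function(e) seq_len(e) - 1L)))
  colnames(coords) <- c("x", "y", "z")[seq_len(ndim)]
  storage.mode(coords) <- "integer"

  # site index from coordinates, row-major: x fastest? index = 1 + x + y*ex + ...
  strides <- cumprod(c(1L, extent[-ndim]))
  idxOf <- function(cc) 1L + as.integer(cc %*% strides)

  neighbors <- vector("list", n)
  for (k in seq_len(nrow(offsets))) {
    cc <- sweep(coords, 2L, offsets[k, ], "+")
    if (boundary == "periodic") {
      cc <- sweep(cc, 2L, extent, function(a, e) a %% e)
      ok <- rep(TRUE, n)
    } else {
      ok <- rowSums(cc < 0L) == 0L & rowSums(sweep(cc, 2L, extent, ">=")) == 0L
    }
    tgt <- rep(NA_integer_, n)
    tgt[ok] <- idxOf(cc[ok, , drop = FALSE])
    for (s in which(ok)) neighbors[[s]] <- c(neighbors[[s]], tgt[s])
  }
  neighbors <- lapply(neighbors, function(v) if (is.null(v)) integer(0) else v)

  new("SiteGraph", nSites = as.integer(n), neighbors = neighbors,
      coords = coords, D = D, topology = topology, boundary = boundary,
      extent = extent)
}

#' Build a site graph from an edge list
#'
#' Arbitrary interaction graphs are supported: sites are relabeled to a
#' contiguous 1-based range, edges are symmetrized and deduplicated, and
#' the nominal neighborhood size `D` is set to the maximum degree.
#'
#' @param edges two-column matrix (or data.frame) of site pairs; labels may
#'   be any integers.
#' @param nSites optional number of sites (to include isolated sites beyond
#'   those named in `edges`); sites are then labeled `1:nSites` and `edges`
#'   must use those labels.
#' @return a [SiteGraph-class] with `topology = "custom"`.
#' @examples
#' g <- fromAdjacency(rbind(c(1, 2), c(2, 3)))
#' siteDegrees(g)   # 1 2 1
#' @export
fromAdjacency <- function(edges, nSites = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("edges must have two columns")
  storage.mode(edges) <- "integer"
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed")
  if (is.null(nSites)) {
    labels <- sort(unique(as.vector(edges)))
    if (length(labels) == 0L) stop("empty edge list: supply nSites")
    edges[] <- match(edges, labels)
    n <- length(labels)
  } else {
    n <- as.integer(nSites)
    if (length(edges) && (any(edges < 1L) || any(edges > n)))
      stop("edge labels must be in 1:nSites")
  }
  neighbors <- rep(list(integer(0)), n)
  if (length(edges)) {
    und <- unique(rbind(edges, edges[, 2:1, drop = FALSE]))
    sp <- split(und[, 2L], und[, 1L])
    for (nm in names(sp)) neighbors[[as.integer(nm)]] <- sort(unname(sp[[nm]]))
  }
  D <- max(1L, vapply(neighbors, length, 1L))
  coords <- matrix(seq_len(n) - 1L, ncol = 1L, dimnames = list(NULL, "x"))
  new("SiteGraph", nSites = n, neighbors = neighbors, coords = coords,
      D = as.integer(D), topology = "custom", boundary = "none",
      extent = integer(0))
}

#' @describeIn buildLattice number of sites.
#' @param x a [SiteGraph-class].
#' @export
setMethod("nSites", "SiteGraph", function(x) x@nSites)

#' @rdname buildLattice
#' @export
setMethod("neighborList", "SiteGraph", function(x) x@neighbors)

#' @rdname buildLattice
#' @export
setMethod("siteDegrees", "SiteGraph",
          function(x) vapply(x@neighbors, length, 1L))

#' @rdname buildLattice
#' @export
setMethod("siteCoords", "SiteGraph", function(x) x@coords)

#' @rdname buildLattice
#' @export
setMethod("latticeD", "SiteGraph", function(x) x@D)

setMethod("show", "SiteGraph", function(object) {
  cat(sprintf("SiteGraph: %s, %d sites", object@topology, object@nSites))
  if (length(object@extent))
    cat(sprintf(" (%s, %s boundary)", paste(object@extent, collapse = "x"),
                object@boundary))
  cat(sprintf(", D = %d\n", object@D))
  dg <- siteDegrees(object)
  cat(sprintf("  degrees: min %d, max %d\n", min(dg), max(dg)))
})
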
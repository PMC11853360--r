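# Internal array helpers shared by the phantom generator and VOI code.

#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm sd var
NULL

# Shift a 3D array along one axis, zero-filling vacated planes.
shift_axis <- function(a, axis, by) {
  dims <- dim(a)
  n <- dims[axis]
  if (by == 0L) return(a)
  out <- array(0, dims)
  keep <- n - abs(by)
  if (keep <= 0L) return(out)
  src <- if (by > 0L) seq_len(keep) else seq.int(abs(by) + 1L, n)
  dst <- if (by > 0L) seq.int(by + 1L, n) else seq_len(keep)
  ai <- list(TRUE, TRUE, TRUE)
  bi <- list(TRUE, TRUE, TRUE)
  ai[[axis]] <- dst
  bi[[axis]] <- src
  do.call(`[<-`, c(list(out), ai, list(do.call(`[`, c(list(a), bi, list(drop = FALSE))))))
}

# Separable Gaussian blur. fwhm_mm = 0 is a no-op. Kernel is a normalized
# discrete Gaussian truncated at 3 sigma; edges are zero-padded (air).
gaussian_blur <- function(a, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(a)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  h <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-0.5 * ((-h:h) / sigma_vox)^2)
  k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_axis(a, axis, j - h - 1L)
    }
    a <- acc
  }
  a
}

# Voxel centers: world coordinate of index i is (i - 0.5) * spacing.
vox_to_world <- function(ijk, spacing) (ijk - 0.5) * spacing

world_to_vox <- function(xyz, spacing) xyz / spacing + 0.5

# linear index <-> (i,j,k) for dims
ijk_to_lin <- function(ijk, dims) {
  ijk[, 1L] + (ijk[, 2L] - 1L) * dims[1L] + (ijk[, 3L] - 1L) * dims[1L] * dims[2L]
}

lin_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1L]
  j <- (lin0 %/% dims[1L]) %% dims[2L]
  k <- lin0 %/% (dims[1L] * dims[2L])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# Integer voxel offsets whose centers fall within `radius_mm` of the origin.
sphere_offsets <- function(radius_mm, spacing) {
  m <- as.integer(floor(radius_mm / spacing))
  g <- expand.grid(di = -m:m, dj = -m:m, dk = -m:m)
  d2 <- (g$di^2 + g$dj^2 + g$dk^2) * spacing^2
  keep <- d2 <= radius_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# 26-connectivity neighbour offsets.
conn26_offsets <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), , drop = FALSE])
}

# Number of connected components (26-connectivity) of a sparse voxel set.
#' @importFrom igraph graph_from_edgelist components make_empty_graph
count_components26 <- function(ijk, dims) {
  m <- nrow(ijk)
  if (m == 0L) return(0L)
  if (m == 1L) return(1L)
  lin <- ijk_to_lin(ijk, dims)
  pos <- seq_len(m)
  offs <- conn26_offsets()
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- cbind(ijk[, 1L] + offs[o, 1L], ijk[, 2L] + offs[o, 2L], ijk[, 3L] + offs[o, 3L])
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    if (!any(ok)) next
    nb_lin <- ijk_to_lin(nb[ok, , drop = FALSE], dims)
    hit <- match(nb_lin, lin)
    found <- !is.na(hit)
    if (any(found)) {
      edges[[o]] <- cbind(pos[ok][found], hit[found])
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) return(m)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  # voxels with indices above max(edges) never entered the graph: singletons
  comp$no + (m - igraph::vcount(g))
}

# order rows lexicographically by (x, y, z)
lex_order <- function(xyz) order(xyz[, 1L], xyz[, 2L], xyz[, 3L])

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
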
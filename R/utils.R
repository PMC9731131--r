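# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-stream seed; stays below 2^31 and exact in doubles
subSeed <- function(master, tag) {
  as.integer((as.numeric(master) * 48271 + as.numeric(tag)) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# neighbour offsets for 6/18/26-connectivity
neighborOffsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = ord == 1L, "18" = ord <= 2L, "26" = rep(TRUE, nrow(g)))
  unname(g[keep, , drop = FALSE])
}

# label connected components of a binary 3D array; returns a list with the
# linear indices per component, ordered by smallest member index
labelComponents <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  if (length(dims) != 3L) stop("mask must be a 3D array")
  idx <- which(mask > 0)
  if (!length(idx)) return(list())
  coords <- arrayInd(idx, dims)
  offs <- neighborOffsets(connectivity)
  # half the offsets suffice for an undirected adjacency
  offs <- offs[offs[, 3] > 0L | (offs[, 3] == 0L & offs[, 2] > 0L) |
               (offs[, 3] == 0L & offs[, 2] == 0L & offs[, 1] > 0L), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], nrow(coords), 3L, byrow = TRUE)
    valid <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
             nb[, 2] >= 1L & nb[, 2] <= dims[2] &
             nb[, 3] >= 1L & nb[, 3] <= dims[3]
    nlin <- (nb[, 3] - 1L) * dims[1] * dims[2] + (nb[, 2] - 1L) * dims[1] + nb[, 1]
    j <- match(nlin, idx)
    hit <- valid & !is.na(j)
    from <- c(from, which(hit)); to <- c(to, j[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  comp <- split(idx, memb)
  comp[order(vapply(comp, min, numeric(1)))]
}

# binary dilation of a 3D logical array by the 6/18/26 structuring element
dilateMask <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  mask <- mask > 0
  out <- mask
  offs <- neighborOffsets(connectivity)
  for (o in seq_len(nrow(offs))) {
    s <- offs[o, ]
    src <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    dst <- src
    for (ax in 1:3) {
      if (s[ax] > 0) { dst[[ax]] <- (1L + s[ax]):dims[ax]; src[[ax]] <- 1L:(dims[ax] - s[ax]) }
      else if (s[ax] < 0) { dst[[ax]] <- 1L:(dims[ax] + s[ax]); src[[ax]] <- (1L - s[ax]):dims[ax] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

coordsToLinear <- function(coords, dims) {
  (coords[, 3] - 1L) * dims[1] * dims[2] + (coords[, 2] - 1L) * dims[1] + coords[, 1]
}
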
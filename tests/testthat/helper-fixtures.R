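# Shared fixtures; everything is generated in code at test time.

toyProtocol <- function(nControl = 725L) {
  scanProtocol(matrixSize = c(24L, 24L, 12L), nControl = nControl)
}

toyPhantom <- function() defaultPhantom(c(24L, 24L, 12L))

# a deterministic localizer-only analysis on the toy grid, cached per
# session so the heavier tests can share it
toyLocalizer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- toyProtocol(nControl = 0L)
      sched <- buildCueSchedule(p, seed = 1)
      ses <- synthesizeSession(p, sched, toyPhantom(), canonicalHrf(1.62),
                               noiseModel(seed = 42))
      cache <<- list(protocol = p, schedule = sched, phantom = toyPhantom(),
                     session = ses, result = runLocalizer(ses))
    }
    cache
  }
})

# a smooth test volume for interpolation accuracy checks
smoothBlob <- function(dims = c(20L, 20L, 16L)) {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3]))
  ctr <- (dims + 1) / 2
  array(1000 * exp(-((g$i - ctr[1])^2 / 80 + (g$j - ctr[2])^2 / 80 +
                       (g$k - ctr[3])^2 / 50)), dims)
}

# independent flood-fill connected components (recursive frontier
# growth over an explicit voxel list); oracle for cluster removal
floodFillComponents <- function(voxels, dims, connectivity = 6L) {
  offs <- switch(as.character(connectivity),
                 "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                 stop("oracle only implements 6-connectivity"))
  coords <- cbind((voxels - 1L) %% dims[1] + 1L,
                  ((voxels - 1L) %/% dims[1]) %% dims[2] + 1L,
                  (voxels - 1L) %/% (dims[1] * dims[2]) + 1L)
  labels <- integer(length(voxels))
  nextLab <- 0L
  for (i in seq_along(voxels)) {
    if (labels[i] > 0L) next
    nextLab <- nextLab + 1L
    frontier <- i
    labels[i] <- nextLab
    while (length(frontier)) {
      cur <- frontier[1]
      frontier <- frontier[-1]
      for (r in seq_len(nrow(offs))) {
        nb <- coords[cur, ] + offs[r, ]
        j <- which(coords[, 1] == nb[1] & coords[, 2] == nb[2] & coords[, 3] == nb[3])
        if (length(j) == 1L && labels[j] == 0L) {
          labels[j] <- nextLab
          frontier <- c(frontier, j)
        }
      }
    }
  }
  labels
}
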
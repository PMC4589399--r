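# shared fixtures built in code

# a short contiguous schedule for cheap unit tests
shortSchedule <- function() frameSchedule(durations = c(1, 1, 2, 2, 4, 10))

# a small uniform-valued dynamic volume
uniformVolume <- function(value = 3, nf = 4L, d = c(6L, 6L, 6L),
                          voxel = 1) {
  imageVolume4D(array(value, c(nf, d)), rep(voxel, 3),
                frameSchedule(durations = rep(1, nf)))
}

# brute-force 6-connected flood fill inside an intensity band, as an
# independent oracle for regionGrowRefine
floodFillOracle <- function(img, seed, lo, hi) {
  d <- dim(img)
  inband <- img >= lo & img <= hi
  vis <- array(FALSE, d)
  stopifnot(inband[seed[1], seed[2], seed[3]])
  vis[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
      nb <- cur + off
      if (all(nb >= 1) && all(nb <= d) && !vis[nb[1], nb[2], nb[3]] &&
          inband[nb[1], nb[2], nb[3]]) {
        vis[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  which(vis, arr.ind = TRUE)
}

# random valid kinetic parameter draw
randomParams <- function(maxRate = 0.5, vbMax = 0.5) {
  kineticParams(runif(1, 0, maxRate), runif(1, 0, maxRate),
                runif(1, 0, maxRate), runif(1, 0, maxRate),
                runif(1, 0, vbMax))
}
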
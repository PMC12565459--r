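# Independent nested-loop oracles for the texture-matrix families. These are
# deliberately written as plain voxel loops, sharing no code with the package
# implementations.

oracle_dirs <- rbind(
  c(1, 0, 0), c(-1, 1, 0), c(0, 1, 0), c(1, 1, 0),
  c(-1, -1, 1), c(0, -1, 1), c(1, -1, 1), c(-1, 0, 1), c(0, 0, 1),
  c(1, 0, 1), c(-1, 1, 1), c(0, 1, 1), c(1, 1, 1))

.in_bounds <- function(p, dims) all(p >= 1) && all(p <= dims)

# symmetric co-occurrence counts for one direction
oracle_glcm <- function(A, ng, d) {
  dims <- dim(A)
  P <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(A[x, y, z])) next
    q <- c(x, y, z) + d
    if (!.in_bounds(q, dims) || is.na(A[q[1], q[2], q[3]])) next
    i <- A[x, y, z]; j <- A[q[1], q[2], q[3]]
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  P
}

# run-length counts (level x length) for one direction, by explicit walking
oracle_glrlm <- function(A, d) {
  dims <- dim(A)
  runs <- list()
  visited <- array(FALSE, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(A[x, y, z]) || visited[x, y, z]) next
    prev <- c(x, y, z) - d
    if (.in_bounds(prev, dims) && !is.na(A[prev[1], prev[2], prev[3]]) &&
        A[prev[1], prev[2], prev[3]] == A[x, y, z]) next  # run starts earlier
    len <- 0L; p <- c(x, y, z)
    while (.in_bounds(p, dims) && !is.na(A[p[1], p[2], p[3]]) &&
           A[p[1], p[2], p[3]] == A[x, y, z]) {
      visited[p[1], p[2], p[3]] <- TRUE
      len <- len + 1L
      p <- p + d
    }
    runs[[length(runs) + 1L]] <- c(A[x, y, z], len)
  }
  do.call(rbind, runs)
}

# zones: (level, size) per 26-connected constant-level component, flood fill
oracle_glszm <- function(A) {
  dims <- dim(A)
  seen <- array(FALSE, dims)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(A[x, y, z]) || seen[x, y, z]) next
    lev <- A[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (.in_bounds(q, dims) && !seen[q[1], q[2], q[3]] &&
            !is.na(A[q[1], q[2], q[3]]) && A[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

# (level, dependence-size) per voxel; dependence = equal 26-neighbours + 1
oracle_gldm <- function(A) {
  dims <- dim(A)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(A[x, y, z])) next
    dep <- 0L
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (.in_bounds(q, dims) && !is.na(A[q[1], q[2], q[3]]) &&
          A[q[1], q[2], q[3]] == A[x, y, z]) dep <- dep + 1L
    }
    out[[length(out) + 1L]] <- c(A[x, y, z], dep + 1L)
  }
  do.call(rbind, out)
}

# NGTDM per-level occupancy and absolute-difference sums
oracle_ngtdm <- function(A) {
  dims <- dim(A)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lev <- c(); diffs <- c()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(A[x, y, z])) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (.in_bounds(q, dims) && !is.na(A[q[1], q[2], q[3]]))
        nb <- c(nb, A[q[1], q[2], q[3]])
    }
    if (length(nb) == 0L) next
    lev <- c(lev, A[x, y, z])
    diffs <- c(diffs, abs(A[x, y, z] - mean(nb)))
  }
  list(
    s = vapply(sort(unique(lev)), function(l) sum(diffs[lev == l]), numeric(1)),
    n = vapply(sort(unique(lev)), function(l) sum(lev == l), numeric(1)),
    levels = sort(unique(lev)), nvp = length(lev))
}

# random small level array with NA border cut-outs, fixed seed
random_level_roi <- function(dims = c(6, 6, 3), ng = 4, seed = 1, na_frac = 0.2) {
  set.seed(seed)
  A <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  A[sample(prod(dims), round(na_frac * prod(dims)))] <- NA_integer_
  if (all(is.na(A))) A[1] <- 1L
  A
}
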
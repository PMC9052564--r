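# Naive reference implementations used as independent oracles. All are
# written as direct nested loops over array indices, deliberately without
# sharing code with the package internals.

oracle_dirs13 <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dz > 0 | (d$dz == 0 & d$dy > 0) |
    (d$dz == 0 & d$dy == 0 & d$dx > 0)
  as.matrix(d[keep, ])
}

in_grid <- function(p, dm) all(p >= 1) && all(p <= dm)

# symmetric merged co-occurrence counts
oracle_glcm <- function(lev, ng) {
  dm <- dim(lev)
  dirs <- oracle_dirs13()
  counts <- matrix(0, ng, ng)
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    for (r in seq_len(nrow(dirs))) {
      p <- c(x, y, z) + dirs[r, ]
      if (!in_grid(p, dm)) next
      lj <- lev[p[1], p[2], p[3]]
      if (lj == 0) next
      counts[li, lj] <- counts[li, lj] + 1
      counts[lj, li] <- counts[lj, li] + 1
    }
  }
  counts
}

# merged run-length counts: walk each full line in each direction
oracle_glrlm <- function(lev, ng) {
  dm <- dim(lev)
  dirs <- oracle_dirs13()
  counts <- matrix(0, ng, max(dm))
  maxlen <- 1
  for (r in seq_len(nrow(dirs))) {
    dvec <- dirs[r, ]
    for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
      prev <- c(x, y, z) - dvec
      cur <- lev[x, y, z]
      if (cur == 0) next
      if (in_grid(prev, dm) && lev[prev[1], prev[2], prev[3]] == cur) next
      len <- 1
      p <- c(x, y, z) + dvec
      while (in_grid(p, dm) && lev[p[1], p[2], p[3]] == cur) {
        len <- len + 1
        p <- p + dvec
      }
      counts[cur, len] <- counts[cur, len] + 1
      maxlen <- max(maxlen, len)
    }
  }
  counts[, seq_len(maxlen), drop = FALSE]
}

# 26-connected flood fill returning per-zone (level, size, min border dist)
oracle_zones <- function(lev) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  dmap <- oracle_distance_map(lev)
  res <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    lv <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    dmin <- Inf
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      dmin <- min(dmin, dmap[p[1], p[2], p[3]])
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!in_grid(q, dm)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == lv) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    res <- rbind(res, c(lv, size, dmin))
  }
  colnames(res) <- c("level", "size", "distance")
  res
}

# exact Chebyshev distance to outside the ROI by exhaustive search
oracle_distance_map <- function(lev) {
  dm <- dim(lev)
  out <- array(0L, dm)
  bg <- which(lev == 0, arr.ind = TRUE)
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    if (lev[x, y, z] == 0) next
    # distance to grid boundary
    d <- min(x, y, z, dm[1] - x + 1, dm[2] - y + 1, dm[3] - z + 1)
    if (nrow(bg)) {
      dd <- pmax(abs(bg[, 1] - x), pmax(abs(bg[, 2] - y), abs(bg[, 3] - z)))
      d <- min(d, min(dd))
    }
    out[x, y, z] <- d
  }
  out
}

oracle_ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  s <- numeric(ng)
  n <- numeric(ng)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    vals <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_grid(q, dm)) next
      lj <- lev[q[1], q[2], q[3]]
      if (lj > 0) vals <- c(vals, lj)
    }
    if (length(vals)) {
      s[li] <- s[li] + abs(li - mean(vals))
      n[li] <- n[li] + 1
    }
  }
  cbind(s, n)
}

# direct padded-correlation oracle matching the package's centring and
# half-sample symmetric boundary
oracle_filter_1d <- function(x, kernel) {
  n <- length(x)
  L <- length(kernel)
  pl <- (L - 1) %/% 2
  reflect <- function(i) {
    j <- (i - 1) %% (2 * n)
    if (j >= n) 2 * n - 1 - j + 1 else j + 1
  }
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (k in seq_len(L)) acc <- acc + kernel[k] * x[reflect(i + k - 1 - pl)]
    acc
  }, numeric(1))
}

# random discretised test array with background
random_level_array <- function(dims, ng, p_bg = 0.25) {
  a <- array(sample(0:ng, prod(dims), replace = TRUE,
                    prob = c(p_bg, rep((1 - p_bg) / ng, ng))), dim = dims)
  if (all(a == 0)) a[1] <- 1L
  a
}

as_droi <- function(lev, spacing = c(1, 1, 1)) {
  structure(list(levels = lev, n_levels = max(lev), scheme = NULL,
                 spacing_mm = spacing),
            class = "discretised_roi")
}

small_case <- function(seed = 1, n_cases = 4, ...) {
  generate_cohort(synthetic_cohort_config(n_cases = n_cases, seed = seed, ...))
}

# memoised store for expensive shared fixtures
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}
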
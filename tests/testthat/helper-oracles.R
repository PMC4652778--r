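# Independent oracles used against the package implementations. Each is a
# deliberately different algorithm from the production code path.

# Rodrigues rotation of v about unit axis by theta degrees
rotate_about <- function(v, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1, -180, 180)
  function(v) rotate_about(v, axis, theta)
}

# Bottleneck (minimax) barrier by threshold sweep + flood fill: the smallest
# F-level at which start and goal are connected on the allowed 8-neighbour
# graph with periodic columns. Independent of the Dijkstra implementation.
minimax_oracle <- function(F, allowed, from, to) {
  nx <- nrow(F); ny <- ncol(F)
  levels <- sort(unique(F[allowed]))
  levels <- levels[levels >= max(F[from[1], from[2]], F[to[1], to[2]])]
  for (t in levels) {
    open <- allowed & (F <= t)
    if (!open[from[1], from[2]]) next
    # flood fill
    seen <- matrix(FALSE, nx, ny)
    stack <- list(from)
    seen[from[1], from[2]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        i <- cur[1] + dx
        if (i < 1 || i > nx) next
        j <- ((cur[2] + dy - 1) %% ny) + 1
        if (seen[i, j] || !open[i, j]) next
        seen[i, j] <- TRUE
        stack[[length(stack) + 1]] <- c(i, j)
      }
    }
    if (seen[to[1], to[2]]) return(t)
  }
  Inf
}

# Brute-force cluster sizes: all-pairs distances + union-find
cluster_oracle <- function(positions, box, cutoff) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- positions[i, ] - positions[j, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sort(as.integer(table(roots)))
}

# Bin the analytic truth surface on the estimator's lattice
truth_fes <- function(ms, bin_width = 5, cpdb_range = c(-122.5, 122.5),
                      chi_range = c(-182.5, 177.5), temperature = 300) {
  xe <- seq(cpdb_range[1], cpdb_range[2], by = bin_width)
  ye <- seq(chi_range[1], chi_range[2], by = bin_width)
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  yc <- (ye[-1] + ye[-length(ye)]) / 2
  g <- expand.grid(x = xc, y = yc)
  F <- matrix(ms$f(g$x, g$y), length(xc), length(yc))
  fes_grid(xe, ye, F, matrix(TRUE, length(xc), length(yc)), temperature = temperature)
}
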
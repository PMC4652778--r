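# Deoxyribonucleoside aggregation analysis: centre-of-mass cluster statistics
# under a 3.5 Angstrom criterion, the osmotic coefficient
# phi = m_N / m_T = sum_i [A_i] / sum_i i*[A_i], and the equal-K association
# model (1 - phi)/phi^2 = K_A * m_T.

#' A frame of molecular centres of mass
#'
#' @param positions N x 3 numeric matrix of centres of mass, Angstrom.
#' @param box Optional orthorhombic periodic box lengths (3-vector,
#'   Angstrom); `NULL` for non-periodic distances.
#' @return An object of class `com_frame`.
#' @export
com_frame <- function(positions, box = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) >= 1L)
  if (!is.null(box)) {
    stopifnot(length(box) == 3L, all(box > 0))
  }
  structure(list(positions = positions, box = box, n = nrow(positions)),
            class = "com_frame")
}

min_image_dist <- function(positions, box) {
  n <- nrow(positions)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(positions[, k], positions[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d <- d + dk^2
  }
  sqrt(d)
}

#' Cluster-size distribution of one frame
#'
#' Two molecules are associated when their (minimum-image) centre-of-mass
#' distance is within `cutoff`; clusters are the connected components of
#' the resulting graph, so a chain a-b-c is one trimer even when a and c
#' are far apart.
#'
#' @param frame A [com_frame()].
#' @param cutoff Association distance, Angstrom (3.5 by convention).
#' @return An object of class `cluster_size_distribution` with `counts`
#'   (named integer vector: number of i-mers per size i), `n_molecules`
#'   and `n_clusters`.
#' @export
cluster_sizes <- function(frame, cutoff = 3.5) {
  stopifnot(inherits(frame, "com_frame"), cutoff > 0)
  n <- frame$n
  if (n == 1L) {
    sizes <- 1L
  } else {
    d <- min_image_dist(frame$positions, frame$box)
    adj <- (d <= cutoff)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    sizes <- igraph::components(g)$csize
  }
  tab <- table(sizes)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, n_molecules = n, n_clusters = length(sizes)),
            class = "cluster_size_distribution")
}

#' Osmotic coefficient from cluster counts
#'
#' `phi = sum_i [A_i] / sum_i i * [A_i]`: with per-frame counts standing
#' in for molal concentrations (the solvent-mass factor cancels), this is
#' the number of clusters divided by the number of molecules. A list of
#' distributions is averaged frame-wise.
#'
#' @param dist A `cluster_size_distribution` or a list of them.
#' @return phi, dimensionless in `(0, 1]`.
#' @examples
#' # 16 molecules as 8 dimers: phi = 8/16 = 0.5
#' @export
osmotic_coefficient <- function(dist) {
  if (inherits(dist, "cluster_size_distribution")) dist <- list(dist)
  phi <- vapply(dist, function(d) {
    sizes <- as.integer(names(d$counts))
    sum(d$counts) / sum(sizes * d$counts)
  }, numeric(1))
  mean(phi)
}

#' Fit the equal-K association constant
#'
#' Under the equal-K model every association step shares one constant and
#' `(1 - phi)/phi^2 = K_A * m_T`; K_A is the least-squares slope through
#' the origin of `y = (1 - phi)/phi^2` against `m_T`.
#'
#' @param points Data frame with columns `m_T` (molal) and `phi`.
#' @param weights Optional least-squares weights (default unweighted).
#' @return An object of class `equal_k_fit` with `K_A` (molal^-1) and
#'   `residual` (root mean square of `y - K_A * m_T`).
#' @export
fit_equal_k <- function(points, weights = NULL) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("m_T", "phi") %in% names(points)))
  phi <- points$phi
  m <- points$m_T
  if (any(phi <= 0 | phi > 1)) {
    stop("fit_equal_k: the transform (1 - phi)/phi^2 requires phi in (0, 1]")
  }
  if (any(m <= 0)) stop("fit_equal_k: m_T must be > 0")
  w <- if (is.null(weights)) rep(1, length(m)) else weights
  y <- (1 - phi) / phi^2
  K <- sum(w * m * y) / sum(w * m^2)
  structure(list(K_A = max(K, 0), residual = sqrt(mean((y - K * m)^2))),
            class = "equal_k_fit")
}

#' @export
print.equal_k_fit <- function(x, ...) {
  cat(sprintf("equal-K fit: K_A = %.4g molal^-1 (rms residual %.3g)\n", x$K_A, x$residual))
  invisible(x)
}

#' Osmotic coefficient predicted by the equal-K model
#'
#' Inverts `(1 - phi)/phi^2 = K_A m_T`:
#' `phi = (-1 + sqrt(1 + 4 K_A m_T)) / (2 K_A m_T)`, with `phi = 1` in
#' the no-association limit `K_A = 0`.
#'
#' @param K_A Association constant, molal^-1 (>= 0).
#' @param m_T Total monomer molality (> 0); vectorised.
#' @return phi in `(0, 1]`.
#' @export
predict_phi <- function(K_A, m_T) {
  stopifnot(K_A >= 0, all(m_T > 0))
  if (K_A == 0) return(rep(1, length(m_T)))
  r <- K_A * m_T
  (-1 + sqrt(1 + 4 * r)) / (2 * r)
}

# Equal-K i-mer cluster-level distribution at total molality m_T:
# [A_i] = m1 (K m1)^(i-1), geometric in u = K m1 with m_T = m1/(1-u)^2.
equal_k_u <- function(K_A, m_T) {
  r <- K_A * m_T
  if (r == 0) return(0)
  (2 * r + 1 - sqrt(4 * r + 1)) / (2 * r)
}

#' Synthetic equilibrium aggregation data with known K_A
#'
#' For each total molality, draws per-frame cluster-size configurations
#' of `n_molecules` molecules from the equal-K equilibrium distribution:
#' cluster sizes are geometric in `u = K_A * m1` (the monomer activity
#' solved from `m_T = m1 / (1 - u)^2`), realised as run lengths of
#' independent cluster boundaries between the N molecules of a frame.
#' Partitioning a finite frame this way has expected osmotic coefficient
#' `(1 - u) + u/N` (the last molecule always closes a cluster), so the
#' boundary probability uses `u' = u N/(N-1)`, which makes the expected
#' per-frame phi equal the equal-K model value exactly. Optionally also
#' realises the first frames geometrically: cluster members placed
#' within the association cutoff of a chain, clusters far apart in a
#' periodic box, so that [cluster_sizes()] reproduces the drawn
#' configuration.
#'
#' @param K_A Designed association constant, molal^-1.
#' @param m_T Vector of total molalities; the defaults are the two
#'   conventional deoxyribonucleoside concentration sets 0.0450/0.0375/
#'   0.0300 m (dA) and 0.20/0.15/0.10 m (dT) combined as chosen.
#' @param n_frames Frames per concentration.
#' @param n_molecules Molecules per frame (16 by convention).
#' @param seed Integer seed (bit-reproducible output).
#' @param geometric Also return `com_frame` realisations of the first
#'   `min(n_frames, 5)` frames per concentration.
#' @param cutoff Association cutoff used for the geometric mode, Angstrom.
#' @return A data frame of class `osmotic_points` with columns `m_T`,
#'   `phi` (frame-averaged), `phi_se` (standard error over frames); when
#'   `geometric` is set, an attribute `frames` holds the realisations.
#' @export
make_aggregation_points <- function(K_A, m_T = c(0.0450, 0.0375, 0.0300),
                                    n_frames = 2000, n_molecules = 16, seed = 1,
                                    geometric = FALSE, cutoff = 3.5) {
  stopifnot(K_A >= 0, all(m_T > 0), n_frames >= 1, n_molecules >= 1)
  set.seed(as.integer(seed))
  draw_frame <- function(u) {
    if (u == 0 || n_molecules == 1L) return(rep(1L, n_molecules))
    u_adj <- min(u * n_molecules / (n_molecules - 1), 0.999)
    # cluster boundaries between adjacent molecules; run lengths are the sizes
    open_bond <- stats::runif(n_molecules - 1L) < u_adj
    bounds <- which(!open_bond)
    diff(c(0L, bounds, n_molecules))
  }
  frames_out <- list()
  rows <- lapply(m_T, function(m) {
    u <- equal_k_u(K_A, m)
    phis <- numeric(n_frames)
    geo <- list()
    for (fidx in seq_len(n_frames)) {
      sizes <- draw_frame(u)
      phis[fidx] <- length(sizes) / n_molecules
      if (geometric && fidx <= min(n_frames, 5L)) {
        geo[[fidx]] <- realize_cluster_frame(sizes, cutoff)
      }
    }
    if (geometric) frames_out[[as.character(m)]] <<- geo
    data.frame(m_T = m, phi = mean(phis),
               phi_se = stats::sd(phis) / sqrt(n_frames))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("osmotic_points", "data.frame")
  if (geometric) attr(out, "frames") <- frames_out
  out
}

# place clusters as tight chains (spacing 0.8 * cutoff) on a lattice with
# generous separation inside a periodic box
realize_cluster_frame <- function(sizes, cutoff) {
  spacing <- 0.8 * cutoff
  sep <- 6 * cutoff
  k <- length(sizes)
  side <- ceiling(sqrt(k))
  pos <- matrix(NA_real_, sum(sizes), 3L)
  row <- 1L
  for (ci in seq_len(k)) {
    ox <- ((ci - 1L) %% side) * sep
    oy <- ((ci - 1L) %/% side) * sep
    for (s in seq_len(sizes[ci])) {
      pos[row, ] <- c(ox, oy, (s - 1L) * spacing)
      row <- row + 1L
    }
  }
  box_len <- side * sep + max(sizes) * spacing + sep
  com_frame(pos, box = rep(box_len, 3L))
}
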
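# Topography of the estimated surface: local minima, minimax (lowest-saddle)
# transition states on the 8-connected bin graph with periodic chi, the
# WC/HG/LS basin labelling, the six-route pathway taxonomy
# (clockwise/counterclockwise chi rotation x small/major/minor base flipping),
# and the cumulative-time convergence diagnostic.

critical_point <- function(kind, cpdb, chi, F, ix = NA_integer_, iy = NA_integer_) {
  structure(list(kind = kind, cpdb = cpdb, chi = chi, F = F,
                 ix = as.integer(ix), iy = as.integer(iy)),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("%s at (CPDb = %.1f, chi = %.1f), F = %.2f kcal/mol\n",
              x$kind, x$cpdb, x$chi, x$F))
  invisible(x)
}

neighbor_offsets <- expand.grid(dx = -1:1, dy = -1:1)
neighbor_offsets <- neighbor_offsets[!(neighbor_offsets$dx == 0 & neighbor_offsets$dy == 0), ]

#' Local minima of a free-energy surface
#'
#' A bin is a minimum when it is strictly lower than every sampled
#' 8-neighbour (chi neighbours wrap periodically; CPDb does not). Minima
#' within one bin of each other are merged keeping the lower (ties broken
#' by lexicographic (CPDb, chi) order); the result is sorted by F.
#'
#' @param fes A [fes_grid()].
#' @return List of `critical_point` objects of kind `"minimum"`.
#' @export
find_minima <- function(fes) {
  F <- fes$F
  S <- fes$sampled
  nx <- nrow(F); ny <- ncol(F)
  mins <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (!S[i, j]) next
      lower <- TRUE
      for (k in seq_len(nrow(neighbor_offsets))) {
        ii <- i + neighbor_offsets$dx[k]
        jj <- ((j + neighbor_offsets$dy[k] - 1L) %% ny) + 1L
        if (ii < 1L || ii > nx || !S[ii, jj]) next
        if (F[ii, jj] <= F[i, j]) { lower <- FALSE; break }
      }
      if (lower) {
        mins[[length(mins) + 1L]] <- critical_point("minimum",
          fes$cpdb_centers[i], fes$chi_centers[j], F[i, j], i, j)
      }
    }
  }
  if (length(mins) <= 1L) return(mins)
  # merge minima within one bin (Chebyshev, periodic chi)
  ord <- order(vapply(mins, function(m) m$F, numeric(1)),
               vapply(mins, function(m) m$cpdb, numeric(1)),
               vapply(mins, function(m) m$chi, numeric(1)))
  mins <- mins[ord]
  kept <- list()
  for (m in mins) {
    dup <- any(vapply(kept, function(k) {
      abs(k$ix - m$ix) <= 1L && min((k$iy - m$iy) %% ny, (m$iy - k$iy) %% ny) <= 1L
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- m
  }
  kept
}

#' Minimax (lowest-saddle) path between two bins
#'
#' Bottleneck shortest path on the 8-connected graph of allowed bins with
#' periodic chi: among all connecting paths, the one whose maximum F is
#' smallest (Dijkstra on the bottleneck metric). The path cost includes
#' both endpoints.
#'
#' @param fes A [fes_grid()].
#' @param from,to Bin indices `c(ix, iy)`.
#' @param allowed Logical matrix of admissible bins; defaults to the
#'   sampled mask.
#' @return `NULL` when no path exists, otherwise a list with `path`
#'   (matrix of bin indices), `barrier_F` (the bottleneck value) and
#'   `ts_index` (position of the maximum along the path).
#' @export
minimax_path <- function(fes, from, to, allowed = NULL) {
  F <- fes$F
  S <- if (is.null(allowed)) fes$sampled else (fes$sampled & allowed)
  nx <- nrow(F); ny <- ncol(F)
  idx <- function(i, j) (j - 1L) * nx + i
  u0 <- idx(from[1L], from[2L]); v0 <- idx(to[1L], to[2L])
  if (!S[from[1L], from[2L]] || !S[to[1L], to[2L]]) return(NULL)
  n <- nx * ny
  dist <- rep(Inf, n)
  cost <- rep(Inf, n)   # accumulated F, tie-break so equal-bottleneck paths prefer valleys
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[u0] <- F[from[1L], from[2L]]
  cost[u0] <- F[from[1L], from[2L]]
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    if (u == v0) break
    done[u] <- TRUE
    i <- ((u - 1L) %% nx) + 1L
    j <- ((u - 1L) %/% nx) + 1L
    for (k in seq_len(nrow(neighbor_offsets))) {
      ii <- i + neighbor_offsets$dx[k]
      if (ii < 1L || ii > nx) next
      jj <- ((j + neighbor_offsets$dy[k] - 1L) %% ny) + 1L
      if (!S[ii, jj]) next
      v <- idx(ii, jj)
      if (done[v]) next
      nd <- max(dist[u], F[ii, jj])
      nc <- cost[u] + F[ii, jj]
      if (nd < dist[v] || (nd == dist[v] && nc < cost[v])) {
        dist[v] <- nd
        cost[v] <- nc
        parent[v] <- u
      }
    }
  }
  if (!is.finite(dist[v0])) return(NULL)
  # reconstruct
  path <- integer(0)
  v <- v0
  while (!is.na(v)) {
    path <- c(v, path)
    v <- parent[v]
    if (length(path) > n) stop("minimax_path: cycle in parent chain")
  }
  pij <- cbind(ix = ((path - 1L) %% nx) + 1L, iy = ((path - 1L) %/% nx) + 1L)
  Fs <- F[pij]
  list(path = pij, barrier_F = dist[v0], ts_index = which.max(Fs))
}

#' Transition state between two minima
#'
#' The highest bin on the minimax path between the two minima over the
#' sampled 8-connected grid.
#'
#' @param fes A [fes_grid()].
#' @param a,b `critical_point` minima (or basin labels).
#' @return A `critical_point` of kind `"transition_state"`.
#' @export
find_ts <- function(fes, a, b) {
  a <- as_point(a); b <- as_point(b)
  mp <- minimax_path(fes, point_bin(fes, a), point_bin(fes, b))
  if (is.null(mp)) stop("find_ts: basins are not connected on the sampled grid")
  k <- mp$ts_index
  critical_point("transition_state",
                 fes$cpdb_centers[mp$path[k, 1L]], fes$chi_centers[mp$path[k, 2L]],
                 fes$F[mp$path[k, , drop = FALSE]],
                 mp$path[k, 1L], mp$path[k, 2L])
}

as_point <- function(x) if (inherits(x, "basin_label")) x$point else x

point_bin <- function(fes, p) {
  if (!is.na(p$ix)) return(c(p$ix, p$iy))
  c(which.min(abs(fes$cpdb_centers - p$cpdb)),
    which.min(abs(angle_diff(fes$chi_centers, p$chi))))
}

#' Label minima as WC, HG, LS or other
#'
#' WC is the lowest minimum with an anti glycosidic angle and little base
#' flipping (|CPDb| at most `flip_small`); HG the lowest syn minimum with
#' little flipping; LS any syn minimum flipped into the minor groove
#' (CPDb at or below `ls_cut`). Everything else is labelled `other`.
#'
#' @param minima List of `critical_point` minima, e.g. [find_minima()].
#' @param flip_small Small-flipping cutoff, degrees.
#' @param ls_cut Minor-groove cutoff for the LS intermediate, degrees.
#' @return List of `basin_label` objects (`label`, `point`). Emits a
#'   warning (labels still returned) when no anti minimum exists.
#' @export
label_basins <- function(minima, flip_small = 20, ls_cut = -40) {
  stopifnot(length(minima) >= 1L)
  cls <- vapply(minima, function(m) classify_chi(m$chi), character(1))
  cpdb <- vapply(minima, function(m) m$cpdb, numeric(1))
  F <- vapply(minima, function(m) m$F, numeric(1))
  labels <- rep("other", length(minima))
  wc_cand <- which(cls == "anti" & abs(cpdb) <= flip_small)
  if (length(wc_cand)) labels[wc_cand[which.min(F[wc_cand])]] <- "WC"
  hg_cand <- which(cls == "syn" & abs(cpdb) <= flip_small)
  if (length(hg_cand)) labels[hg_cand[which.min(F[hg_cand])]] <- "HG"
  ls_cand <- which(cls == "syn" & cpdb <= ls_cut & labels == "other")
  if (length(ls_cand)) labels[ls_cand[which.min(F[ls_cand])]] <- "LS"
  if (!any(labels == "WC")) {
    warning("label_basins: surface has no anti minimum (no WC basin)")
  }
  lapply(seq_along(minima), function(i) {
    structure(list(label = labels[i], point = minima[[i]]), class = "basin_label")
  })
}

#' @export
print.basin_label <- function(x, ...) {
  cat(x$label, ": ")
  print(x$point)
  invisible(x)
}

#' Classify a transition path into the six-route taxonomy
#'
#' The rotation sense is the sign of the net wrapped chi travel from
#' start to end: net decrease (through the +-180 seam) is clockwise (R),
#' net increase counterclockwise (L). The flipping class is 1 (small)
#' when max |CPDb| along the path is at most `small_cut`, 2 (large, major
#' groove) when max CPDb reaches `large_cut`, 3 (large, minor groove)
#' when min CPDb reaches `-large_cut`, otherwise unclassified.
#'
#' @param path A `transition_path` or a matrix/data.frame with columns
#'   cpdb, chi ordered along the path.
#' @param small_cut,large_cut Flipping cutoffs, degrees.
#' @return A label: `"R1"`, `"R2"`, `"R3"`, `"L1"`, `"L2"`, `"L3"` or
#'   `"unclassified"`.
#' @export
classify_path <- function(path, small_cut = 20, large_cut = 60) {
  pts <- if (inherits(path, "transition_path")) path$points else as.data.frame(path)
  stopifnot(nrow(pts) >= 1L)
  chi <- pts$chi
  net <- if (length(chi) > 1L) sum(angle_diff(chi[-1L], chi[-length(chi)])) else 0
  dir <- if (net < 0) "R" else "L"
  cpdb <- pts$cpdb
  size <- if (max(abs(cpdb)) <= small_cut) "1"
          else if (max(cpdb) >= large_cut) "2"
          else if (min(cpdb) <= -large_cut) "3"
          else return("unclassified")
  paste0(dir, size)
}

route_mask <- function(fes, wc_chi, hg_chi, direction, size,
                       small_cut, large_cut, transit_halfwidth) {
  xc <- fes$cpdb_centers
  yc <- fes$chi_centers
  near_basin <- abs(angle_diff(yc, wc_chi)) <= transit_halfwidth |
                abs(angle_diff(yc, hg_chi)) <= transit_halfwidth
  tpos <- (yc - wc_chi) %% 360
  Tend <- (hg_chi - wc_chi) %% 360
  in_ccw <- tpos > 0 & tpos < Tend
  in_cw <- tpos > Tend
  arc_ok <- if (direction == "R") in_cw else in_ccw
  allowed <- matrix(FALSE, length(xc), length(yc))
  for (j in seq_along(yc)) {
    if (near_basin[j]) {
      ok <- switch(size,
                   small = abs(xc) <= small_cut,
                   major = xc >= -small_cut,
                   minor = xc <= small_cut)
    } else if (arc_ok[j]) {
      ok <- switch(size,
                   small = abs(xc) <= small_cut,
                   major = xc >= large_cut,
                   minor = xc <= -large_cut)
    } else {
      ok <- rep(FALSE, length(xc))
    }
    allowed[, j] <- ok
  }
  allowed
}

make_transition_path <- function(fes, mp, wc, hg, ls, small_cut, large_cut) {
  pts <- data.frame(cpdb = fes$cpdb_centers[mp$path[, 1L]],
                    chi = fes$chi_centers[mp$path[, 2L]],
                    F = fes$F[mp$path])
  k <- mp$ts_index
  ts <- critical_point("transition_state", pts$cpdb[k], pts$chi[k], pts$F[k],
                       mp$path[k, 1L], mp$path[k, 2L])
  sub_ts <- NULL
  if (!is.null(ls)) {
    lp <- as_point(ls)
    ny <- ncol(fes$F)
    hit <- which(abs(mp$path[, 1L] - lp$ix) <= 1L &
                 pmin((mp$path[, 2L] - lp$iy) %% ny, (lp$iy - mp$path[, 2L]) %% ny) <= 1L)
    if (length(hit)) {
      m <- hit[which.min(pts$F[hit])]
      if (m > 1L && m < nrow(pts)) {
        k1 <- which.max(pts$F[seq_len(m)])
        k2 <- m - 1L + which.max(pts$F[m:nrow(pts)])
        sub_ts <- list(
          ts1 = critical_point("transition_state", pts$cpdb[k1], pts$chi[k1], pts$F[k1],
                               mp$path[k1, 1L], mp$path[k1, 2L]),
          ts2 = critical_point("transition_state", pts$cpdb[k2], pts$chi[k2], pts$F[k2],
                               mp$path[k2, 1L], mp$path[k2, 2L]))
      }
    }
  }
  structure(list(points = pts, start = wc, end = hg, ts = ts, sub_ts = sub_ts,
                 forward_barrier = ts$F - as_point(wc)$F,
                 reverse_barrier = ts$F - as_point(hg)$F,
                 class = classify_path(pts, small_cut, large_cut)),
            class = "transition_path")
}

#' @export
print.transition_path <- function(x, ...) {
  cat(sprintf("transition_path %s: %d bins, TS (%.1f, %.1f) F = %.2f, forward barrier %.2f kcal/mol\n",
              x$class, nrow(x$points), x$ts$cpdb, x$ts$chi, x$ts$F, x$forward_barrier))
  if (!is.null(x$sub_ts)) {
    cat(sprintf("  via intermediate: TS1 F = %.2f, TS2 F = %.2f kcal/mol\n",
                x$sub_ts$ts1$F, x$sub_ts$ts2$F))
  }
  invisible(x)
}

#' Extract the six WC <-> HG transition routes
#'
#' For each combination of rotation sense (clockwise R / counterclockwise
#' L, judged by which side of the chi circle the rotation crosses) and
#' flipping class (small: the whole path confined to |CPDb| at most
#' `small_cut`; large via the major or the minor groove: the chi rotation
#' segment forced beyond `large_cut` on that side), the minimax path
#' within the constraint region is computed together with its transition
#' state and barriers. Routes through the LS intermediate additionally
#' report the two sub-transition-states flanking it. A constraint set
#' with no connected path is reported absent (`NULL`).
#'
#' @param fes A [fes_grid()].
#' @param wc,hg `basin_label`s (or minima) of the WC and HG states.
#' @param ls Optional LS `basin_label` for sub-TS reporting.
#' @param small_cut,large_cut Flipping cutoffs, degrees.
#' @param transit_halfwidth Half-width (degrees) of the chi sectors
#'   around each basin treated as basin territory rather than rotation
#'   transit when applying the flipping constraints.
#' @return Named list (`R1`, `R2`, `R3`, `L1`, `L2`, `L3`) of
#'   `transition_path` objects or `NULL` for absent routes.
#' @export
extract_paths <- function(fes, wc, hg, ls = NULL,
                          small_cut = 20, large_cut = 60, transit_halfwidth = 25) {
  wcp <- as_point(wc); hgp <- as_point(hg)
  from <- point_bin(fes, wcp); to <- point_bin(fes, hgp)
  routes <- expand.grid(direction = c("R", "L"), size = c("small", "major", "minor"),
                        stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(routes))) {
    dir <- routes$direction[r]; size <- routes$size[r]
    name <- paste0(dir, match(size, c("small", "major", "minor")))
    mask <- route_mask(fes, wcp$chi, hgp$chi, dir, size,
                       small_cut, large_cut, transit_halfwidth)
    mp <- minimax_path(fes, from, to, allowed = mask)
    out[[name]] <- if (is.null(mp)) NULL else
      make_transition_path(fes, mp, wc, hg, if (size == "minor") ls else NULL,
                           small_cut, large_cut)
  }
  out[c("R1", "R2", "R3", "L1", "L2", "L3")]
}

#' Free-energy difference between two labelled basins
#'
#' `F(b) - F(a)` at the basin minima; positive when `b` lies above `a`.
#'
#' @param fes A [fes_grid()] (used only for validation).
#' @param a,b `basin_label`s or minima.
#' @return kcal/mol.
#' @export
delta_g <- function(fes, a, b) {
  as_point(b)$F - as_point(a)$F
}

#' Cumulative-time convergence of the estimated surface
#'
#' Re-estimates the surface from the first `ceiling(fraction * n)`
#' samples of every window (samples are stored in time order) and
#' reports, for each fraction, the RMS deviation from the full-data
#' surface over bins sampled in both, after aligning the two surfaces by
#' their mean difference on the common bins. The conventional acceptance
#' threshold kB*T at the stated temperature is reported alongside.
#'
#' @param ensembles List of [biased_ensemble()] objects.
#' @param fractions Ascending fractions ending at 1.
#' @param ... Passed to [wham2d()] (bin width, temperature, tolerances).
#' @return A list of class `convergence_report`: `fractions`, `rms`
#'   (kcal/mol), `threshold` (kB*T), `temperature`.
#' @export
convergence_report <- function(ensembles, fractions = c(0.25, 0.5, 0.75, 1), ...) {
  stopifnot(!is.unsorted(fractions), isTRUE(all.equal(fractions[length(fractions)], 1)))
  args <- list(...)
  full <- wham2d(ensembles, ...)
  # freeze the binning so cumulative surfaces are bin-compatible
  if (is.null(args$cpdb_range)) {
    args$cpdb_range <- range(full$fes$cpdb_edges)
  }
  temperature <- if (is.null(args$temperature)) 300 else args$temperature
  rms <- vapply(fractions, function(fr) {
    if (isTRUE(all.equal(fr, 1))) return(0)
    sub <- lapply(ensembles, function(e) {
      k <- ceiling(fr * e$n)
      if (k < 1L) stop("convergence_report: fraction ", fr,
                       " leaves window ", e$window$id, " empty")
      biased_ensemble(e$window, e$samples[seq_len(k), , drop = FALSE])
    })
    part <- do.call(wham2d, c(list(sub), args, list(init_f = full$wham$window_shifts)))
    common <- full$fes$sampled & part$fes$sampled
    d <- part$fes$F[common] - full$fes$F[common]
    d <- d - mean(d)
    sqrt(mean(d^2))
  }, numeric(1))
  structure(list(fractions = fractions, rms = rms,
                 threshold = KCAL_R * temperature, temperature = temperature),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("cumulative-time convergence (RMS vs full surface, kcal/mol):\n")
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %4.0f%%  %.4f\n", 100 * x$fractions[i], x$rms[i]))
  }
  cat(sprintf("  threshold kB*T at %g K: %.4f kcal/mol\n", x$temperature, x$threshold))
  invisible(x)
}
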
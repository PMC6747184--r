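#' Reweighting scheme
#'
#' How to undo the aMD boost when histogramming observables:
#' `"maclaurin"` uses the truncated series
#' \eqn{w = \sum_{k=0}^{K} (\beta\Delta V)^k / k!} (equivalent to a
#' first-order cumulant expansion at K = 1 and approaching the exponential
#' from below as K grows); `"exponential"` uses the exact
#' \eqn{w = e^{\beta\Delta V}}; `"cumulant2"` applies the second-order
#' cumulant correction per bin,
#' \eqn{\exp(\beta\langle\Delta V\rangle_{bin} + \beta^2\sigma^2_{bin}/2)},
#' which is exact when the boost is Gaussian within each bin.
#'
#' @param method One of `"maclaurin"`, `"exponential"`, `"cumulant2"`.
#' @param K Maclaurin truncation order (default 10).
#' @param temperature Temperature in K defining \eqn{\beta = 1/kT}.
#' @return A `reweight_scheme` list.
#' @export
reweight_scheme <- function(method = c("maclaurin", "exponential", "cumulant2"),
                            K = 10, temperature = 300) {
  method <- match.arg(method)
  stopifnot(K >= 1, temperature > 0)
  structure(list(method = method, K = as.integer(K),
                 temperature = temperature, kT = KB_KCAL * temperature),
            class = "reweight_scheme")
}

#' Per-frame reweighting factors
#'
#' @param delta_V Non-negative boost energy per frame (kcal mol^-1).
#' @param scheme A [reweight_scheme()]; `"cumulant2"` is a bin-level method
#'   and is rejected here.
#' @return Strictly positive weights, one per frame.
#' @examples
#' s <- reweight_scheme("maclaurin", K = 10)
#' frame_weights(kT(300), s)  # beta dV = 1: truncated e = 2.7182818
#' @export
frame_weights <- function(delta_V, scheme) {
  stopifnot(inherits(scheme, "reweight_scheme"))
  if (any(delta_V < 0)) stop("boost energies must be non-negative")
  b <- delta_V / scheme$kT
  switch(scheme$method,
    exponential = exp(b),
    maclaurin = {
      w <- rep(1, length(b))
      term <- rep(1, length(b))
      for (k in seq_len(scheme$K)) {
        term <- term * b / k
        w <- w + term
      }
      w
    },
    cumulant2 = stop("cumulant2 is a bin-level method; use reweighted_pmf()"))
}

fes_new <- function(edges, prob, counts, kT) {
  dims <- length(edges)
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  pmf <- -kT * log(prob)
  pmf[counts == 0] <- NA_real_
  pmf <- pmf - min(pmf, na.rm = TRUE)
  structure(list(edges = edges, centers = centers, prob = prob,
                 pmf = pmf, counts = counts, kT = kT, dims = dims),
            class = "fe_surface")
}

#' @export
print.fe_surface <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat("<fe_surface>", x$dims, "D,", occ, "occupied bins,",
      sprintf("kT = %.4f kcal/mol\n", x$kT))
  if (!is.null(attr(x, "flat"))) cat("  note: all frames in one bin\n")
  invisible(x)
}

bin_edges <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1] - 1e-9 * max(1, abs(r[1])), r[2] + 1e-9 * max(1, abs(r[2])),
      length.out = bins + 1)
}

#' Reweighted probability and PMF over a reaction coordinate
#'
#' Histograms a 1-D or 2-D coordinate with aMD reweighting and returns the
#' normalised probability and the PMF \eqn{-kT \ln p}, minimum-shifted to
#' zero. Empty bins carry `NA` PMF (flagged, not zero energy).
#'
#' @param coordinate Numeric vector (1-D) or two-column matrix (2-D),
#'   one row/element per frame.
#' @param delta_V Per-frame boost (kcal mol^-1); `NULL` or all zero means
#'   unweighted.
#' @param bins Bin count per axis (default 50 in 1-D, 60 in 2-D), or a
#'   list of explicit break vectors.
#' @param scheme A [reweight_scheme()].
#' @return An `fe_surface` with `edges`, `centers`, `prob`, `pmf`,
#'   `counts`, `kT`.
#' @export
reweighted_pmf <- function(coordinate, delta_V = NULL,
                           bins = NULL, scheme = reweight_scheme()) {
  stopifnot(inherits(scheme, "reweight_scheme"))
  coord <- if (is.matrix(coordinate)) coordinate else matrix(coordinate, ncol = 1)
  nfr <- nrow(coord)
  d <- ncol(coord)
  if (!d %in% 1:2) stop("coordinate must be 1-D or 2-D")
  if (is.null(delta_V)) delta_V <- numeric(nfr)
  if (length(delta_V) != nfr)
    stop("coordinate and delta_V must be aligned frame-by-frame")
  if (any(delta_V < 0)) stop("boost energies must be non-negative")
  if (is.null(bins)) bins <- if (d == 1) 50 else 60
  edges <- if (is.list(bins)) bins else
    lapply(seq_len(d), function(j) bin_edges(coord[, j], bins[min(j, length(bins))]))
  idx <- lapply(seq_len(d), function(j)
    findInterval(coord[, j], edges[[j]], rightmost.closed = TRUE,
                 all.inside = TRUE))
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  flat_idx <- if (d == 1) idx[[1]] else (idx[[2]] - 1L) * nb[1] + idx[[1]]
  counts <- tabulate(flat_idx, nbins = prod(nb))

  if (scheme$method == "cumulant2") {
    b <- 1 / scheme$kT
    m <- rep(0, prod(nb)); s2 <- rep(0, prod(nb))
    grp <- split(delta_V, flat_idx)
    gi <- as.integer(names(grp))
    m[gi] <- vapply(grp, mean, 0)
    s2[gi] <- vapply(grp, function(v) if (length(v) > 1) stats::var(v) else 0, 0)
    w_bin <- exp(b * m + b^2 * s2 / 2)
    p <- counts * w_bin
  } else {
    w <- frame_weights(delta_V, scheme)
    p <- numeric(prod(nb))
    sums <- rowsum(w, flat_idx)
    p[as.integer(rownames(sums))] <- sums
  }
  p <- p / sum(p)
  if (d == 2) {
    p <- matrix(p, nb[1], nb[2])
    counts <- matrix(counts, nb[1], nb[2])
  }
  fes <- fes_new(edges, p, counts, scheme$kT)
  if (sum(counts > 0) == 1) attr(fes, "flat") <- TRUE
  fes
}

## Locate basins in a 1-D PMF: the two deepest local minima and the
## barrier between them; basin free energies integrate the probability on
## each side of the barrier.
find_basins <- function(fes) {
  stopifnot(fes$dims == 1)
  pmf <- fes$pmf
  x <- fes$centers[[1]]
  ok <- which(!is.na(pmf))
  if (length(ok) < 2)
    return(list(n_basins = length(ok),
                minima = x[ok], barrier = NA_real_, delta_G = NA_real_))
  ## local minima over the occupied bins (runs of NA split segments)
  v <- pmf
  v[is.na(v)] <- Inf
  n <- length(v)
  is_min <- vapply(seq_len(n), function(i) {
    if (!is.finite(v[i])) return(FALSE)
    left <- if (i > 1) v[i - 1] else Inf
    right <- if (i < n) v[i + 1] else Inf
    v[i] <= left && v[i] <= right
  }, TRUE)
  mins <- which(is_min)
  if (length(mins) < 2)
    return(list(n_basins = 1L, minima = x[which.min(v)],
                barrier = NA_real_, delta_G = NA_real_))
  ord <- mins[order(v[mins])][1:2]
  lo <- min(ord); hi <- max(ord)
  bar_idx <- lo + which.max(v[lo:hi]) - 1L
  split_at <- bar_idx
  pA <- sum(fes$prob[seq_len(split_at - 1)])
  pB <- sum(fes$prob[split_at:n])
  ## report basins ordered by position (left basin first)
  list(n_basins = 2L,
       minima = sort(x[ord]),
       minima_pmf = v[ord][order(x[ord])],
       barrier = v[bar_idx] - min(v[ord]),
       barrier_x = x[bar_idx],
       prob_left = pA, prob_right = pB,
       delta_G = -fes$kT * log(pA / pB))
}

#' End-to-end distance PMF with basin analysis
#'
#' Composes [end_to_end_distance()] with [reweighted_pmf()] and reports
#' the two deepest basins (minima positions and PMF values, the barrier
#' between them, and the basin free-energy difference
#' \eqn{\Delta G = -kT \ln(P_{left}/P_{right})} from integrated basin
#' probabilities).
#'
#' @param traj A `Trajectory`.
#' @param top A `Topology` with resolvable terminal CA atoms.
#' @param delta_V Optional per-frame boost series.
#' @param scheme A [reweight_scheme()].
#' @param bins Bin count (default 50).
#' @return List with `fes` (the `fe_surface`), `distance` (the series) and
#'   `basins` (see above).
#' @export
pmf_1d_end_to_end <- function(traj, top, delta_V = NULL,
                              scheme = reweight_scheme(), bins = 50) {
  dist <- end_to_end_distance(traj, top)
  fes <- reweighted_pmf(dist, delta_V, bins = bins, scheme = scheme)
  list(fes = fes, distance = dist, basins = find_basins(fes))
}
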
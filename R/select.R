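#' Loess smoothing of community counts over the rank grid
#'
#' Locally weighted quadratic regression (tricube weights, direct surface so
#' the fit is deterministic and exact for polynomials up to the local
#' degree), evaluated at the distinct grid points.
#'
#' @param k numeric vector of rank values (replicate points allowed).
#' @param y community counts at those points.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return data.frame with `k` (sorted distinct values) and `fitted`.
#' @export
loess_smooth <- function(k, y, span = 0.75, degree = 2) {
  ku <- sort(unique(k))
  if (length(ku) < 4) stop("need at least 4 distinct k values")
  # small grids need a wider neighborhood than the default span provides
  span <- max(span, (degree + 2) / length(ku))
  fit <- loess(y ~ k, data = data.frame(k = k, y = y), span = span,
               degree = degree, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  data.frame(k = ku, fitted = as.numeric(predict(fit, newdata =
                                                   data.frame(k = ku))))
}

#' Inflection (elbow) of a smoothed community curve
#'
#' Draws the chord from the first to the last smoothed point and takes the
#' vertical residual `r(k) = smoothed(k) - chord(k)`; the inflection `k*` is
#' the leftmost maximizer. Residuals beyond `k*` are the "cost values" used
#' by the Jaccard-length slope rule.
#'
#' @param k sorted distinct rank values (>= 3).
#' @param smoothed fitted curve values at `k`.
#' @return list with `k_star`, `residuals` (full profile), `cost`
#'   (data.frame of `k > k_star` and their residuals) and `degenerate`
#'   (TRUE when the curve is essentially linear/non-concave).
#' @export
find_inflection <- function(k, smoothed) {
  stopifnot(length(k) == length(smoothed))
  if (length(k) < 3) stop("need at least 3 points")
  n <- length(k)
  slope <- (smoothed[n] - smoothed[1]) / (k[n] - k[1])
  chord <- smoothed[1] + slope * (k - k[1])
  res <- smoothed - chord
  i_star <- which.max(res)              # leftmost on ties
  degenerate <- max(res) <= 1e-8 * max(1, diff(range(smoothed)))
  post <- k > k[i_star]
  list(k_star = k[i_star],
       residuals = setNames(res, k),
       cost = data.frame(k = k[post], cost = res[post]),
       degenerate = degenerate)
}

#' Select the Jaccard length by the post-inflection slope rule
#'
#' For each community curve, ordinary least squares of the cost values
#' (chord residuals beyond the inflection) against `k`; the optimal Jaccard
#' length is the one whose slope is closest to -1.0, the signature of a
#' replicated-program count that stays constant for all ranks above the
#' ground truth. Ties take the smaller `J`.
#'
#' @param curves list of community-curve objects (elements of an
#'   [acnmf_scan()] result's `curves`), each with `J`, `k_star` and `cost`.
#' @param target slope aimed for (default -1.0).
#' @return the selected Jaccard length (integer), with attribute
#'   `"slopes"` (named vector of per-curve slopes).
#' @export
select_jaccard_length <- function(curves, target = -1.0) {
  usable <- Filter(function(cv) nrow(cv$cost) >= 2, curves)
  if (length(usable) == 0)
    stop("no curve has at least 2 post-inflection points")
  slopes <- vapply(usable, function(cv)
    unname(coef(lm(cost ~ k, data = cv$cost))[2]), numeric(1))
  names(slopes) <- vapply(usable, function(cv) as.character(cv$J),
                          character(1))
  if (length(usable) == 1)
    warning("single candidate curve; Jaccard length ", usable[[1]]$J,
            " returned regardless of slope")
  js <- vapply(usable, function(cv) cv$J, numeric(1))
  ord <- order(abs(slopes - target), js)
  structure(as.integer(js[ord[1]]), slopes = slopes)
}

#' Scan ranks and Jaccard lengths by split-half reproducibility
#'
#' The rank-selection engine: for each replicate, the cells are split 50/50
#' at random and each half is consensus-factorized at every rank `k`; at
#' each Jaccard length `J` the split programs are matched by the exact
#' overlap test and the number of replicated-program communities is
#' recorded. Community counts are loess-smoothed over `k` per `J`, the
#' inflection `k*` located, and the Jaccard length chosen by the slope rule.
#'
#' @param X non-negative genes x cells matrix prepared for NMF (see
#'   [scale_for_nmf()]).
#' @param k_grid ranks to scan.
#' @param j_grid Jaccard lengths to scan.
#' @param n_reps number of independent split/factorization replicates.
#' @param n_restarts NMF restarts per consensus factorization.
#' @param seed master integer seed.
#' @param alpha split-match significance threshold (Bonferroni-adjusted).
#' @param max_iter,tol NMF solver settings for the scan path (lighter than
#'   the finalization defaults; the consensus step absorbs partial
#'   convergence).
#' @param span loess span.
#' @param filter_rate outlier-component filtering rate.
#' @param verbose print progress.
#' @return an object of class `"acnmf_scan"`: `points` (rep, k, J,
#'   n_communities), `curves` (per-J list: `J`, `smoothed`, `k_star`,
#'   `cost`, `slope`, `degenerate`), `chosen_J`, `chosen_k`, grids and seed.
#' @export
acnmf_scan <- function(X, k_grid, j_grid, n_reps = 3L, n_restarts = 30L,
                       seed = 1L, alpha = 0.05, max_iter = 100L, tol = 1e-4,
                       span = 0.75, filter_rate = 0.10, verbose = FALSE) {
  X <- as_dense(X)
  stopifnot(length(k_grid) >= 1, length(j_grid) >= 1, n_reps >= 1)
  k_grid <- sort(unique(as.integer(k_grid)))
  j_grid <- sort(unique(as.integer(j_grid)))
  if (max(j_grid) > nrow(X)) stop("Jaccard length exceeds the gene universe")
  if (max(k_grid) >= min(dim(X)) / 2)
    stop("k grid too large for the split size")

  split_seeds <- derive_seeds(seed, n_reps, "scan_split")
  nmf_seeds <- matrix(derive_seeds(seed, 2L * n_reps * length(k_grid),
                                   "scan_nmf"),
                      nrow = n_reps)
  pts <- list()
  for (r in seq_len(n_reps)) {
    sp <- split_half(ncol(X), seed = split_seeds[r])
    Xa <- X[, sp$indices_a, drop = FALSE]
    Xb <- X[, sp$indices_b, drop = FALSE]
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      ca <- consensus_nmf(Xa, k, n_restarts = n_restarts,
                          seed = nmf_seeds[r, 2 * ki - 1],
                          max_iter = max_iter, tol = tol,
                          filter_rate = filter_rate)
      cb <- consensus_nmf(Xb, k, n_restarts = n_restarts,
                          seed = nmf_seeds[r, 2 * ki],
                          max_iter = max_iter, tol = tol,
                          filter_rate = filter_rate)
      for (J in j_grid) {
        ed <- match_split_programs(ca$Wz, cb$Wz, J, alpha = alpha)
        nc <- count_communities(ed)$n_communities
        pts[[length(pts) + 1L]] <- data.frame(rep = r, k = k, J = J,
                                              n_communities = nc)
        if (verbose)
          message(sprintf("rep %d k %d J %d -> %d communities", r, k, J, nc))
      }
    }
  }
  points <- do.call(rbind, pts)

  curves <- lapply(j_grid, function(J) {
    pj <- points[points$J == J, ]
    sm <- loess_smooth(pj$k, pj$n_communities, span = span)
    infl <- find_inflection(sm$k, sm$fitted)
    slope <- if (nrow(infl$cost) >= 2)
      unname(coef(lm(cost ~ k, data = infl$cost))[2]) else NA_real_
    list(J = J, points = pj, smoothed = sm, k_star = infl$k_star,
         residuals = infl$residuals, cost = infl$cost,
         post_inflection_slope = slope, degenerate = infl$degenerate)
  })
  names(curves) <- as.character(j_grid)

  sel <- lapply(curves, function(cv)
    list(J = cv$J, cost = cv$cost))
  chosen_J <- tryCatch(select_jaccard_length(sel),
                       error = function(e) j_grid[1])
  chosen_k <- curves[[as.character(chosen_J)]]$k_star

  structure(list(points = points, curves = curves,
                 chosen_J = as.integer(chosen_J),
                 chosen_k = as.integer(chosen_k),
                 k_grid = k_grid, j_grid = j_grid,
                 n_reps = n_reps, n_restarts = n_restarts,
                 seed = as.integer(seed), alpha = alpha),
            class = "acnmf_scan")
}

#' @export
print.acnmf_scan <- function(x, ...) {
  cat("acNMF scan over k = {", paste(x$k_grid, collapse = ", "),
      "}, J = {", paste(x$j_grid, collapse = ", "), "}, ",
      x$n_reps, " replicate split(s)\n", sep = "")
  cat("  selected Jaccard length J* = ", x$chosen_J,
      ", rank k* = ", x$chosen_k, "\n", sep = "")
  for (cv in x$curves)
    cat(sprintf("  J = %3d: k_star = %d, post-inflection slope = %s%s\n",
                cv$J, cv$k_star,
                ifelse(is.na(cv$post_inflection_slope), "NA",
                       signif(cv$post_inflection_slope, 3)),
                if (cv$degenerate) " (degenerate curve)" else ""))
  invisible(x)
}

#' @export
plot.acnmf_scan <- function(x, ...) {
  pal <- grDevices::hcl.colors(length(x$curves), "Dark 3")
  with(x$points, plot(jitter(k, 0.3), n_communities,
                      col = pal[match(J, x$j_grid)], pch = 16, cex = 0.6,
                      xlab = "rank k",
                      ylab = "replicated program communities", ...))
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    graphics::lines(cv$smoothed$k, cv$smoothed$fitted, col = pal[i], lwd = 2)
  }
  graphics::abline(v = x$chosen_k, lty = 2)
  graphics::legend("bottomright", legend = paste0("J = ", x$j_grid),
                   col = pal, lwd = 2, bty = "n")
  invisible(x)
}
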
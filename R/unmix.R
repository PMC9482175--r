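#' Optical-density stain basis for a triple chromogen + haematoxylin panel
#'
#' Returns the 3 x 4 dictionary of unit-norm optical-density vectors (rows
#' R, G, B) for haematoxylin, DAB (brown), fast red and PermaGreen. The
#' haematoxylin and DAB vectors are the standard published brightfield
#' deconvolution vectors; the fast red and green vectors were measured from
#' synthetic single-stain renderings and are configurable, since the basis
#' is an input to the model rather than part of it.
#'
#' @param vectors optional 3 x 4 replacement matrix (columns will be
#'   normalized to unit Euclidean norm).
#' @return 3 x 4 numeric matrix, columns named
#'   `haematoxylin, dab, fast_red, perma_green`, each column unit-norm and
#'   non-negative.
#' @export
stain_basis <- function(vectors = NULL) {
  if (is.null(vectors)) {
    vectors <- cbind(haematoxylin = c(0.650, 0.704, 0.286),
                     dab          = c(0.269, 0.568, 0.778),
                     fast_red     = c(0.250, 0.700, 0.100),
                     perma_green  = c(0.850, 0.100, 0.250))
  }
  stopifnot(is.matrix(vectors), nrow(vectors) == 3L, ncol(vectors) == 4L)
  if (any(vectors < 0)) stop("stain vectors must be non-negative")
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) stop("stain vectors must be non-zero")
  vectors <- sweep(vectors, 2, nrm, "/")
  colnames(vectors) <- stain_channel_names()
  rownames(vectors) <- c("R", "G", "B")
  # duplicate or near-collinear stain vectors make the model ill-conditioned
  g <- crossprod(vectors)
  off <- g[upper.tri(g)]
  if (any(off > 1 - 1e-6))
    stop("ill-conditioned basis: two stain vectors are (near-)collinear")
  vectors
}

#' Unmixing configuration
#'
#' @param lambda group-sparsity regularization weight (>= 0); with one
#'   stain per group the penalty is `lambda * sum_s a_s` over non-negative
#'   concentrations. `lambda = 0` requests the sparsity-limit solution:
#'   minimal residual, with minimal total concentration as tie-break (the
#'   dictionary is overcomplete in RGB space, so the tie-break is what
#'   makes the zero-penalty solution well defined).
#' @param I0 background (blank) transmitted intensity per channel.
#' @param od_floor pixels whose total optical density falls below this
#'   value are treated as background and skipped.
#' @param debias refit an unpenalized least-squares on the support selected
#'   by the penalized solve, removing the soft-threshold shrinkage bias
#'   from the reported concentrations (relaxed-lasso convention).
#' @param tol coordinate-descent convergence tolerance (max absolute
#'   coefficient change).
#' @param max_iter maximum coordinate-descent sweeps.
#' @return list of class `unmix_config`.
#' @export
unmix_config <- function(lambda = 0.1, I0 = 255, od_floor = 0.02,
                         debias = TRUE, tol = 1e-8, max_iter = 1000L) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (I0 <= 0) stop("`I0` must be > 0")
  structure(list(lambda = lambda, I0 = I0, od_floor = od_floor,
                 debias = isTRUE(debias), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "unmix_config")
}

#' Convert transmitted RGB intensity to optical density
#'
#' Beer-Lambert preprocessing: `OD_c = log10(I0 / I_c)` per channel, with
#' intensities clamped to at least one count before the logarithm so that
#' fully absorbed pixels stay finite.
#'
#' @param rgb x-by-y-by-3 intensity array (values in `[0, I0]`) or a 3-row
#'   matrix of pixel intensities.
#' @param I0 background intensity (> 0).
#' @return array/matrix of the same shape with non-negative optical
#'   densities.
#' @export
rgb_to_od <- function(rgb, I0 = 255) {
  if (I0 <= 0) stop("`I0` must be > 0")
  od <- log10(I0 / pmax(pmin(rgb, I0), 1))
  od[od < 0] <- 0
  od
}

#' Non-negative group-sparse stain unmixing
#'
#' Per pixel, finds concentrations `a >= 0` minimizing
#' `0.5 * ||od - D a||^2 + lambda * sum_groups ||a_g||` where `D` is the
#' stain dictionary. With the model's restriction of one stain per group
#' the group penalty reduces to a non-negative lasso over the four stain
#' concentrations, solved by cyclic coordinate descent (soft-threshold
#' updates), vectorized over pixels.
#'
#' @param od optical densities: x-by-y-by-3 array or 3-row matrix (one
#'   column per pixel).
#' @param basis a [stain_basis()].
#' @param config an [unmix_config()]; `config$lambda = 0` reduces the
#'   problem to non-negative least squares.
#' @return concentrations in the same layout as the input
#'   (x-by-y-by-4 array or 4-row matrix), channels named by stain, with
#'   attribute `residual` holding the mean squared reconstruction residual
#'   over unmixed pixels.
#' @export
group_sparse_unmix <- function(od, basis = stain_basis(),
                               config = unmix_config()) {
  stopifnot(inherits(config, "unmix_config"))
  as_array <- is.array(od) && length(dim(od)) == 3L
  if (as_array) {
    dims <- dim(od)[1:2]
    odm <- t(matrix(od, nrow = prod(dims), ncol = 3L))   # 3 x N
  } else {
    odm <- as.matrix(od)
    stopifnot(nrow(odm) == 3L)
  }
  if (any(!is.finite(odm))) stop("optical densities must be finite")
  n_px <- ncol(odm)
  a <- matrix(0, 4L, n_px, dimnames = list(colnames(basis), NULL))

  active <- colSums(odm) >= config$od_floor
  if (any(active)) {
    sub <- odm[, active, drop = FALSE]
    if (config$lambda == 0) {
      a[, active] <- nnls_sparse_exact(sub, basis)
    } else {
      sol <- nnlasso_cd(sub, basis, config$lambda, config$tol,
                        config$max_iter)
      if (config$debias) sol <- debias_on_support(sub, basis, sol)
      a[, active] <- sol
    }
  }
  resid <- odm - basis %*% a
  res <- mean(colSums(resid^2))

  if (as_array) {
    out <- array(t(a), c(dims, 4L),
                 dimnames = list(NULL, NULL, colnames(basis)))
  } else {
    out <- a
  }
  attr(out, "residual") <- res
  out
}

# cyclic coordinate descent for min_{a>=0} 0.5||od - D a||^2 + lambda*sum(a),
# vectorized across pixels; with unit-norm columns the update for stain s is
# a_s <- max(0, d_s'od - sum_{t != s} (d_s'd_t) a_t - lambda)
nnlasso_cd <- function(odm, D, lambda, tol, max_iter) {
  G <- crossprod(D)                 # 4 x 4, unit diagonal
  B <- crossprod(D, odm)            # 4 x N
  a <- matrix(0, 4L, ncol(odm))
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (s in 1:4) {
      g_s <- B[s, ] - G[s, ] %*% a + a[s, ]
      new_s <- pmax(0, as.numeric(g_s) - lambda)
      delta <- max(delta, max(abs(new_s - a[s, ])))
      a[s, ] <- new_s
    }
    if (delta < tol) break
  }
  a
}

# exact non-negative least squares with minimal-l1 tie-break, by
# enumeration of the 15 stain subsets (the dictionary has 4 atoms in a
# 3-dimensional colour space, so zero-residual representations are not
# unique; the sparsity limit of the group penalty selects the one with
# minimal total concentration, attained at a subset-restricted LS vertex)
nnls_sparse_exact <- function(odm, D) {
  n_px <- ncol(odm)
  best_a <- matrix(0, 4L, n_px)
  best_rss <- colSums(odm^2)          # empty support
  best_l1 <- rep(0, n_px)
  subsets <- unlist(lapply(1:3, function(k) combn(4L, k, simplify = FALSE)),
                    recursive = FALSE)
  for (S in subsets) {
    Ds <- D[, S, drop = FALSE]
    As <- solve(crossprod(Ds), crossprod(Ds, odm))   # |S| x N
    feas <- colSums(As < -1e-10) == 0L
    if (!any(feas)) next
    As[As < 0] <- 0
    fit <- Ds %*% As
    rss <- colSums((odm - fit)^2)
    l1 <- colSums(As)
    # the residual tie tolerance bounds the smallest true coefficient the
    # sparsity tie-break can drop (~sqrt(tol/eig_min) ~ 3e-8)
    better <- feas & (rss < best_rss - 1e-16 |
                        (rss < best_rss + 1e-16 & l1 < best_l1 - 1e-12))
    if (any(better)) {
      best_rss[better] <- rss[better]
      best_l1[better] <- l1[better]
      best_a[, better] <- 0
      best_a[S, better] <- As[, better]
    }
  }
  best_a
}

# refit plain least squares on each pixel's selected stain subset; exact
# whenever the selected support contains the true one and has at most 3
# linearly independent atoms
debias_on_support <- function(odm, D, a) {
  supp <- a > 0
  key <- as.integer(1L + colSums(supp * (2L^(0:3))))
  for (k in unique(key)) {
    S <- which(bitwAnd(k - 1L, 2L^(0:3)) > 0L)
    if (length(S) == 0L || length(S) > 3L) next
    cols <- key == k
    Ds <- D[, S, drop = FALSE]
    As <- solve(crossprod(Ds), crossprod(Ds, odm[, cols, drop = FALSE]))
    As[As < 0] <- 0                  # rare sign flips under noise
    a[, cols] <- 0
    a[S, cols] <- As
  }
  a
}

#' Unmix a brightfield RGB core image into stain concentrations
#'
#' Composition of [rgb_to_od()] and [group_sparse_unmix()]: converts a
#' brightfield RGB image to a named 4-channel stain-concentration image
#' (haematoxylin, DAB, fast red, PermaGreen).
#'
#' @inheritParams group_sparse_unmix
#' @param rgb x-by-y-by-3 intensity array.
#' @return x-by-y-by-4 concentration array with channel names and a
#'   `residual` attribute (mean squared reconstruction residual).
#' @export
unmix_core <- function(rgb, basis = stain_basis(), config = unmix_config()) {
  od <- rgb_to_od(rgb, config$I0)
  group_sparse_unmix(od, basis, config)
}
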
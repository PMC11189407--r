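# Cubic regression spline bases (natural and cyclic) with second-derivative
# roughness penalties, optional null-space shrinkage, and sum-to-zero
# centring. The natural basis is parameterised by the function values at the
# knots; the penalty is the exact integrated squared second derivative of the
# interpolating natural cubic spline.

#' Specify a penalized smooth term
#'
#' @param covariate Name of the model-frame column the smooth acts on.
#' @param k Basis dimension (number of knots; `>= 3`). The penalty, not `k`,
#'   controls the fitted complexity, so `k` only needs to be generous.
#' @param cyclic Use the cyclic basis (value and first two derivatives match
#'   at the period ends)? Intended for periodic covariates such as birth
#'   month.
#' @param shrink Add a small penalty on the roughness penalty's null space so
#'   the whole term can shrink to zero (effective degrees of freedom -> 0 as
#'   the smoothing parameter grows)? Default `TRUE`.
#' @param knots Optional explicit knot vector (length `k`, strictly
#'   increasing). Default: quantiles of the distinct covariate values
#'   (natural basis) or an even grid over the covariate range (cyclic basis).
#'   For a month effect use `seq(0.5, 12.5, length.out = k)` so December and
#'   January remain distinct while wrapping smoothly.
#' @return An object of class `"ssr_smooth_spec"`.
#' @export
smooth_spec <- function(covariate, k = 10, cyclic = FALSE, shrink = TRUE,
                        knots = NULL) {
  if (k < 3) stop_ssr("basis dimension `k` must be >= 3")
  if (!is.null(knots)) {
    if (length(knots) != k) stop_ssr("`knots` must have length `k`")
    if (any(diff(knots) <= 0)) stop_ssr("`knots` must be strictly increasing")
  }
  structure(list(covariate = covariate, k = as.integer(k),
                 cyclic = isTRUE(cyclic), shrink = isTRUE(shrink),
                 knots = knots),
            class = "ssr_smooth_spec")
}

# Natural cubic regression spline: design + penalty from knot values.
# Wood-style construction: B and D map knot values to second derivatives.
cr_matrices <- function(knots) {
  k <- length(knots)
  h <- diff(knots)
  D <- matrix(0, k - 2, k)
  B <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) {
      B[i, i + 1] <- h[i + 1] / 6
      B[i + 1, i] <- h[i + 1] / 6
    }
  }
  Fmat <- rbind(0, solve(B, D), 0)   # knot values -> second derivatives
  S <- crossprod(D, solve(B, D))     # integral of squared second derivative
  list(F = Fmat, S = (S + t(S)) / 2)
}

cr_design <- function(x, knots, Fmat) {
  k <- length(knots)
  j <- findInterval(x, knots, all.inside = TRUE)
  h <- (knots[j + 1] - knots[j])
  am <- (knots[j + 1] - x) / h
  ap <- (x - knots[j]) / h
  cm <- ((knots[j + 1] - x)^3 / h - h * (knots[j + 1] - x)) / 6
  cp <- ((x - knots[j])^3 / h - h * (x - knots[j])) / 6
  X <- matrix(0, length(x), k)
  for (i in seq_along(x)) {
    X[i, j[i]] <- X[i, j[i]] + am[i]
    X[i, j[i] + 1] <- X[i, j[i] + 1] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * Fmat[j[i], ] + cp[i] * Fmat[j[i] + 1, ]
  }
  X
}

# Cyclic variant: k knots, knot k identified with knot 1 (k-1 coefficients).
cc_matrices <- function(knots) {
  k <- length(knots)
  n <- k - 1
  h <- diff(knots)                    # h[1..n]; interval left of knot 1 is h[n]
  B <- matrix(0, n, n)
  D <- matrix(0, n, n)
  wrap <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    hl <- h[wrap(i - 1)]
    hr <- h[i]
    B[i, i] <- (hl + hr) / 3
    B[i, wrap(i - 1)] <- B[i, wrap(i - 1)] + hl / 6
    B[i, wrap(i + 1)] <- B[i, wrap(i + 1)] + hr / 6
    D[i, i] <- -1 / hl - 1 / hr
    D[i, wrap(i - 1)] <- D[i, wrap(i - 1)] + 1 / hl
    D[i, wrap(i + 1)] <- D[i, wrap(i + 1)] + 1 / hr
  }
  delta <- solve(B, D)               # knot values -> second derivatives
  S <- crossprod(D, solve(B, D))
  list(delta = delta, S = (S + t(S)) / 2, h = h)
}

cc_design <- function(x, knots, delta) {
  k <- length(knots)
  n <- k - 1
  if (any(x < knots[1] | x > knots[k]))
    stop_ssr("cyclic covariate values must lie within the knot range [",
             knots[1], ", ", knots[k], "]")
  j <- findInterval(x, knots, all.inside = TRUE)
  h <- knots[j + 1] - knots[j]
  am <- (knots[j + 1] - x) / h
  ap <- (x - knots[j]) / h
  cm <- ((knots[j + 1] - x)^3 / h - h * (knots[j + 1] - x)) / 6
  cp <- ((x - knots[j])^3 / h - h * (x - knots[j])) / 6
  X <- matrix(0, length(x), n)
  for (i in seq_along(x)) {
    jl <- j[i]
    jr <- if (j[i] == n) 1L else j[i] + 1L
    X[i, jl] <- X[i, jl] + am[i]
    X[i, jr] <- X[i, jr] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * delta[jl, ] + cp[i] * delta[jr, ]
  }
  X
}

#' Build a penalized spline basis for a smooth term
#'
#' Constructs the cubic regression spline design matrix (cyclic variant when
#' requested) and its second-derivative roughness penalty; with `shrink` a
#' small multiple of the penalty's null-space projector is added so the term
#' can be penalized all the way to zero.
#'
#' @param spec An [smooth_spec()].
#' @param x Covariate values.
#' @return List of class `"ssr_basis"`: `X` (n x k design, uncentred), `S`
#'   (k x k penalty), `knots`, `null_dim` (dimension of the unpenalized space
#'   of the roughness penalty alone), and the pieces needed to evaluate the
#'   basis on new values.
#' @export
build_basis <- function(spec, x) {
  stopifnot(inherits(spec, "ssr_smooth_spec"))
  ux <- sort(unique(x))
  k <- spec$k
  needed <- if (spec$cyclic) k - 1 else k
  if (length(ux) < needed)
    stop_ssr("smooth '", spec$covariate, "': basis dimension ", k,
             " exceeds the ", length(ux), " distinct covariate values")
  if (spec$cyclic) {
    knots <- spec$knots %||% seq(min(ux), max(ux), length.out = k)
    mats <- cc_matrices(knots)
    X <- cc_design(x, knots, mats$delta)
    S <- mats$S
    eval_fun <- function(newx) cc_design(newx, knots, mats$delta)
    null_dim <- 1L
  } else {
    knots <- spec$knots %||%
      unname(stats::quantile(ux, probs = seq(0, 1, length.out = k), type = 7))
    if (any(diff(knots) <= 0)) knots <- seq(min(ux), max(ux), length.out = k)
    mats <- cr_matrices(knots)
    X <- cr_design(x, knots, mats$F)
    S <- mats$S
    eval_fun <- function(newx) cr_design(newx, knots, mats$F)
    null_dim <- 2L
  }
  # normalize the penalty to unit spectral norm so smoothing parameters are
  # comparable across terms and the log-lambda search box is meaningful
  eg <- eigen(S, symmetric = TRUE)
  S <- S / max(eg$values)
  if (spec$shrink) {
    pos <- eg$values > max(eg$values) * 1e-10
    U0 <- eg$vectors[, !pos, drop = FALSE]
    if (ncol(U0) > 0) {
      # null-space weight an order below the weakest curvature eigenvalue:
      # strong enough to shrink an absent term to zero at large lambda, weak
      # enough not to distort genuinely linear signal at moderate lambda
      eps <- 0.1 * min(eg$values[pos] / max(eg$values))
      S <- S + eps * tcrossprod(U0)
    }
    null_dim <- 0L
  }
  structure(list(X = X, S = S, knots = knots, null_dim = null_dim,
                 eval_fun = eval_fun, spec = spec, x_range = range(x)),
            class = "ssr_basis")
}

# Sum-to-zero centring: X -> X Z with 1'XZ = 0; penalty transformed likewise.
center_basis <- function(basis) {
  C <- colSums(basis$X)
  qrC <- qr(matrix(C, ncol = 1))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  basis$Z <- Z
  basis$Xc <- basis$X %*% Z
  basis$Sc <- crossprod(Z, basis$S %*% Z)
  basis$Sc <- (basis$Sc + t(basis$Sc)) / 2
  basis
}
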
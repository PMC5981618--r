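# Robust conic/ellipse fitting on edge-point sets.
#
# A conic is stored as coefficients (A, B, C, D, E, F) of
# A x^2 + B xy + C y^2 + D x + E y + F = 0. All fitting is done in a
# normalized frame (centered, isotropically scaled) for numerical
# conditioning; ellipse parameters are mapped back through the similarity.

fit_conic_ls <- function(x, y) {
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  # minimizer of ||D k|| with ||k|| = 1: smallest eigenvector of D'D
  ev <- eigen(crossprod(D), symmetric = TRUE)
  ev$vectors[, 6]
}

conic_is_ellipse <- function(k) {
  is.finite(k[2]^2 - 4 * k[1] * k[3]) && (k[2]^2 - 4 * k[1] * k[3]) < 0
}

# conic -> list(cx, cy, a, b, theta); NULL if not a real ellipse
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  det2 <- 4 * A * C - B^2
  if (!is.finite(det2) || det2 <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / det2
  cy <- (B * D - 2 * A * E) / det2
  # value of the quadratic form at the center
  F0 <- F + (D * cx + E * cy) / 2
  M <- matrix(c(A, B / 2, B / 2, C), 2)
  ev <- eigen(M, symmetric = TRUE)
  ax2 <- -F0 / ev$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(NULL)
  axes <- sqrt(ax2)            # ev$values descending => axes ascending
  list(cx = cx, cy = cy, a = max(axes), b = min(axes),
       theta = atan2(ev$vectors[2, which.min(ev$values)],
                     ev$vectors[1, which.min(ev$values)]))
}

# radial distance of points to an ellipse (exact for circles, good
# approximation for the moderate eccentricities seen here)
ellipse_radial_dist <- function(el, x, y) {
  dx <- x - el$cx; dy <- y - el$cy
  phi <- atan2(dy, dx) - el$theta
  # ellipse radius along direction phi (theta = major-axis direction)
  re <- el$a * el$b / sqrt((el$b * cos(phi))^2 + (el$a * sin(phi))^2)
  abs(sqrt(dx^2 + dy^2) - re)
}

# Consensus (RANSAC-style) ellipse fit: random 5-point conic fits, best
# inlier support kept, least-squares refit on the inliers. Runs under a
# fixed private RNG stream so results are reproducible.
fit_ellipse_robust <- function(x, y, n_iter = 60L, inlier_tol = 1.5,
                               seed = 42L) {
  n <- length(x)
  if (n < 6) return(NULL)
  mx <- mean(x); my <- mean(y)
  s <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (!is.finite(s) || s <= 0) return(NULL)
  xn <- (x - mx) / s; yn <- (y - my) / s
  tol <- inlier_tol / s

  best <- NULL; best_support <- -1L
  subsets <- with_local_seed(seed, {
    lapply(seq_len(n_iter), function(i) sample.int(n, 5L))
  })
  for (idx in subsets) {
    k <- tryCatch(fit_conic_ls(xn[idx], yn[idx]), error = function(e) NULL)
    if (is.null(k) || !conic_is_ellipse(k)) next
    el <- conic_to_ellipse(k)
    if (is.null(el)) next
    support <- sum(ellipse_radial_dist(el, xn, yn) <= tol)
    if (support > best_support) {
      best_support <- support
      best <- el
    }
  }
  if (is.null(best)) return(NULL)

  # two rounds of inlier-set least-squares refinement
  inl <- ellipse_radial_dist(best, xn, yn) <= tol
  for (round in 1:2) {
    if (sum(inl) < 6) break
    k <- fit_conic_ls(xn[inl], yn[inl])
    if (!conic_is_ellipse(k)) break
    el <- conic_to_ellipse(k)
    if (is.null(el)) break
    best <- el
    inl <- ellipse_radial_dist(best, xn, yn) <= tol
  }
  list(cx = mx + s * best$cx, cy = my + s * best$cy,
       a = s * best$a, b = s * best$b, theta = best$theta,
       quality = mean(inl), n_edge = n)
}
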
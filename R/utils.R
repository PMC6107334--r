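# Internal geometry / RNG helpers shared across modules.

vec_norm <- function(m) {
  if (is.null(dim(m))) sqrt(sum(m^2)) else sqrt(rowSums(m^2))
}

unitize <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  n <- vec_norm(m)
  m / pmax(n, .Machine$double.xmin)
}

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Derive a per-stage RNG seed from one global seed
#'
#' Stage insertion must not perturb other stages' random streams, so each
#' pipeline stage draws from its own seed derived deterministically from the
#' global one. Values stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0) or stage name (hashed).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003L
  }
  s <- (as.double(seed) %% 1000003) * 2011 + as.double(stage) * 7919 + 17
  as.integer(s %% 2147483647)
}

# isotropic directions on the unit sphere
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# von Mises-Fisher directions on S^2 with per-row mean direction `mu` (n x 3,
# unit rows) and common concentration kappa. Wood's simulation of the axial
# component: W = 1 + log(u + (1-u) e^{-2 kappa}) / kappa.
rvmf <- function(n, mu, kappa) {
  if (kappa < 1e-12) return(runif_sphere(n))
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = n, ncol = 3, byrow = TRUE)
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmin(1, pmax(-1, w))
  phi <- stats::runif(n, 0, 2 * pi)
  rt <- sqrt(pmax(0, 1 - w^2))
  # orthonormal frame around each mu; fallback axis where mu ~ +-z
  helper <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  flip <- abs(mu[, 3]) > 0.9
  helper[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
  e1 <- unitize(cross3(mu, helper))
  e2 <- cross3(mu, e1)
  mu * w + e1 * (rt * cos(phi)) + e2 * (rt * sin(phi))
}

# truncated-at-zero normal step speeds
rspeed <- function(n, mean, sd) {
  pmax(0, stats::rnorm(n, mean, sd))
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in logs
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
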
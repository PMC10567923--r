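# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded internals never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a stream of child seeds from one seed; keeps every derived seed
# well inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Solve least squares and return coefficients, standard errors, and residual
# variance; drops rank-deficient columns (coefficient NA).
ols_fit <- function(X, y) {
  qr_x <- qr(X)
  coefs <- qr.coef(qr_x, y)
  fitted <- qr.fitted(qr_x, y)
  resid <- y - fitted
  df <- length(y) - qr_x$rank
  sigma2 <- if (df > 0) sum(resid^2) / df else 0
  keep <- !is.na(coefs)
  se <- rep(NA_real_, length(coefs))
  if (any(keep)) {
    xtx_inv <- chol2inv(qr.R(qr_x)[seq_len(qr_x$rank), seq_len(qr_x$rank), drop = FALSE])
    se[qr_x$pivot[seq_len(qr_x$rank)]] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  }
  names(se) <- names(coefs)
  list(coef = coefs, se = se, sigma2 = sigma2, rank = qr_x$rank, resid = resid)
}

# Residualize columns of y (matrix or vector) on design X (with intercept
# added), via QR projection.
residualize <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  qr_x <- qr(X)
  y <- as.matrix(y)
  y - qr.fitted(qr_x, y)
}
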
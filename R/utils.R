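# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's \code{.Random.seed}, so seeded package
#' internals never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: a fixed affine hash keeps every derived
# seed inside the 32-bit integer range, and makes per-sample/per-replicate
# streams independent of how many other samples exist.
subSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

# Sample standard deviation (n - 1) per column of a matrix.
colSds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute column SDs")
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
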
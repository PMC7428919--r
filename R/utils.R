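## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

## Derive a reproducible child seed from a base seed and a stream label,
## keeping the result inside the 32-bit integer range.
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  parts <- paste(c(seed, ...), collapse = "/")
  raw <- utf8ToInt(parts)
  as.integer((sum(raw * (seq_along(raw) %% 7919 + 1)) + seed * 131L) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x < 1

## Round hours to charting (minute) resolution.
to_minutes <- function(hours) round(hours * 60) / 60

## Pairwise Euclidean distances between rows of a and rows of b, computed in
## blocks so memory stays bounded for large training folds.
block_dist <- function(a, b, block = 512L) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- matrix(0, nrow(a), nrow(b))
  bb <- rowSums(b^2)
  idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / block))
  for (ii in idx) {
    aa <- rowSums(a[ii, , drop = FALSE]^2)
    cross <- a[ii, , drop = FALSE] %*% t(b)
    d2 <- outer(aa, bb, "+") - 2 * cross
    d2[d2 < 0] <- 0
    out[ii, ] <- sqrt(d2)
  }
  out
}

## Indices of the k nearest rows of `ref` for each row of `x` (self excluded
## when `self_idx` gives the identity mapping between x and ref rows).
knn_index <- function(x, ref, k, self_idx = NULL) {
  d <- block_dist(x, ref)
  if (!is.null(self_idx)) {
    d[cbind(seq_len(nrow(d)), self_idx)] <- Inf
  }
  out <- apply(d, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(out, ncol = 1L) else t(out)
}
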
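#' @import methods
NULL

QC_CLASSES <- c("M", "D", "N")

# severity order used everywhere a single class must be chosen among several:
# Malignant > Uncategorized > Dysplasia > Negative
CLASS_PRIORITY <- c(M = 4L, U = 3L, D = 2L, N = 1L)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' previous RNG state afterwards, so seeded package internals never perturb a
#' caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a distinct 31-bit sub-seed from a base seed and a stream label
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}

#' Largest-remainder apportionment
#'
#' Distributes \code{n} items over categories proportionally to \code{props},
#' assigning leftover units to the largest fractional remainders (ties broken
#' by category order).
#'
#' @param n total count to distribute.
#' @param props non-negative proportions, summing to 1.
#' @return integer vector of counts summing to \code{n}.
#' @examples
#' largestRemainder(10, c(0.2, 0.3, 0.5))  # 2 3 5
#' @export
largestRemainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0), abs(sum(props) - 1) < 1e-8)
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  cnt <- as.integer(base)
  names(cnt) <- names(props)
  cnt
}

# luminance in [0,1] from an H x W x 3 array (Rec. 601 weights)
luminance <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# argmax over an (M, D, N) probability triple; which.max takes the first
# maximum, and the vector is ordered by severity, so ties resolve M > D > N
argmaxClass <- function(p) {
  stopifnot(length(p) == 3)
  QC_CLASSES[which.max(p)]
}
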
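#' @importFrom stats rnorm runif setNames sd phyper
#' @importFrom utils head tail
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## wildcard positions admit X (unknown residue) but not B/Z/U
AA_WILD <- c(AA20, "X")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generators route randomness through this
# so they are pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# all pairwise Euclidean distances between rows of two matrices
crossDist <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    out[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  out
}

# smallest circular difference between angles in degrees, result in [0, 180]
circularDiff <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

# wrap angles in degrees to (-180, 180]
wrapAngle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}
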
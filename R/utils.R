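# internal helpers shared across modules

# evaluate expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# deterministic per-item sub-seed derived from a root seed (kept below 2^31)
.sub_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629
}

# truncated-normal draw by rejection (bounds far in the tail fall back to clamping)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(n)
  need <- seq_len(n)
  for (attempt in 1:200) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (length(need) == 0) return(out)
  }
  out[need] <- pmin(pmax(stats::rnorm(length(need), mean, sd), lower), upper)
  out
}

# runs of TRUE in a logical vector -> matrix of (start, end) indices
.runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# vertex of the parabola through (x1,y1),(x2,y2),(x3,y3) with arbitrary spacing;
# returns c(x, y) of the vertex, or the middle point when degenerate
.parabola_vertex <- function(x1, y1, x2, y2, x3, y3) {
  d1 <- (y1 - y2) / (x1 - x2)
  d2 <- (y3 - y2) / (x3 - x2)
  a <- (d2 - d1) / (x3 - x1)
  if (!is.finite(a) || a >= 0) return(c(x2, y2))
  b <- d1 - a * (x1 + x2)
  cc <- y2 - a * x2^2 - b * x2
  xv <- -b / (2 * a)
  # clamp to the bracket
  xv <- min(max(xv, min(x1, x3)), max(x1, x3))
  c(xv, a * xv^2 + b * xv + cc)
}
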
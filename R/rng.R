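# Local random-number streams: every stochastic operation takes an explicit
# integer seed and draws from its own stream, leaving the caller's
# .Random.seed untouched. A stream is an environment holding a saved
# .Random.seed that is swapped in around each draw.

.seeded_rng <- function(seed) {
  if (!is.numeric(seed) || !is.finite(seed)) {
    stop("seed must be a finite integer", call. = FALSE)
  }
  rs <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  rs$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  rs
}

.with_rng <- function(rs, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", rs$state, envir = globalenv())
  on.exit({
    rs$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

.rng_runif <- function(rs, n, min = 0, max = 1) .with_rng(rs, stats::runif(n, min, max))
.rng_rnorm <- function(rs, n, mean = 0, sd = 1) .with_rng(rs, stats::rnorm(n, mean, sd))
.rng_sample <- function(rs, x, size, replace = FALSE, prob = NULL) {
  .with_rng(rs, sample(x, size, replace = replace, prob = prob))
}

# uniform draws in (0, max]: strictly positive NMF initializations
.runif_pos <- function(rs, n, max) {
  u <- .rng_runif(rs, n, 0, max)
  u[u == 0] <- max
  u
}
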
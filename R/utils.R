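# RNG scoping: stash and restore .Random.seed so seeded package internals
# never perturb the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Varimax with multiple deterministic starts. stats::varimax() begins at
# the identity, which can be a stationary saddle for symmetric loading
# patterns; restarting from fixed random orthogonal rotations and keeping
# the best varimax criterion makes the rotation reliable and still
# deterministic.
varimax_best <- function(L, n_starts = 10L) {
  nf <- ncol(L)
  crit <- function(M) {
    M2 <- M^2
    sum(apply(M2, 2, function(cl) mean(cl^2) - mean(cl)^2))
  }
  run <- function(start) {
    v <- stats::varimax(L %*% start)
    rot <- start %*% v$rotmat
    list(loadings = L %*% rot, rotmat = rot,
         crit = crit(L %*% rot))
  }
  best <- run(diag(nf))
  old <- local_seed(1L)
  on.exit(restore_seed(old))
  for (i in seq_len(n_starts)) {
    start <- qr.Q(qr(matrix(stats::rnorm(nf * nf), nf)))
    cand <- run(start)
    if (cand$crit > best$crit + 1e-12) best <- cand
  }
  best
}

#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL
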
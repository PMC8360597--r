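# Exhaustive-matching Wasserstein oracle for tiny diagrams (<= ~5 points per
# side).  Enumerates every partial matching: each point of D1 goes to the
# diagonal or to a distinct point of D2; leftover D2 points go to the
# diagonal.  Independent of the assignment solver used by the package.
oracle_wasserstein <- function(m1, m2, q = 2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n1 <- nrow(m1); n2 <- nrow(m2)
  diag_cost <- function(m) if (nrow(m)) (m[, 2] - m[, 1]) / 2 else numeric(0)
  d1 <- diag_cost(m1); d2 <- diag_cost(m2)
  if (n1 == 0 && n2 == 0) return(0)
  best <- Inf
  recurse <- function(i, used2, acc) {
    if (acc >= best) return()
    if (i > n1) {
      tot <- acc + sum(d2[!used2]^q)
      if (tot < best) best <<- tot
      return()
    }
    recurse(i + 1L, used2, acc + d1[i]^q)   # to the diagonal
    for (j in seq_len(n2)) {
      if (used2[j]) next
      cost <- max(abs(m1[i, 1] - m2[j, 1]), abs(m1[i, 2] - m2[j, 2]))
      used2[j] <- TRUE
      recurse(i + 1L, used2, acc + cost^q)
      used2[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, n2), 0)
  unname(best^(1 / q))
}

random_diagram <- function(n, lim = 3) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  b <- runif(n, 0, lim)
  unname(cbind(b, b + runif(n, 0, lim)))
}
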
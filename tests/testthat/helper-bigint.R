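# Exact big-integer arithmetic (base 1e7 digit vectors, little-endian) for a
# rational-arithmetic binomial-tail oracle independent of pbinom: Pascal's
# triangle gives exact C(n, j); the tail p-value is sum(C(n, j:n)) / 2^n.

bi_norm <- function(x) {
  base <- 1e7
  carry <- 0
  for (i in seq_along(x)) {
    x[i] <- x[i] + carry
    carry <- x[i] %/% base
    x[i] <- x[i] %% base
  }
  while (carry > 0) {
    x <- c(x, carry %% base)
    carry <- carry %/% base
  }
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

bi_to_double <- function(x) {
  sum(x * 1e7^(seq_along(x) - 1))
}

# exact tail P(X >= k), X ~ Bi(n, 1/2), via Pascal's triangle in exact
# integer arithmetic; returns a double formed from the exact numerator and
# the exact power-of-two denominator
binom_tail_oracle <- function(k, n) {
  row <- list(bi_norm(1)) # C(0, 0)
  if (n > 0) {
    for (r in seq_len(n)) {
      prev <- row
      row <- vector("list", r + 1)
      row[[1]] <- bi_norm(1)
      row[[r + 1]] <- bi_norm(1)
      if (r > 1) {
        for (j in 2:r) row[[j]] <- bi_add(prev[[j - 1]], prev[[j]])
      }
    }
  }
  tail_sum <- bi_norm(0)
  for (j in k:n) tail_sum <- bi_add(tail_sum, row[[j + 1]])
  bi_to_double(tail_sum) / 2^n
}
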
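# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Textbook single-component PLS1: w = X'y / ||X'y||, t = Xw, p = X't/t't.
pls1_oracle <- function(X, y) {
  w <- crossprod(X, y)
  w <- w / sqrt(sum(w^2))
  t1 <- as.numeric(X %*% w)
  p1 <- as.numeric(crossprod(X, t1) / sum(t1^2))
  list(w = as.numeric(w), t = t1, p = p1)
}

# brute-force bucket membership: which descending half-open interval
# (upper - i*w, upper - (i-1)*w] contains the point
bucket_of_oracle <- function(p, upper, lower, width) {
  n <- floor((upper - lower) / width)
  for (i in seq_len(n)) {
    hi <- upper - (i - 1) * width
    lo <- upper - i * width
    if (p <= hi + 1e-12 && p > lo + 1e-12) return(i)
  }
  NA_integer_
}

# maximum absolute deviation between two vectors up to a global sign
dev_up_to_sign <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}
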
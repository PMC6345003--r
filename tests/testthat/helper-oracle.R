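# Independent oracles used to pin expected values. These deliberately avoid
# dynamic programming: alignments are enumerated as explicit move sequences.

blosum <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# Exhaustive affine-gap global alignment score by brute-force enumeration of
# all move sequences (match/insert/delete). Gap of length k costs
# open + k * ext. Only usable for sequences of length <= ~5.
oracle_global_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(av))   # gap in b (consume a)
      best <- max(best,
                  -(if (last == "A") ext else open + ext) + rec(i + 1, j, "A"))
    if (j <= length(bv))   # gap in a (consume b)
      best <- max(best,
                  -(if (last == "B") ext else open + ext) + rec(i, j + 1, "B"))
    best
  }
  rec(1, 1, "M")
}

# Local score: best global score over all substring pairs, floored at 0
# (the empty alignment).
oracle_local_score <- function(a, b, mat, open = 11, ext = 1) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb)
      best <- max(best, oracle_global_score(substr(a, i1, i2),
                                            substr(b, j1, j2),
                                            mat, open, ext))
  best
}

# Exact two-sided Mann-Whitney p by explicit enumeration over all group
# assignments (the permutation null), independent of the package's own
# enumeration path.
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  sets <- combn(length(all_v), n1)
  us <- apply(sets, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Direct BH step-up computation from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}
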
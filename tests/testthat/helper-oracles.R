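# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles and
# share no code with the functions they validate.

# Jensen-Shannon divergence via the Kullback-Leibler formulation
# (the package uses the entropy-of-mixture formulation).
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Exhaustive argmax(x - y) search over the min-max scaled rank curve.
cutoff_oracle <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  if (n <= 1 || max(s) == min(s)) return(Inf)
  best_d <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(n)) {
    x <- (i - 1) / (n - 1)
    y <- (s[i] - min(s)) / (max(s) - min(s))
    if (x - y >= best_d) {  # ties resolve to the largest x
      best_d <- x - y
      best_i <- i
    }
  }
  if (best_d <= 1e-12) return(Inf)
  s[best_i]
}

# Fisher exact two-sided p by enumerating every table with the observed
# margins and summing hypergeometric probabilities (via choose()) that do
# not exceed the observed table's probability.
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments of
# the pooled observations.
mw_p_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    g1 <- pooled[ix]; g2 <- pooled[-ix]
    sum(outer(g1, g2, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, u_of)
  pl <- mean(us <= u_obs)
  pg <- mean(us >= u_obs)
  min(1, 2 * min(pl, pg))
}

# Brute-force circular seed-site scan on the doubled sequence with modular
# dedup: every seed-core occurrence is located with substring comparisons
# and classified by its flanking bases.
seed_sites_oracle <- function(circ, mirna) {
  circ <- chartr("U", "T", toupper(circ))
  m <- chartr("U", "T", toupper(mirna))
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  L <- nchar(circ)
  doubled <- paste0(circ, circ)
  core6 <- rc(substr(m, 2, 7))
  m8c <- chartr("ACGT", "TGCA", substr(m, 8, 8))
  found <- list()
  for (p in 0:(L - 1)) {
    if (substr(doubled, p + 1, p + 6) != core6) next
    prev <- substr(doubled, ((p - 1) %% L) + 1, ((p - 1) %% L) + 1)
    nxt <- substr(doubled, p + 7, p + 7)
    has_m8 <- prev == m8c
    has_a1 <- nxt == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    pos <- if (has_m8) (p - 1) %% L else p
    found[[length(found) + 1]] <- data.frame(
      position = pos, site_class = cls, stringsAsFactors = FALSE)
  }
  if (length(found) == 0) {
    return(data.frame(position = integer(), site_class = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, found)
  hier <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  out <- out[order(out$position, match(out$site_class, hier)), ]
  out <- out[!duplicated(out$position), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
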
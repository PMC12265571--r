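# Naive brute-force re-implementations of the summary statistics, used
# as independent oracles. Everything here is written with explicit loops
# over allele copies / pairs, deliberately avoiding the vectorized code
# paths of the package.

# expand one site's dosages into allele copies (0/1), dropping missing
copies_at_site <- function(dos, j) {
  out <- integer(0)
  for (i in seq_len(nrow(dos))) {
    d <- dos[i, j]
    if (is.na(d)) next
    out <- c(out, switch(as.character(d), "0" = c(0L, 0L),
                         "1" = c(0L, 1L), "2" = c(1L, 1L)))
  }
  out
}

pi_naive <- function(dos) {
  total <- 0
  for (j in seq_len(ncol(dos))) {
    cp <- copies_at_site(dos, j)
    n <- length(cp)
    if (n < 2) next
    diff_pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      if (cp[a] != cp[b]) diff_pairs <- diff_pairs + 1
    total <- total + diff_pairs / choose(n, 2)
  }
  total
}

is_segregating_naive <- function(dos, j) {
  cp <- copies_at_site(dos, j)
  length(cp) >= 2 && any(cp == 0) && any(cp == 1)
}

theta_w_naive <- function(dos) {
  S <- 0
  for (j in seq_len(ncol(dos))) if (is_segregating_naive(dos, j)) S <- S + 1
  if (S == 0) return(0)
  n <- 0
  for (i in seq_len(nrow(dos))) if (any(!is.na(dos[i, ]))) n <- n + 2
  a <- 0
  for (i in seq_len(n - 1)) a <- a + 1 / i
  S / a
}

tajimas_d_naive <- function(dos) {
  S <- 0
  for (j in seq_len(ncol(dos))) if (is_segregating_naive(dos, j)) S <- S + 1
  if (S == 0) return(0)
  n <- 0
  for (i in seq_len(nrow(dos))) if (any(!is.na(dos[i, ]))) n <- n + 2
  if (n < 3) return(0)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(0)
  (pi_naive(dos) - S / a1) / sqrt(v)
}

r2_naive <- function(a, b) {
  xs <- ys <- numeric(0)
  for (i in seq_along(a)) {
    if (!is.na(a[i]) && !is.na(b[i])) {
      xs <- c(xs, a[i]); ys <- c(ys, b[i])
    }
  }
  n <- length(xs)
  if (n < 2) return(NA_real_)
  mx <- sum(xs) / n; my <- sum(ys) / n
  sxx <- sum((xs - mx)^2); syy <- sum((ys - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy <- sum((xs - mx) * (ys - my))
  (sxy / sqrt(sxx * syy))^2
}

usable_naive <- function(dos) {
  keep <- integer(0)
  for (j in seq_len(ncol(dos))) if (is_segregating_naive(dos, j))
    keep <- c(keep, j)
  keep
}

zns_naive <- function(dos) {
  keep <- usable_naive(dos)
  if (length(keep) < 2) return(0)
  vals <- numeric(0)
  for (a in seq_len(length(keep) - 1)) for (b in (a + 1):length(keep)) {
    r2 <- r2_naive(dos[, keep[a]], dos[, keep[b]])
    if (!is.na(r2)) vals <- c(vals, r2)
  }
  if (length(vals) == 0) return(0)
  sum(vals) / length(vals)
}

omega_max_naive <- function(dos) {
  keep <- usable_naive(dos)
  S <- length(keep)
  if (S < 4) return(0)
  r2m <- matrix(0, S, S)
  for (a in 1:(S - 1)) for (b in (a + 1):S) {
    v <- r2_naive(dos[, keep[a]], dos[, keep[b]])
    r2m[a, b] <- r2m[b, a] <- if (is.na(v)) 0 else v
  }
  best <- 0
  for (l in 2:(S - 2)) {
    sl <- sr <- sb <- 0
    for (a in 1:(l - 1)) for (b in (a + 1):l) sl <- sl + r2m[a, b]
    for (a in (l + 1):(S - 1)) for (b in (a + 1):S) sr <- sr + r2m[a, b]
    for (a in 1:l) for (b in (l + 1):S) sb <- sb + r2m[a, b]
    if (sb == 0) next
    w <- ((sl + sr) / (choose(l, 2) + choose(S - l, 2))) /
      (sb / (l * (S - l)))
    if (w > best) best <- w
  }
  best
}

pwdiff_naive <- function(dos) {
  n <- nrow(dos)
  d <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    acc <- 0
    for (s in seq_len(ncol(dos)))
      if (!is.na(dos[i, s]) && !is.na(dos[j, s]))
        acc <- acc + abs(dos[i, s] - dos[j, s])
    d <- c(d, acc)
  }
  m <- sum(d) / length(d)
  m2 <- sum((d - m)^2) / length(d)
  if (m2 == 0) return(c(0, 0, 0))
  m3 <- sum((d - m)^3) / length(d)
  m4 <- sum((d - m)^4) / length(d)
  c(m2, m3 / m2^1.5, m4 / m2^2 - 3)
}

h_stats_naive <- function(freq) {
  h1 <- sum(freq^2)
  p1 <- freq[1]
  p2 <- if (length(freq) >= 2) freq[2] else 0
  rest <- if (length(freq) >= 3) sum(freq[3:length(freq)]^2) else 0
  c((p1 + p2)^2 + rest, h1, (h1 - p1^2) / h1)
}

# random small dosage matrix, optionally with missingness
random_dosage_matrix <- function(n_ind, n_sites, p_missing = 0) {
  m <- matrix(sample(0:2, n_ind * n_sites, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)),
              nrow = n_ind)
  if (p_missing > 0)
    m[runif(length(m)) < p_missing] <- NA
  m
}
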
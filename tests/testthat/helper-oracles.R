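# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration/naive scanning, never by calling the
# implementation paths they check.

# exhaustive regex scan for GATC motif starts (0-based)
oracle_gatc_starts <- function(seq) {
  hits <- gregexpr("(?=GATC)", seq, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

# recursive flood fill component count (8- or 4-connectivity)
oracle_component_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  n <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    n <- n + 1
    stack <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(r, cc)
        }
      }
    }
  }
  n
}

# exhaustive 0..254 threshold search minimizing Huang-Wang fuzziness,
# written independently from the implementation
oracle_huang_threshold <- function(image8) {
  v <- as.integer(round(image8))
  h <- tabulate(v + 1L, nbins = 256L)
  g <- 0:255
  C <- max(g[h > 0]) - min(g[h > 0])
  best_t <- NA; best_f <- Inf
  for (t in 0:254) {
    lo <- h[g <= t]; hi <- h[g > t]
    if (sum(lo) == 0 || sum(hi) == 0) next
    mu0 <- sum(lo * g[g <= t]) / sum(lo)
    mu1 <- sum(hi * g[g > t]) / sum(hi)
    f <- 0
    for (gi in g[h > 0]) {
      mu <- if (gi <= t) mu0 else mu1
      u <- 1 / (1 + abs(gi - mu) / C)
      if (u > 0 && u < 1)
        f <- f + h[gi + 1] * (-u * log(u) - (1 - u) * log(1 - u))
    }
    if (f < best_f) { best_f <- f; best_t <- t }
  }
  best_t
}

# exact two-sided Mann-Whitney p by enumeration over all group labelings
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, u_of)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force most-probable HMM state path by full enumeration
oracle_best_path <- function(em, lA, lpi) {
  Tn <- nrow(em)
  grid <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  best <- NULL; bv <- -Inf
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    v <- lpi[p[1]] + em[1, p[1]]
    if (Tn > 1)
      for (t in 2:Tn) v <- v + lA[p[t - 1], p[t]] + em[t, p[t]]
    if (v > bv) { bv <- v; best <- p }
  }
  unname(as.integer(best))
}

# small high-quality read table
make_reads <- function(seqs, qual_char = "I") {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = vapply(seqs, function(s) strrep(qual_char, nchar(s)),
                              character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
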
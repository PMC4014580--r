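# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal code paths (tapply/loops instead of rowsum
# vectorisation) so they can certify the implementation.

# all permutations of 1..n as an n! x n matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matrix(0L, nrow(sub), n)
    m[, i] <- n
    m[, -i] <- sub
    out[[i]] <- m
  }
  do.call(rbind, out)
}

# WR amplitude by direct folding with tapply (NA-aware), sample sd
oracle_wr_amplitude <- function(v, period) {
  grp <- (seq_along(v) - 1L) %% period
  m <- tapply(v, grp, mean, na.rm = TRUE)
  m <- m[!is.nan(m)]
  stats::sd(m)
}

# exhaustive permutation p-value of the WR amplitude at one period:
# proportion of all rearrangements of the observed values (over the observed
# slots) whose amplitude reaches the observed one (identity included)
oracle_wr_exact_p <- function(v, period) {
  obs <- which(!is.na(v))
  vo <- v[obs]
  pm <- all_perms(length(vo))
  a0 <- oracle_wr_amplitude(v, period)
  amps <- apply(pm, 1L, function(p) {
    w <- v
    w[obs] <- vo[p]
    oracle_wr_amplitude(w, period)
  })
  mean(amps >= a0 - 1e-12)
}

# exhaustive permutation p for the two-tailed Pearson correlation
oracle_cor_exact_p <- function(x, y) {
  pm <- all_perms(length(y))
  r0 <- stats::cor(x, y)
  rr <- apply(pm, 1L, function(p) stats::cor(x, y[p]))
  mean(abs(rr) >= abs(r0) - 1e-12)
}

# nearest-neighbour counts by explicit double loop
oracle_nn_counts <- function(points, taxa) {
  n <- nrow(points)
  N <- matrix(0L, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_len(n)) {
    d <- sqrt((points$x - points$x[i])^2 + (points$y - points$y[i])^2)
    d[i] <- Inf
    j <- which(d == min(d))[1L]
    N[points$taxon[i], points$taxon[j]] <- N[points$taxon[i], points$taxon[j]] + 1L
  }
  N
}

# Dixon segregation index from first principles (both odds written out)
oracle_segregation <- function(N, n) {
  Ntot <- sum(n)
  k <- length(n)
  S <- matrix(NA_real_, k, k, dimnames = dimnames(N))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    odds_obs <- N[a, b] / (n[a] - N[a, b])
    odds_exp <- if (a == b) (n[a] - 1) / (Ntot - n[a])
                else n[b] / (Ntot - 1 - n[b])
    S[a, b] <- log(odds_obs / odds_exp)
  }
  S
}

# three well-separated single-cluster taxa, repeated over frames
segregated_points <- function(n_frames, per_taxon = c(A = 5L, B = 6L, C = 7L),
                              jitter = 8, seed = 42L) {
  centres <- list(A = c(50, 50), B = c(450, 60), C = c(250, 420))
  set.seed(seed)
  out <- list()
  for (f in seq_len(n_frames)) {
    for (tx in names(per_taxon)) {
      k <- per_taxon[[tx]]
      out[[length(out) + 1L]] <- data.frame(
        frame = f, taxon = tx,
        x = centres[[tx]][1L] + stats::rnorm(k, 0, jitter),
        y = centres[[tx]][2L] + stats::rnorm(k, 0, jitter))
    }
  }
  do.call(rbind, out)
}

toy_grid <- function(n, start = "2011-10-07 08:00") {
  g <- build_grid(start, start)
  seq(g, by = 3600, length.out = n)
}
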
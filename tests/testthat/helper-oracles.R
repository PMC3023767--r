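# Independent oracles used to freeze expected values: each is a direct,
# brute-force restatement of the quantity being tested, sharing no code with
# the implementation path it checks.

# disjoint-segment MSD by explicit enumeration
oracle_msd <- function(x, y, dt) {
  nf <- length(x)
  ndisp <- nf - 1L
  do.call(rbind, lapply(seq_len(ndisp), function(n) {
    vals <- c()
    start <- 1L
    while (start + n <= nf) {
      vals <- c(vals, (x[start + n] - x[start])^2 + (y[start + n] - y[start])^2)
      start <- start + n
    }
    data.frame(interval = n, t_min = n * dt, msd_um2 = mean(vals),
               n_segments = length(vals))
  }))
}

# shoelace area / edge-sum perimeter by independent elementwise summation
oracle_shoelace <- function(v) {
  n <- nrow(v)
  a <- 0; p <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- a + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
    p <- p + sqrt(sum((v[j, ] - v[i, ])^2))
  }
  list(area = abs(unname(a)) / 2, perimeter = unname(p))
}

# mass-weighted COM by explicit sum(m_i r_i) / sum(m_i)
oracle_com <- function(coords, masses) {
  num <- c(0, 0, 0)
  for (i in seq_len(nrow(coords))) num <- num + masses[i] * coords[i, ]
  num / sum(masses)
}

# permutation p-value for the pooled two-sample t statistic, vectorized
oracle_permutation_p <- function(g1, g2, n_perm = 1e5) {
  x <- c(g1, g2)
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  pooled_t <- function(s1, ss1) {
    m1 <- s1 / n1
    s2 <- sum(x) - s1
    m2 <- s2 / n2
    v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
    v2 <- (sum(x^2) - ss1 - n2 * m2^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t_obs <- pooled_t(sum(g1), sum(g1^2))
  perm_idx <- replicate(n_perm, sample.int(n, n1))
  xm <- matrix(x[perm_idx], nrow = n1)
  xm2 <- matrix(x[perm_idx]^2, nrow = n1)
  t_perm <- pooled_t(colSums(xm), colSums(xm2))
  mean(abs(t_perm) >= abs(t_obs))
}

# make a noiseless single-event curve with exact planted parameters
make_noiseless_curve <- function(f_r = 80, k_eff = 0.6, min_index = 800,
                                 n = 2000, velocity = 5000) {
  disp <- as.numeric(0:(n - 1))
  force <- numeric(n)
  ramp_len <- ceiling(f_r / k_eff)
  d_start <- disp[min_index] - f_r / k_eff
  jr <- (min_index - ramp_len):min_index
  force[jr] <- -pmax(0, k_eff * (disp[jr] - d_start))
  force_curve(disp, force, velocity = velocity, spring_constant = 25)
}
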
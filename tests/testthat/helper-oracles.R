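# Independent brute-force oracles, kept deliberately naive (explicit loops,
# textbook formulas) so they share no code with the implementation.

# Pair enumeration over every pixel for one GLCM direction.
oracle_glcm <- function(levels, direction_deg, n_levels,
                        symmetric = TRUE, normalize = TRUE) {
  off <- switch(as.character(direction_deg),
                "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                "135" = c(-1, -1))
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  if (normalize) counts / sum(counts) else counts
}

# Exhaustive O(n^2) summation of the four texture statistics.
oracle_glcm_stats <- function(p) {
  n <- nrow(p)
  hom <- 0; con <- 0; ene <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    hom <- hom + p[i, j] / (1 + abs(i - j))
    con <- con + p[i, j] * (i - j)^2
    ene <- ene + p[i, j]^2
    mu_i <- mu_i + i * p[i, j]
    mu_j <- mu_j + j * p[i, j]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 1:n) for (j in 1:n) {
    v_i <- v_i + (i - mu_i)^2 * p[i, j]
    v_j <- v_j + (j - mu_j)^2 * p[i, j]
    cov <- cov + (i - mu_i) * (j - mu_j) * p[i, j]
  }
  corr <- if (v_i > 0 && v_j > 0) cov / sqrt(v_i * v_j) else NA_real_
  c(homogeneity = hom, contrast = con, energy = ene, correlation = corr)
}

# Per-pixel minimum Euclidean distance to any non-lung pixel.
oracle_band <- function(mask, depth) {
  bg <- which(!mask, arr.ind = TRUE)
  band <- mask & FALSE
  for (idx in which(mask)) {
    r <- (idx - 1) %% nrow(mask) + 1
    c <- (idx - 1) %/% nrow(mask) + 1
    if (nrow(bg) == 0) next
    d <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
    if (d <= depth) band[idx] <- TRUE
  }
  band
}

# Textbook moment formulas.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, sd = sqrt(sum((x - mu)^2) / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis_excess = m4 / m2^2 - 3)
}

# Textbook one-way ANOVA partition.
oracle_oneway <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ss_b <- 0; ss_w <- 0
  for (g in groups) {
    ss_b <- ss_b + length(g) * (mean(g) - gm)^2
    ss_w <- ss_w + sum((g - mean(g))^2)
  }
  df_b <- length(groups) - 1
  df_w <- length(all) - length(groups)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(ss_between = ss_b, ss_within = ss_w, f = f,
       p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# Explicit sums-of-squares for the balanced two-way (time + subject) model.
oracle_rm_ss <- function(y, subject, time) {
  subject <- as.character(subject); time <- as.character(time)
  subs <- unique(subject); tps <- unique(time)
  s <- length(subs); t <- length(tps)
  gm <- mean(y)
  ss_time <- 0
  for (tp in tps) ss_time <- ss_time + s * (mean(y[time == tp]) - gm)^2
  ss_sub <- 0
  for (sb in subs) ss_sub <- ss_sub + t * (mean(y[subject == sb]) - gm)^2
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_time - ss_sub
  f <- (ss_time / (t - 1)) / (ss_err / ((t - 1) * (s - 1)))
  list(ss_time = ss_time, ss_subject = ss_sub, ss_error = ss_err,
       ss_total = ss_tot, f = f)
}

disc_mask <- function(n, center, radius) {
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  (r - center)^2 + (c - center)^2 <= radius^2
}

# Small random masked level image for GLCM property tests.
random_masked_slice <- function(seed, max_dim = 16) {
  set.seed(seed)
  nr <- sample(4:max_dim, 1); nc <- sample(4:max_dim, 1)
  hu <- matrix(runif(nr * nc, -1024, -242), nr, nc)
  mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
  # guarantee at least one adjacent pair in every direction
  mask[1:2, 1:2] <- TRUE
  list(slice = ct_slice(hu, c(1, 1)), mask = lung_mask(mask, "Rx"))
}

# hu_mean study table of a simulated CT study (full lung masks).
hu_mean_table <- function(study) {
  tab <- NULL
  for (sl in study$slices) {
    for (lung in c("Rx", "CON")) {
      f <- first_order_stats(sl, study$masks[[lung]])
      tab <- rbind(tab, data.frame(
        sheep_id = sl$sheep_id, lung_label = lung,
        timepoint_days = sl$timepoint_days,
        variable_name = "hu_mean", value = f$hu_mean))
    }
  }
  tab
}
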
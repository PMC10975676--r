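# Small builders and independent oracles shared across test files.

# build a vmr_track from an n x 2 coordinate matrix
make_track <- function(xy, fps = 30, radius = 50, subject_id = "s1") {
  xy <- as.matrix(xy)
  vmr_track(subject_id,
            data.frame(frame = seq_len(nrow(xy)) - 1L,
                       time_s = (seq_len(nrow(xy)) - 1L) / fps,
                       x_mm = xy[, 1], y_mm = xy[, 2]),
            fps = fps, arena_radius = radius)
}

# kinematics tibble from a bare speed profile (for classification tests)
make_kin <- function(speed_mm_s, fps = 30) {
  n <- length(speed_mm_s)
  tibble::tibble(frame = 0:(n - 1), time_s = (0:(n - 1)) / fps,
                 step_mm = speed_mm_s / fps, speed_mm_s = speed_mm_s,
                 turn_rad = rep(0, n))
}

# all permutations of 1..n (plain recursion; used only for tiny n)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Brute-force permutation ANOVA oracle: enumerate every ordering of the
# observations, recompute the one-way F from group means and variances,
# and count orderings at least as extreme as the observed one.
perm_oracle_linear <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  f_stat <- function(v) {
    m <- tapply(v, groups, mean)
    ng <- tapply(v, groups, length)
    k <- length(m)
    ssb <- sum(ng * (m - mean(v))^2)
    ssw <- sum((v - m[groups])^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  obs <- f_stat(values)
  perms <- all_perms(n)
  stats <- apply(perms, 1, function(ix) f_stat(values[ix]))
  mean(stats >= obs - 1e-9 * max(1, abs(obs)))
}

# Brute-force binomial oracle: every ordering of the 0/1 outcomes,
# likelihood-ratio statistic of the one-way logistic model recomputed
# from scratch via binomial log-likelihoods.
perm_oracle_binomial <- function(y, groups) {
  groups <- factor(groups)
  n <- length(y)
  ll <- function(s, m) {
    p <- s / m
    out <- 0
    if (s > 0) out <- out + s * log(p)
    if (m - s > 0) out <- out + (m - s) * log(1 - p)
    out
  }
  dev_stat <- function(v) {
    s <- tapply(v, groups, sum)
    m <- tapply(v, groups, length)
    2 * (sum(mapply(ll, s, m)) - ll(sum(v), n))
  }
  obs <- dev_stat(y)
  perms <- all_perms(n)
  stats <- apply(perms, 1, function(ix) dev_stat(y[ix]))
  mean(stats >= obs - 1e-9 * max(1, abs(obs)))
}

rmse_to <- function(track, xy_ref) {
  xy <- cbind(track$frames$x_mm, track$frames$y_mm)
  sqrt(mean(rowSums((xy - xy_ref)^2)))
}
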
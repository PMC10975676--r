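#' Configuration for the permutation ANOVA
#'
#' The permutation test estimates the p-value `P` by Monte Carlo and
#' stops when the estimated standard error of `P` drops below
#' `P * se_ratio`, or at the iteration cap. The reference analysis this
#' mirrors used `se_ratio = 1e-5` with a cap of 2e9 iterations; that cap
#' is impractical on a workstation, so the default cap is 1e5 with the
#' same (rarely-reached) SE rule, both configurable. Designs whose
#' number of distinct label assignments is at most `exhaustive_limit`
#' are enumerated exactly instead.
#'
#' @param se_ratio Target ratio: stop when `se(P) < P * se_ratio`
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 1e5).
#' @param min_iter Minimum iterations before the SE rule is checked
#'   (default 1000).
#' @param batch Permutations drawn per vectorized batch (default 1e4).
#' @param exhaustive_limit Enumerate exactly when the number of
#'   distinct assignments is at most this (default 1e4).
#' @param response_type `"linear"` (F-type statistic) or `"binomial"`
#'   (logistic-model deviance statistic).
#' @param seed Optional integer seed for the permutation stream.
#' @return A `perm_config` list.
#' @export
perm_config <- function(se_ratio = 1e-5, max_iter = 1e5, min_iter = 1000,
                        batch = 1e4, exhaustive_limit = 1e4,
                        response_type = c("linear", "binomial"),
                        seed = NULL) {
  response_type <- match.arg(response_type)
  if (se_ratio <= 0) stop("se_ratio must be > 0", call. = FALSE)
  if (max_iter < min_iter || min_iter < 1) {
    stop("need max_iter >= min_iter >= 1", call. = FALSE)
  }
  structure(list(se_ratio = se_ratio, max_iter = max_iter,
                 min_iter = min_iter, batch = batch,
                 exhaustive_limit = exhaustive_limit,
                 response_type = response_type, seed = seed),
            class = "perm_config")
}

perm_result <- function(statistic_obs, p_hat, se_p, n_iter, stopped_by) {
  structure(list(statistic_obs = statistic_obs, p_hat = p_hat, se_p = se_p,
                 n_iter = n_iter, stopped_by = stopped_by),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> stat = %.4g, p = %.5g (se %.2g), %s after %d iterations\n",
              x$statistic_obs, x$p_hat, x$se_p, x$stopped_by, x$n_iter))
  invisible(x)
}

# number of distinct group-label assignments: n! / prod(n_g!)
n_distinct_assignments <- function(n_g) {
  exp(lgamma(sum(n_g) + 1) - sum(lgamma(n_g + 1)))
}

# all distinct labelings of positions 1..n into groups with sizes counts;
# returns a matrix with one labeling per column
enum_labelings <- function(counts) {
  n <- sum(counts)
  rec <- function(pos, counts_left, lab) {
    if (length(counts_left) == 1L) {
      lab[pos] <- length(counts)
      return(list(lab))
    }
    g <- length(counts) - length(counts_left) + 1L
    ch <- utils::combn(length(pos), counts_left[1])
    out <- list()
    for (j in seq_len(ncol(ch))) {
      lab2 <- lab
      lab2[pos[ch[, j]]] <- g
      out <- c(out, rec(pos[-ch[, j]], counts_left[-1], lab2))
    }
    out
  }
  labs <- rec(seq_len(n), counts, integer(n))
  matrix(unlist(labs), nrow = n)
}

ssb_stat <- function(group_sums, n_g, grand, n) {
  colSums(group_sums^2 / n_g) - grand^2 / n
}

#' One-way nonparametric permutation ANOVA (linear response)
#'
#' Computes the observed one-way F statistic (for a single factor the
#' type-III and sequential decompositions coincide), then permutes the
#' group labels of the raw observations uniformly. The estimated
#' p-value is the proportion of permuted statistics at least as large
#' as the observed one, with the add-one estimator `(b + 1) / (m + 1)`
#' so the Monte Carlo p-value is never zero and remains a valid
#' permutation p-value. Permutation proceeds in batches until the
#' standard-error stopping rule of [perm_config()] is met or the cap is
#' reached; small designs are enumerated exactly (no add-one, `se = 0`).
#'
#' The between-group sum of squares is used internally for the
#' permutation comparison; it is a strictly increasing function of F
#' under label permutation (the total sum of squares is invariant), so
#' the p-value is identical to one computed on F itself.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param cfg A [perm_config()].
#' @return A `perm_result`.
#' @export
#' @examples
#' perm_anova(c(1, 2, 3, 4), c("a", "a", "b", "b")) # exhaustive: p = 1/3
perm_anova <- function(values, groups, cfg = perm_config()) {
  groups <- factor(groups)
  values <- as.numeric(values)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("invalid design: need >= 2 groups", call. = FALSE)
  n_g <- as.numeric(table(groups))
  if (any(n_g < 1)) stop("invalid design: empty group", call. = FALSE)
  sst <- sum(values^2) - sum(values)^2 / n
  if (sst <= .Machine$double.eps * max(1, sum(values^2))) {
    warning("zero total variance; p = 1 returned", call. = FALSE)
    return(perm_result(0, 1, 0, 0L, "degenerate"))
  }
  grand <- sum(values)
  obs_ssb <- sum(tapply(values, groups, sum)^2 / n_g) - grand^2 / n
  f_obs <- (obs_ssb / (k - 1)) / ((sst - obs_ssb) / (n - k))
  tol <- 1e-9 * max(1, abs(obs_ssb))

  if (n_distinct_assignments(n_g) <= cfg$exhaustive_limit) {
    labs <- enum_labelings(n_g)
    stats <- vapply(seq_len(ncol(labs)), function(j) {
      s <- rowsum(values, labs[, j])[, 1]
      sum(s^2 / n_g) - grand^2 / n
    }, numeric(1))
    p <- mean(stats >= obs_ssb - tol)
    return(perm_result(f_obs, p, 0, ncol(labs), "exhaustive"))
  }

  run <- function() {
    b <- 0L; m <- 0L
    stopped <- "max_iter"
    gidx <- as.integer(groups)
    while (m < cfg$max_iter) {
      bsize <- min(cfg$batch, cfg$max_iter - m)
      idx <- vapply(seq_len(bsize), function(j) sample.int(n), integer(n))
      X <- matrix(values[idx], n, bsize)
      S <- rowsum(X, gidx)
      stats <- ssb_stat(S, n_g, grand, n)
      b <- b + sum(stats >= obs_ssb - tol)
      m <- m + bsize
      p <- (b + 1) / (m + 1)
      se <- sqrt(p * (1 - p) / m)
      if (m >= cfg$min_iter && se < p * cfg$se_ratio) {
        stopped <- "se_rule"
        break
      }
    }
    p <- (b + 1) / (m + 1)
    perm_result(f_obs, p, sqrt(p * (1 - p) / m), m, stopped)
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

# binomial one-way deviance statistic from group success counts
g2_stat <- function(s, n_g, S, N) {
  # s: k x B matrix of per-group successes
  p0 <- S / N
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  term <- xlogx(s) - s * log(n_g * p0) +
    xlogx(n_g - s) - (n_g - s) * log(n_g * (1 - p0))
  2 * colSums(term)
}

#' One-way permutation ANOVA for binary outcomes (binomial response)
#'
#' For per-subject binary outcomes the statistic is the likelihood-ratio
#' (deviance) statistic of a one-way logistic-link model against the
#' intercept-only model, which depends on the data only through the
#' per-group success counts. Labels are permuted as in [perm_anova()].
#' When the lattice of possible per-group success counts is small the
#' p-value is computed exactly by multivariate-hypergeometric
#' enumeration.
#'
#' @param successes Binary 0/1 outcome per subject, or per-cluster
#'   success counts when `totals` is supplied.
#' @param groups Group labels, one per subject/cluster.
#' @param totals Cluster sizes matching `successes` (default 1, i.e.
#'   per-subject binary data). Clusters are expanded to subjects before
#'   permutation.
#' @param cfg A [perm_config()].
#' @return A `perm_result`.
#' @export
perm_anova_binomial <- function(successes, groups, totals = 1,
                                cfg = perm_config(response_type = "binomial")) {
  totals <- rep_len(totals, length(successes))
  if (any(successes < 0 | successes > totals)) {
    stop("successes must lie in [0, totals]", call. = FALSE)
  }
  y <- rep(rep(c(1L, 0L), length(successes)),
           times = as.vector(rbind(successes, totals - successes)))
  g <- rep(rep(as.character(groups), each = 2),
           times = as.vector(rbind(successes, totals - successes)))
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2L) stop("invalid design: need >= 2 groups", call. = FALSE)
  n_g <- as.numeric(table(g))
  N <- length(y)
  S <- sum(y)
  if (S == 0L || S == N) {
    warning("degenerate outcome (all 0 or all 1); p = 1 returned",
            call. = FALSE)
    return(perm_result(0, 1, 0, 0L, "degenerate"))
  }
  s_obs <- as.numeric(rowsum(y, g))
  obs <- g2_stat(matrix(s_obs, ncol = 1), n_g, S, N)
  tol <- 1e-9 * max(1, obs)

  if (prod(pmin(n_g, S) + 1) <= cfg$exhaustive_limit) {
    grid <- do.call(expand.grid, lapply(n_g, function(m) 0:m))
    grid <- as.matrix(grid[rowSums(grid) == S, , drop = FALSE])
    stats <- g2_stat(t(grid), n_g, S, N)
    logw <- vapply(seq_len(nrow(grid)), function(r) {
      sum(lchoose(n_g, grid[r, ]))
    }, numeric(1)) - lchoose(N, S)
    p <- sum(exp(logw)[stats >= obs - tol])
    return(perm_result(obs, min(p, 1), 0, nrow(grid), "exhaustive"))
  }

  run <- function() {
    b <- 0L; m <- 0L
    stopped <- "max_iter"
    gidx <- as.integer(g)
    while (m < cfg$max_iter) {
      bsize <- min(cfg$batch, cfg$max_iter - m)
      idx <- vapply(seq_len(bsize), function(j) sample.int(N), integer(N))
      X <- matrix(y[idx], N, bsize)
      Smat <- rowsum(X, gidx)
      stats <- g2_stat(Smat, n_g, S, N)
      b <- b + sum(stats >= obs - tol)
      m <- m + bsize
      p <- (b + 1) / (m + 1)
      se <- sqrt(p * (1 - p) / m)
      if (m >= cfg$min_iter && se < p * cfg$se_ratio) {
        stopped <- "se_rule"
        break
      }
    }
    p <- (b + 1) / (m + 1)
    perm_result(obs, p, sqrt(p * (1 - p) / m), m, stopped)
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

#' Tukey honest significant difference comparisons
#'
#' Pairwise group comparisons with studentized-range adjusted p-values
#' (family-wise coverage), via [stats::TukeyHSD()] on a one-way fit;
#' unbalanced designs use the unequal-n generalization. Groups with a
#' single observation are excluded with a warning. When a control group
#' is designated, pairs involving it carry the direction of the treated
#' group relative to control.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Family-wise significance level (default 0.05).
#' @param control Optional control group label for direction calls.
#' @return Tibble with one row per pair: `group_a`, `group_b`, `diff`
#'   (mean of `group_a` minus mean of `group_b`), `lwr`, `upr`, `p_adj`,
#'   `significant`, `direction` (`"Increase"`/`"Decrease"` of the
#'   treated group vs control, `NA` for non-control pairs).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05, control = NULL) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("excluding group(s) with a single observation: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    keep <- groups %in% names(sizes)[sizes >= 2]
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  ga <- vapply(pairs, `[`, character(1), 1)
  gb <- vapply(pairs, `[`, character(1), 2)
  out <- tibble::tibble(
    group_a = ga, group_b = gb,
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
  dir <- rep(NA_character_, nrow(out))
  if (!is.null(control)) {
    means <- tapply(values, groups, mean)
    has_ctl <- out$group_a == control | out$group_b == control
    treated <- ifelse(out$group_a == control, out$group_b, out$group_a)
    dir[has_ctl] <- ifelse(
      means[treated[has_ctl]] >= means[[control]], "Increase", "Decrease")
  }
  out$direction <- dir
  out
}

#' Expected number of significant tests under a global null
#'
#' The count of tests expected significant by chance alone at level
#' `alpha` when `n_tests` independent endpoints are screened.
#'
#' @param n_tests Number of tests run.
#' @param alpha Significance level (default 0.05).
#' @return `alpha * n_tests`.
#' @export
#' @examples
#' expected_false_positives(28) # 1.4
expected_false_positives <- function(n_tests, alpha = 0.05) {
  alpha * n_tests
}

#' Permutation ANOVA battery over an endpoint table
#'
#' Runs [perm_anova()] and [tukey_hsd()] for every endpoint column,
#' grouping subjects by dose within each chemical, and reports the
#' expected-by-chance significant count alongside the observed count.
#'
#' @param endpoints Endpoint tibble (as from [compute_endpoints()] rows
#'   bound together), with a `subject_id` column.
#' @param design Design tibble from [read_design()].
#' @param cfg A [perm_config()].
#' @param endpoint_cols Endpoint columns to test (default
#'   [endpoint_names()] intersected with available columns).
#' @param alpha Significance level (default 0.05).
#' @return List with `anova` (tibble: `chemical`, `endpoint`,
#'   `statistic`, `p`, `se_p`, `n_iter`, `stopped_by`), `tukey` (tibble
#'   of pairwise rows), `n_tests`, `expected_by_chance`,
#'   `observed_significant`.
#' @export
endpoint_battery <- function(endpoints, design, cfg = perm_config(),
                             endpoint_cols = NULL, alpha = 0.05) {
  if (is.null(endpoint_cols)) {
    endpoint_cols <- intersect(endpoint_names(), names(endpoints))
  }
  miss <- setdiff(endpoint_cols, names(endpoints))
  if (length(miss) > 0) {
    stop("missing endpoint column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- merge(endpoints, design, by = "subject_id")
  if (nrow(df) == 0L) stop("empty design/endpoint join", call. = FALSE)
  anova_rows <- list()
  tukey_rows <- list()
  for (chem in unique(df$chemical)) {
    sub <- df[df$chemical == chem, , drop = FALSE]
    grp <- factor(sub$dose_ppm)
    ctl <- as.character(min(sub$dose_ppm))
    for (ep in endpoint_cols) {
      res <- perm_anova(sub[[ep]], grp, cfg)
      anova_rows[[length(anova_rows) + 1L]] <- tibble::tibble(
        chemical = chem, endpoint = ep, statistic = res$statistic_obs,
        p = res$p_hat, se_p = res$se_p, n_iter = res$n_iter,
        stopped_by = res$stopped_by)
      tk <- tukey_hsd(sub[[ep]], grp, alpha = alpha, control = ctl)
      tukey_rows[[length(tukey_rows) + 1L]] <-
        tibble::tibble(chemical = chem, endpoint = ep, tk)
    }
  }
  anova_tab <- do.call(rbind, anova_rows)
  list(anova = anova_tab,
       tukey = do.call(rbind, tukey_rows),
       n_tests = nrow(anova_tab),
       expected_by_chance = expected_false_positives(nrow(anova_tab), alpha),
       observed_significant = sum(anova_tab$p < alpha))
}
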
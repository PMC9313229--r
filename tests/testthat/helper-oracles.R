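# Independent brute-force oracles used across the test files. These are
# deliberately naive re-derivations from first principles — sums written
# out longhand, exhaustive enumeration, numeric 1-D optimization — and
# never call the package functions they check.

# product-moment correlation written out as the defining sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- sum(x) / n; ym <- sum(y) / n
  num <- sum((x - xm) * (y - ym))
  num / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# average ranks by brute force (count smaller + share ties), then pearson
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    smaller <- sum(x < x[i])
    ties <- sum(x == x[i])
    smaller + (ties + 1) / 2
  }, numeric(1))
}
oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# two-sided p for a correlation via the t transform, evaluated longhand
oracle_cor_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

oracle_fisher_z <- function(r1, n1, r2, n2) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

# two-group log-rank by an explicit tally over event-time risk sets
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  ts <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# the step-up FDR formula applied literally: ranked p * m / j, capped at 1,
# running minimum from the largest rank down, mapped back
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, ranked * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch statistic and p written out longhand
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# optimal 2-partition of scalar values by full enumeration of all 2^(n-1)-1
# nontrivial assignments (n <= 16)
oracle_ward_2split <- function(x) {
  n <- length(x)
  stopifnot(n >= 2, n <= 16)
  best <- NULL; bestw <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    m <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (all(m) || !any(m)) next
    w <- sum((x[m] - mean(x[m]))^2) + sum((x[!m] - mean(x[!m]))^2)
    if (w < bestw - 1e-12) { bestw <- w; best <- m }
  }
  list(members = best, wss = bestw)
}

# Cox partial log-likelihood for a single binary covariate, no ties,
# written from the definition; maximized by golden-section search
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}
oracle_cox_beta <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, event, x),
                  c(lower, upper), tol = 1e-10)$minimum
}

# small deterministic expression fixture: g genes x s samples
fixture_expression <- function(g = 5, s = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(g * s, mean = 8), g, s,
              dimnames = list(sprintf("G%03d", 1:g), sprintf("S%02d", 1:s)))
  m
}

fixture_clinical <- function(n_wt = 5, n_mut = 3) {
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_wt + n_mut)),
    days_to_death = c(rep(NA_integer_, n_wt), 100L * seq_len(n_mut)),
    days_to_last_follow_up = c(300L * seq_len(n_wt), rep(NA_integer_, n_mut)),
    vital_status = c(rep("alive", n_wt), rep("dead", n_mut)),
    tp53_status = c(rep("wild_type", n_wt), rep("mutated", n_mut)),
    subtype = NA_character_
  )
}
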
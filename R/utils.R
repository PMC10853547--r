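#' @keywords internal
"_PACKAGE"

## pseudo-count used in every log-ratio computation
.EPS <- 1e-9

#' Two-sample Wilcoxon rank-sum test
#'
#' One comparison of `x` (group 1) versus `y` (group 2), two-sided. Uses the
#' exact rank-sum distribution when both groups have at most 50 observations
#' and there are no ties; otherwise a normal approximation with tie
#' correction and continuity correction (the same switching rule as
#' [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors.
#' @return list with `statistic` (W, number of (x, y) pairs with x > y plus
#'   half the ties) and `p_value`.
#' @keywords internal
wilcox_rank_sum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 50 && n2 <= 50) {
    if (w > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(w, n1, n2)
    }
    p <- min(1, p)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w, p_value = p)
}

## Per-event-time risk/death tabulation shared by the log-rank and Cox
## fits: distinct event times with at-risk counts (overall and group 1)
## and death counts (overall and group 1).
surv_tables <- function(time, event, group1) {
  ut <- sort(unique(time))
  f <- match(time, ut)
  u <- length(ut)
  n <- length(time)
  n1 <- sum(group1)
  cnt <- tabulate(f, u)
  cnt1 <- tabulate(f[group1], u)
  d_all <- tabulate(f[event == 1], u)
  d1_all <- tabulate(f[event == 1 & group1], u)
  at_risk <- n - c(0, cumsum(cnt))[seq_len(u)]
  at_risk1 <- n1 - c(0, cumsum(cnt1))[seq_len(u)]
  ev <- d_all > 0
  list(dt = ut[ev], n_risk = at_risk[ev], n_risk1 = at_risk1[ev],
       d = d_all[ev], d1 = d1_all[ev])
}

## Log-rank O/E/V tabulation for a binary split.
## Returns observed minus expected events in group 1, the hypergeometric
## variance, the chi-square statistic and its p-value, all via the standard
## per-event-time tally. Vectorized over distinct event times.
logrank_core <- function(time, event, group1) {
  stopifnot(length(time) == length(event), length(group1) == length(time))
  st <- surv_tables(time, event, group1)
  if (length(st$dt) == 0) stop("no events: log-rank test undefined")
  n_risk <- st$n_risk; n_risk1 <- st$n_risk1; d <- st$d; d1 <- st$d1
  e1 <- d * n_risk1 / n_risk
  v1 <- ifelse(n_risk > 1,
               d * (n_risk1 / n_risk) * (1 - n_risk1 / n_risk) *
                 (n_risk - d) / (n_risk - 1),
               0)
  o_minus_e <- sum(d1 - e1)
  v <- sum(v1)
  stat <- if (v > 0) o_minus_e^2 / v else 0
  list(o_minus_e = o_minus_e, var = v, statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       z = if (v > 0) o_minus_e / sqrt(v) else 0)
}

## Ranks of a vector in DESCENDING order (1 = largest), average ties.
rank_desc <- function(x) rank(-x, ties.method = "average")

## validate a length-1 positive integer-ish count
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer", name))
  as.integer(x)
}

## deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + k * 7919) %% 2147483647
}
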
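# Binomial-logit-normal (BLN) distribution --------------------------------
#
# The latent per-individual log allelic fold change delta is Normal(mu, sigma^2);
# conditional on delta, the haplotype-A read count is Binomial(n, logistic(delta)).
# All probability arithmetic is carried out in log space so the law stays usable
# for haplotype totals up to ~1e5.

.gh_cache <- new.env(parent = emptyenv())

# Gauss-Hermite rule (weight exp(-t^2)), cached by order.
gh_rule <- function(order) {
  key <- as.character(order)
  rule <- .gh_cache[[key]]
  if (is.null(rule)) {
    gh <- pracma::gaussHermite(order)
    rule <- list(t = gh$x, logw = log(gh$w))
    .gh_cache[[key]] <- rule
  }
  rule
}

check_bln_args <- function(x, size, mu, sigma, allow_x_outside = FALSE) {
  if (any(!is.finite(size)) || any(size < 0) || any(size != trunc(size)))
    stop("`size` must contain non-negative integers", call. = FALSE)
  if (any(!is.finite(mu)))
    stop("`mu` must be finite", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("`sigma` must be finite and >= 0", call. = FALSE)
  if (!allow_x_outside) {
    if (any(!is.finite(x)) || any(x != trunc(x)))
      stop("`x` must contain integers", call. = FALSE)
    if (any(x < 0) || any(x > size))
      stop("`x` must lie in [0, size]", call. = FALSE)
  }
  invisible(NULL)
}

#' Binomial-logit-normal probability mass function
#'
#' Density of the number of reads on one haplotype when the latent log allelic
#' fold change is `Normal(mu, sigma^2)` and reads are binomial given the
#' latent value: `Pr(x) = \int Binom(x; size, plogis(d)) N(d; mu, sigma^2) dd`.
#' The integral is evaluated by Gauss-Hermite quadrature recentred and rescaled
#' at the per-`x` mode of the integrand, which keeps the result accurate even
#' when `sigma` is much larger than the binomial scale `1/sqrt(size)`.
#'
#' @param x integer counts in `[0, size]`.
#' @param size total haplotype-aggregated read count (non-negative integer).
#' @param mu mean of the latent log allelic fold change. Haplotype labels are
#'   arbitrary, so population-level fits use `mu = 0`.
#' @param sigma standard deviation of the latent log allelic fold change
#'   (natural-log units, `>= 0`). `sigma = 0` reduces exactly to
#'   `dbinom(x, size, plogis(mu))`.
#' @param log logical; return log-probabilities?
#' @param quad_order number of Gauss-Hermite nodes (`>= 2`).
#' @return numeric vector of (log-)probabilities.
#' @examples
#' dbln(0:4, size = 4, sigma = 0.5)
#' sum(dbln(0:50, size = 50, sigma = 1))  # normalizes to 1
#' @export
dbln <- function(x, size, mu = 0, sigma, log = FALSE, quad_order = 61) {
  stopifnot_scalar_count(quad_order, "quad_order", min = 2L)
  k <- max(length(x), length(size), length(mu), length(sigma))
  if (k == 0L) return(numeric(0))
  x <- rep_len(x, k); size <- rep_len(size, k)
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  check_bln_args(x, size, mu, sigma)
  out <- numeric(k)
  deg <- sigma == 0 | size == 0
  if (any(deg))
    out[deg] <- dbinom(x[deg], size[deg], plogis(mu[deg]), log = TRUE)
  if (any(!deg))
    out[!deg] <- bln_logpmf_quad(x[!deg], size[!deg], mu[!deg], sigma[!deg],
                                 quad_order)
  if (log) out else exp(out)
}

# log p and log(1-p) of plogis(d), numerically stable for |d| large.
log_plogis <- function(d) ifelse(d > 0, -log1p(exp(-d)), d - log1p(exp(d)))

# Mode-centred Gauss-Hermite evaluation of the BLN log-pmf; vectorized over
# equal-length x, n, mu, sigma with n >= 1 and sigma > 0.
bln_logpmf_quad <- function(x, n, mu, sigma, quad_order) {
  rule <- gh_rule(quad_order)
  tau2 <- sigma^2
  pt <- (x + 0.5) / (n + 1)
  w2 <- 1 / (n * pt * (1 - pt))      # squared binomial scale in delta
  delta <- (qlogis(pt) * tau2 + mu * w2) / (tau2 + w2)
  # Newton on the log-integrand h(d); h is strictly concave so this converges.
  for (i in seq_len(10L)) {
    p <- plogis(delta)
    step <- (x - n * p - (delta - mu) / tau2) / (n * p * (1 - p) + 1 / tau2)
    delta <- delta + step
    if (max(abs(step)) < 1e-10) break
  }
  p <- plogis(delta)
  s <- 1 / sqrt(n * p * (1 - p) + 1 / tau2)
  lc <- lchoose(n, x)
  t <- rule$t
  nodes <- rep(delta, times = quad_order) +
    sqrt(2) * rep(s, times = quad_order) * rep(t, each = length(x))
  dim(nodes) <- c(length(x), quad_order)
  lp <- log_plogis(nodes)
  h <- lc + x * lp + (n - x) * (lp - nodes) +
    dnorm(nodes, mu, sigma, log = TRUE)
  h <- h + rep(rule$logw + t^2, each = length(x))
  hmax <- apply(h, 1L, max)
  log(sqrt(2) * s) + hmax + log(rowSums(exp(h - hmax)))
}

# Log tail probability by dense trapezoidal quadrature in log space.
# lower = TRUE  -> log Pr(X <= q)
# lower = FALSE -> log Pr(X >  q)
# Grid spacing resolves both the Gaussian scale sigma and the binomial
# transition scale 1/sqrt(n p q); both tails share the construction.
bln_logtail1 <- function(q, n, mu, sigma, lower) {
  if (lower && q >= n) return(0)
  if (!lower && q < 0) return(0)
  if (lower && q < 0) return(-Inf)
  if (!lower && q >= n) return(-Inf)
  if (sigma == 0)
    return(pbinom(q, n, plogis(mu), lower.tail = lower, log.p = TRUE))
  grid <- bln_tail_grid(q, n, mu, sigma)
  g <- pbinom(q, n, plogis(grid$d), lower.tail = lower, log.p = TRUE) +
    dnorm(grid$d, mu, sigma, log = TRUE)
  min(log(grid$h) + logsumexp(g), 0)
}

bln_tail_grid <- function(q, n, mu, sigma) {
  pt <- min(max((q + 0.5) / (n + 1), 0.5 / (n + 1)), 1 - 0.5 / (n + 1))
  w <- 1 / sqrt(n * pt * (1 - pt))
  ctr <- qlogis(pt)
  lo <- min(mu - 9 * sigma, ctr - 9 * w - 1)
  hi <- max(mu + 9 * sigma, ctr + 9 * w + 1)
  m <- min(max(ceiling((hi - lo) / (min(sigma, w) / 8)), 200L), 60000L)
  h <- (hi - lo) / m
  list(d = seq(lo + h / 2, hi - h / 2, length.out = m), h = h)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Binomial-logit-normal cumulative distribution function
#'
#' `Pr(X <= q)` (or the upper tail `Pr(X > q)`) under the BLN law, computed by
#' dense log-space quadrature of the conditional binomial CDF against the
#' latent normal density.
#'
#' @inheritParams dbln
#' @param q integer quantiles.
#' @param lower.tail,log.p as in [stats::pbinom()].
#' @return numeric vector of (log-)tail probabilities.
#' @export
pbln <- function(q, size, mu = 0, sigma, lower.tail = TRUE, log.p = FALSE) {
  k <- max(length(q), length(size), length(mu), length(sigma))
  if (k == 0L) return(numeric(0))
  q <- rep_len(q, k); size <- rep_len(size, k)
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  check_bln_args(q, size, mu, sigma, allow_x_outside = TRUE)
  out <- vapply(seq_len(k), function(i) {
    bln_logtail1(floor(q[i]), size[i], mu[i], sigma[i], lower.tail)
  }, numeric(1))
  if (log.p) out else exp(out)
}

#' Two-sided BLN outlier p-value
#'
#' Doubles the smaller of the two tails that include the observed count and
#' clamps at 1: `p = min(1, 2 min(Pr(X <= x), Pr(X >= x)))`.  This is the test
#' statistic of the dosage outlier test; with `mu = 0` it is symmetric in
#' `x <-> size - x`.
#'
#' @inheritParams dbln
#' @param log.p return the log p-value (useful when `p` underflows).
#' @return numeric vector of p-values in `(0, 1]`.
#' @examples
#' bln_two_sided_p(0, size = 10, sigma = 0)   # 2 * 0.5^10
#' bln_two_sided_p(5, size = 10, sigma = 0.5) # centred: 1
#' @export
bln_two_sided_p <- function(x, size, mu = 0, sigma, log.p = FALSE) {
  k <- max(length(x), length(size), length(mu), length(sigma))
  if (k == 0L) return(numeric(0))
  x <- rep_len(x, k); size <- rep_len(size, k)
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  check_bln_args(x, size, mu, sigma)
  if (any(size < 1))
    stop("`size` must be >= 1 for the two-sided test", call. = FALSE)
  out <- vapply(seq_len(k), function(i) {
    if (sigma[i] == 0) {
      lt <- pbinom(x[i], size[i], plogis(mu[i]), log.p = TRUE)
      ut <- pbinom(x[i] - 1, size[i], plogis(mu[i]), lower.tail = FALSE,
                   log.p = TRUE)
    } else {
      # Both tails include x, so they share one transition region and grid.
      grid <- bln_tail_grid(x[i], size[i], mu[i], sigma[i])
      ld <- dnorm(grid$d, mu[i], sigma[i], log = TRUE)
      pr <- plogis(grid$d)
      lt <- min(log(grid$h) + logsumexp(
        pbinom(x[i], size[i], pr, log.p = TRUE) + ld), 0)
      ut <- min(log(grid$h) + logsumexp(
        pbinom(x[i] - 1, size[i], pr, lower.tail = FALSE, log.p = TRUE) + ld),
        0)
    }
    min(log(2) + min(lt, ut), 0)
  }, numeric(1))
  if (log.p) out else exp(out)
}

#' Sample from the binomial-logit-normal law
#'
#' Draws `delta ~ Normal(mu, sigma^2)` then `x ~ Binomial(size, plogis(delta))`
#' independently per draw.  Randomness comes from R's global RNG, so
#' `set.seed()` (or `withr::with_seed()`) gives reproducible draws.
#'
#' @param n number of draws.
#' @inheritParams dbln
#' @return integer vector of counts.
#' @export
rbln <- function(n, size, mu = 0, sigma) {
  stopifnot_scalar_count(n, "n")
  size <- rep_len(size, max(n, 1L))
  check_bln_args(0, size, mu, sigma)
  if (n == 0L) return(integer(0))
  delta <- rnorm(n, mu, sigma)
  rbinom(n, size[seq_len(n)], plogis(delta))
}
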
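# Independent brute-force oracles. These deliberately use the most literal
# possible formulations (explicit loops, exhaustive enumeration) so they share
# no code path with the package implementations they check.

# Kendall tau-b by looping over all pairs
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- x[i] - x[j]
      b <- y[i] - y[j]
      if (a == 0 && b == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (a == 0) tx <- tx + 1
      else if (b == 0) ty <- ty + 1
      else if (a * b > 0) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  if (tx == n0 || ty == n0) return(NA_real_)
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Benjamini-Hochberg by the literal step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  adj[m] <- sorted[m]
  if (m > 1) {
    for (i in (m - 1):1) {
      adj[i] <- min(adj[i + 1], sorted[i] * m / i)
    }
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# moderated t oracle: same moment equations, coded independently with scalar
# loops and stats::uniroot for the trigamma inversion
modt_oracle <- function(xa, xb) {
  G <- nrow(xa)
  na <- ncol(xa); nb <- ncol(xb)
  dg <- na + nb - 2
  s2 <- lfc <- numeric(G)
  for (g in 1:G) {
    va <- sum((xa[g, ] - mean(xa[g, ]))^2) / (na - 1)
    vb <- sum((xb[g, ] - mean(xb[g, ]))^2) / (nb - 1)
    s2[g] <- ((na - 1) * va + (nb - 1) * vb) / dg
    lfc[g] <- mean(xa[g, ]) - mean(xb[g, ])
  }
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1) - trigamma(dg / 2)
  if (evar <= 0) {
    d0 <- Inf
    s0 <- exp(ebar)
  } else {
    f <- function(y) trigamma(y) - evar
    y <- stats::uniroot(f, c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * y
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  st2 <- if (is.infinite(d0)) rep(s0, G) else (d0 * s0 + dg * s2) / (d0 + dg)
  tmod <- lfc / (sqrt(st2) * sqrt(1 / na + 1 / nb))
  list(d0 = d0, s0_sq = s0, t_mod = tmod, lfc = lfc)
}

# upper-tail hypergeometric probabilities for every k by exhaustively
# enumerating all size-n draws from a universe of N with K annotated items
hyper_enum_oracle <- function(N, K, n) {
  universe <- seq_len(N)
  annotated <- seq_len(K)
  draws <- if (n == 0) matrix(integer(0), nrow = 0, ncol = 1)
           else utils::combn(N, n)
  n_draws <- max(1L, ncol(draws))
  overlaps <- if (n == 0) 0L
              else apply(draws, 2, function(d) sum(d %in% annotated))
  vapply(0:min(K, n), function(k) mean(overlaps >= k), numeric(1))
}
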
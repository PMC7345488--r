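# Independent oracles, written against the definitions rather than the
# package implementation.

# Transfer-matrix reflectance of a single homogeneous film (characteristic
# matrix method), unpolarized.
tm_reflectance <- function(d_nm, lambda_nm, n1 = 1, n2 = 1.48,
                           n3 = 1.336, theta1 = 0) {
  s1 <- sin(theta1)
  th2 <- asin(n1 * s1 / n2)
  th3 <- asin(n1 * s1 / n3)
  one_pol <- function(e1, e2, e3) {
    delta <- 2 * pi * n2 * d_nm * cos(th2) / lambda_nm
    M <- matrix(c(cos(delta), 1i * sin(delta) / e2,
                  1i * e2 * sin(delta), cos(delta)),
                2, 2, byrow = TRUE)
    BC <- M %*% c(1, e3)
    r <- (e1 * BC[1] - BC[2]) / (e1 * BC[1] + BC[2])
    Mod(r)^2
  }
  es <- function(n, th) n * cos(th)
  ep <- function(n, th) n / cos(th)
  (one_pol(es(n1, theta1), es(n2, th2), es(n3, th3)) +
   one_pol(ep(n1, theta1), ep(n2, th2), ep(n3, th3))) / 2
}

# Exhaustive 256-candidate Kapur entropy scan, summing Shannon entropies
# term by term; smallest-threshold tie break.
kapur_exhaustive <- function(gray) {
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  best_t <- NA_integer_
  best_h <- -Inf
  for (t in 0:254) {
    pb <- sum(p[1:(t + 1)])
    pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    hb <- 0
    for (i in 1:(t + 1)) if (p[i] > 0)
      hb <- hb - (p[i] / pb) * log(p[i] / pb)
    hf <- 0
    for (i in (t + 2):256) if (p[i] > 0)
      hf <- hf - (p[i] / pf) * log(p[i] / pf)
    if (hb + hf > best_h + 1e-12) {
      best_h <- hb + hf
      best_t <- t
    }
  }
  best_t
}

# Per-color linear scan for the nearest look-up entry (smallest-llt ties).
nearest_llt_scan <- function(color, table) {
  best <- Inf
  best_llt <- NA_real_
  for (j in seq_len(nrow(table))) {
    d <- sqrt(sum((color - c(table$R[j], table$G[j], table$B[j]))^2))
    if (d < best - 1e-12) {
      best <- d
      best_llt <- table$llt_nm[j]
    }
  }
  best_llt
}

# ICC(2,1) via stats::aov's two-way decomposition.
icc21_aov <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ subj + rater, data = df)
  sm <- summary(fit)[[1]]
  ms <- sm[["Mean Sq"]]
  names(ms) <- trimws(rownames(sm))
  msr <- ms[["subj"]]; msc <- ms[["rater"]]; mse <- ms[["Residuals"]]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
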
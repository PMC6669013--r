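# Independent straight-line oracle implementations of the model
# recursions, written as plain scalar unrollings (no shared code with the
# package's filters). Choices are "a"/"b"/"missed"; outcomes are raw
# feedback values (NA on missed trials).

sig <- function(x) 1 / (1 + exp(-x))

oracle_dyna <- function(ch, out, beta, gamma, rho, stick = 0,
                        alpha1 = 0.5, v0 = 0, pemag0 = 0) {
  va <- v0; vb <- v0; alpha <- alpha1; pemag <- pemag0
  prev <- 0
  n <- length(ch)
  p_a <- v_a <- v_b <- alpha_t <- pemag_t <- wrpe <- rep(NA_real_, n)
  nll <- 0
  for (t in seq_len(n)) {
    p <- sig(beta * (va - vb) + stick * prev)
    p_a[t] <- p
    v_a[t] <- va; v_b[t] <- vb
    if (ch[t] == "missed") next
    nll <- nll - log(if (ch[t] == "a") p else 1 - p)
    vc <- if (ch[t] == "a") va else vb
    delta <- out[t] - vc
    pem2 <- rho * abs(delta) + (1 - rho) * pemag
    m <- if (pem2 + pemag == 0) 0 else
      (pem2 - pemag) / ((pem2 + pemag) / 2)
    f <- 2 / (1 + exp(-m / gamma)) - 1
    if (m > 0) alpha <- alpha + f * (1 - alpha)
    if (m < 0) alpha <- alpha + f * alpha
    if (ch[t] == "a") va <- va + alpha * delta else vb <- vb + alpha * delta
    pemag <- pem2
    prev <- if (ch[t] == "a") 1 else -1
    alpha_t[t] <- alpha; pemag_t[t] <- pemag; wrpe[t] <- alpha * delta
  }
  list(p_a = p_a, v_a = v_a, v_b = v_b, alpha = alpha_t, pemag = pemag_t,
       wrpe = wrpe, nll = nll)
}

oracle_ph <- function(ch, out, S, alpha1, beta, v0 = 0.5) {
  va <- v0; vb <- v0; alpha <- alpha1
  n <- length(ch)
  p_a <- v_a <- v_b <- rep(NA_real_, n)
  nll <- 0
  for (t in seq_len(n)) {
    p <- sig(beta * (va - vb))
    p_a[t] <- p; v_a[t] <- va; v_b[t] <- vb
    if (ch[t] == "missed") next
    nll <- nll - log(if (ch[t] == "a") p else 1 - p)
    r <- if (out[t] > 0) 1 else 0
    vc <- if (ch[t] == "a") va else vb
    delta <- r - vc
    if (ch[t] == "a") va <- va + S * alpha * delta
    else vb <- vb + S * alpha * delta
    alpha <- abs(delta)
  }
  list(p_a = p_a, v_a = v_a, v_b = v_b, nll = nll)
}

# binary three-level filter; u already coded in contingency space,
# hps = "a"/"b" identity per trial
oracle_hgf <- function(ch, u, hps, kappa, omega, theta, beta,
                       mu2 = 0, sa2 = 1, mu3 = 1, sa3 = 1) {
  n <- length(ch)
  p_a <- mu2_t <- mu3_t <- rep(NA_real_, n)
  nll <- 0
  for (t in seq_len(n)) {
    muhat1 <- sig(mu2)
    va <- if (hps[t] == "a") muhat1 else 1 - muhat1
    vb <- 1 - va
    p <- sig(beta * (va - vb))
    p_a[t] <- p
    if (ch[t] == "missed") { mu2_t[t] <- mu2; mu3_t[t] <- mu3; next }
    nll <- nll - log(if (ch[t] == "a") p else 1 - p)
    d1 <- u[t] - muhat1
    v2 <- exp(kappa * mu3 + omega)
    pihat2 <- 1 / (sa2 + v2)
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    mu2new <- mu2 + d1 / pi2
    pihat3 <- 1 / (sa3 + theta)
    w2 <- v2 * pihat2
    d2 <- ((1 / pi2) + (mu2new - mu2)^2) * pihat2 - 1
    pi3 <- pihat3 + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * d2)
    stopifnot(pi3 > 0)
    mu3 <- mu3 + kappa / (2 * pi3) * w2 * d2
    sa3 <- 1 / pi3
    mu2 <- mu2new
    sa2 <- 1 / pi2
    mu2_t[t] <- mu2; mu3_t[t] <- mu3
  }
  list(p_a = p_a, mu2 = mu2_t, mu3 = mu3_t, nll = nll)
}

oracle_k1 <- function(ch, u, hps, mu, h1, beta, v0 = 0.5, b0 = log(0.1)) {
  v <- v0; h <- h1; b <- b0
  n <- length(ch)
  p_a <- gain <- rep(NA_real_, n)
  nll <- 0
  for (t in seq_len(n)) {
    va <- if (hps[t] == "a") v else 1 - v
    p <- sig(beta * (va - (1 - va)))
    p_a[t] <- p
    if (ch[t] == "missed") next
    nll <- nll - log(if (ch[t] == "a") p else 1 - p)
    delta <- u[t] - v
    if (delta != 0) {
      b <- b + mu * delta * h
      if (b > 0) b <- 0
      k <- exp(b)
      v <- v + k * delta
      h <- h * max(0, 1 - k) + k * delta
      gain[t] <- k
    } else gain[t] <- exp(b)
  }
  list(p_a = p_a, gain = gain, nll = nll)
}

# contingency coding used by the oracles
oracle_u <- function(ch, out, hps) {
  ifelse(ch == "missed", NA_real_,
         as.numeric((ch == hps) == (out > 0)))
}

# textbook percentage-bend correlation (Wilcox), coded independently
oracle_pbcor <- function(x, y, beta = 0.2) {
  pbos <- function(v) {
    w <- sort(abs(v - median(v)))
    om <- w[floor((1 - beta) * length(v))]
    psi <- (v - median(v)) / om
    i1 <- sum(psi < -1)
    i2 <- sum(psi > 1)
    sv <- v
    sv[psi < -1 | psi > 1] <- 0
    (sum(sv) + om * (i2 - i1)) / (length(v) - i1 - i2)
  }
  wx <- sort(abs(x - median(x)))
  omx <- wx[floor((1 - beta) * length(x))]
  wy <- sort(abs(y - median(y)))
  omy <- wy[floor((1 - beta) * length(y))]
  a <- (x - pbos(x)) / omx
  a[a < -1] <- -1; a[a > 1] <- 1
  b <- (y - pbos(y)) / omy
  b[b < -1] <- -1; b[b > 1] <- 1
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# random choice/outcome sequence generator for oracle comparisons
random_sequence <- function(n, seed, p_missed = 0, p_pos = 0.7) {
  set.seed(seed)
  hps <- rep("a", n)
  # occasional contingency flips so contingency-space models see reversals
  flips <- sort(sample(seq(5, n - 1), size = max(0, n %/% 20)))
  cur <- "a"
  for (i in seq_len(n)) {
    if (i %in% flips) cur <- if (cur == "a") "b" else "a"
    hps[i] <- cur
  }
  ch <- sample(c("a", "b"), n, replace = TRUE)
  ch[runif(n) < p_missed] <- "missed"
  is_hps <- ch == hps
  pos <- runif(n) < ifelse(is_hps, p_pos, 1 - p_pos)
  out <- ifelse(pos, 10, -10)
  out[ch == "missed"] <- NA_real_
  data.frame(subject = "s01", trial = seq_len(n), choice = ch,
             outcome = out, hps_identity = hps,
             stringsAsFactors = FALSE)
}
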
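# Independent brute-force oracles used to validate the analytical
# implementations. These are written as direct transliterations of the
# defining sums (explicit double loops, no shared code with the package).

random_scm_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m / sum(m)
}

oracle_cor <- function(m) {
  n <- nrow(m)
  pr <- rowSums(m); pc <- colSums(m)
  mu_i <- 0; mu_j <- 0
  for (i in 0:(n - 1)) mu_i <- mu_i + i * pr[i + 1]
  for (j in 0:(n - 1)) mu_j <- mu_j + j * pc[j + 1]
  v_i <- 0; v_j <- 0
  for (i in 0:(n - 1)) v_i <- v_i + (i - mu_i)^2 * pr[i + 1]
  for (j in 0:(n - 1)) v_j <- v_j + (j - mu_j)^2 * pc[j + 1]
  if (v_i <= 0 || v_j <= 0) return(NA_real_)
  s <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1))
    s <- s + m[i + 1, j + 1] * (i - mu_i) * (j - mu_j)
  s / sqrt(v_i * v_j)
}

oracle_idm <- function(m) {
  n <- nrow(m); s <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1))
    s <- s + m[i + 1, j + 1] / (1 + abs(i - j))
  s
}

oracle_ent <- function(m) {
  s <- 0
  for (v in as.vector(m)) if (v > 0) s <- s - v * log2(v)
  s
}

oracle_csd <- function(m) {
  n <- nrow(m); s <- 0
  for (i in 1:n) {
    pe <- sum(m[i, ])
    if (pe > 0) s <- s + (m[i, i] - pe)^2 / pe
  }
  s
}

oracle_csr <- function(m) {
  n <- nrow(m); h <- n / 2
  p1 <- numeric(h); p3 <- numeric(h)
  for (i in 1:h) for (j in 1:h) p1[i] <- p1[i] + m[i, j]
  for (i in (h + 1):n) for (j in (h + 1):n) p3[i - h] <- p3[i - h] + m[i, j]
  s <- 0
  for (i in 1:h) {
    pm <- (p1[i] + p3[i]) / 2
    if (pm > 0) s <- s + (p1[i] - pm)^2 / pm
  }
  s
}

oracle_md <- function(p) {
  sup <- which(p > 0) - 1
  s <- 0
  for (a in seq_along(sup)) for (b in seq_along(sup))
    s <- s + p[sup[a] + 1] * p[sup[b] + 1] * abs(sup[a] - sup[b])
  s
}

oracle_mdr <- function(m) {
  mdc <- oracle_md(colSums(m)); mdr_ <- oracle_md(rowSums(m))
  if (mdc == 0 && mdr_ == 0) return(1)
  min(mdc, mdr_) / max(mdc, mdr_)
}

oracle_dkl <- function(m) {
  pc <- colSums(m); pr <- rowSums(m)
  s <- 0
  for (i in seq_along(pc))
    if (pc[i] > 0 && pr[i] > 0) s <- s + pc[i] * log2(pc[i] / pr[i])
  s
}

oracle_cad <- function(m) {
  pc <- colSums(m); pr <- rowSums(m)
  1 - sum(abs(pc - pr))
}

oracle_features <- function(m) {
  c(cor = oracle_cor(m), idm = oracle_idm(m), ent = oracle_ent(m),
    csd = oracle_csd(m), csr = oracle_csr(m), mdr = oracle_mdr(m),
    dkl = oracle_dkl(m), cad = oracle_cad(m))
}

# ---- optimum-path competition oracle -------------------------------------
# minimax path cost between two nodes by exhaustive simple-path enumeration
minimax_path <- function(d, from, to) {
  n <- nrow(d)
  best <- Inf
  walk <- function(node, visited, worst) {
    if (node == to) {
      best <<- min(best, worst)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt]) {
        v <- visited; v[nxt] <- TRUE
        walk(nxt, v, max(worst, d[node, nxt]))
      }
    }
  }
  vis <- rep(FALSE, n); vis[from] <- TRUE
  walk(from, vis, 0)
  best
}

# exhaustive optimum-path costs from a prototype set
oracle_opf_costs <- function(d, prototypes) {
  n <- nrow(d)
  sapply(seq_len(n), function(t) {
    if (t %in% prototypes) return(0)
    min(sapply(prototypes, function(p) minimax_path(d, p, t)))
  })
}
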
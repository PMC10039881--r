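# Independent brute-force simplex/cross-map oracle: explicit distance
# computation, full sort with index tie-break, explicit weight formula.
# Deliberately naive and kept free of the package's prediction kernel.

oracle_embed <- function(x, E, tau) {
  t_idx <- seq((E - 1) * tau + 1, length(x))
  emb <- sapply(0:(E - 1), function(j) x[t_idx - j * tau])
  list(emb = matrix(emb, nrow = length(t_idx)), t = t_idx)
}

oracle_predict <- function(emb, target, lib, pred, k) {
  vapply(pred, function(p) {
    cand <- lib[lib != p & !is.na(target[lib])]
    if (length(cand) < k) return(NA_real_)
    d <- vapply(cand, function(l) sqrt(sum((emb[p, ] - emb[l, ])^2)), numeric(1))
    ord <- order(d, cand)
    sel <- cand[ord[seq_len(k)]]
    ds <- d[ord[seq_len(k)]]
    w <- if (ds[1] == 0) as.numeric(ds == 0) else exp(-ds / ds[1])
    sum(w * target[sel]) / sum(w)
  }, numeric(1))
}

oracle_simplex <- function(x, E, tau, tp) {
  d <- oracle_embed(x, E, tau)
  target <- rep(NA_real_, nrow(d$emb))
  tt <- d$t + tp
  ok <- tt >= 1 & tt <= length(x)
  target[ok] <- x[tt[ok]]
  rows <- which(!is.na(target))
  est <- oracle_predict(d$emb, target, rows, rows, E + 1)
  list(obs = target[rows], pred = est,
       skill = suppressWarnings(cor(target[rows], est,
                                    use = "complete.obs")))
}

oracle_cross_map <- function(cause, effect, E, tau, lib = NULL, tp = 0) {
  d <- oracle_embed(effect, E, tau)
  target <- rep(NA_real_, nrow(d$emb))
  tt <- d$t + tp
  ok <- tt >= 1 & tt <= length(cause)
  target[ok] <- cause[tt[ok]]
  rows <- which(!is.na(target))
  if (is.null(lib)) lib <- rows
  est <- oracle_predict(d$emb, target, lib, rows, E + 1)
  list(obs = target[rows], pred = est,
       skill = suppressWarnings(cor(target[rows], est,
                                    use = "complete.obs")))
}

# Exhaustive-pair AUC for cross-checking the rank-based implementation.
oracle_auc <- function(real, surr) {
  s <- 0
  for (r in real) for (q in surr) s <- s + (r > q) + 0.5 * (r == q)
  s / (length(real) * length(surr))
}

ar1_sim <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}
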
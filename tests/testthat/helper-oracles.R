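## Independent brute-force oracles used to freeze expected values.
## These deliberately share no code with the package implementations.

## Conditional log-likelihood computed by direct summation over sets.
oracle_clr_loglik <- function(beta, dat) {
  ## dat: data.frame(set, case, x) with a single covariate
  sum(vapply(split(dat, dat$set), function(d) {
    eta <- d$x * beta
    eta[d$case == 1] - log(sum(exp(eta)))
  }, numeric(1)))
}

## 1-D grid maximizer of the conditional likelihood, successively refined.
oracle_clr_grid <- function(dat, lo = -5, hi = 5) {
  for (step in c(0.01, 1e-3, 1e-4, 1e-5, 1e-6)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, oracle_clr_loglik, numeric(1), dat = dat)
    best <- grid[which.max(ll)]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

## AUC by exhaustive pair counting (ties = 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## Exhaustive nearest-k controls for one case (the greedy target when a
## stratum has a single case): order by |date diff|, then |age diff|, then id.
oracle_nearest_k <- function(case, controls, k) {
  dd <- abs(as.numeric(controls$date - case$date))
  da <- abs(controls$age - case$age)
  controls$subject_id[order(dd, da, controls$subject_id)][seq_len(min(k, nrow(controls)))]
}

## One-sided binomial tail P(X >= k | n, 1/2) by enumeration.
oracle_binom_tail <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

## Two-sided Fisher p for a 2x2 table by complete hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Small matched 1:1 binary-exposure design with known discordant counts.
make_pairs <- function(n10, n01, n_conc_exposed = 0, n_conc_unexposed = 0) {
  sets <- list()
  add <- function(xc, x0) {
    s <- length(sets) + 1
    sets[[s]] <<- data.frame(set = s, case = c(1, 0), x = c(xc, x0))
  }
  for (i in seq_len(n10)) add(1, 0)
  for (i in seq_len(n01)) add(0, 1)
  for (i in seq_len(n_conc_exposed)) add(1, 1)
  for (i in seq_len(n_conc_unexposed)) add(0, 0)
  do.call(rbind, sets)
}

## Random 1:m binary-exposure matched design.
random_design <- function(n_sets, m, p_exp = 0.4, beta = 0.7) {
  do.call(rbind, lapply(seq_len(n_sets), function(s) {
    x <- stats::rbinom(m + 1, 1, p_exp)
    pr <- exp(beta * x); pr <- pr / sum(pr)
    case <- stats::rmultinom(1, 1, pr)[, 1]
    data.frame(set = s, case = case, x = x)
  }))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
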
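# Independent oracles used to check the package's survival and meta layers.
# These are deliberately naive re-derivations (loops over risk sets, pair
# enumeration, closed forms) and share no code with the implementation.

# Efron partial log-likelihood for one covariate
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    eR <- sum(exp(beta * x[R]))
    eD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(vapply(0:(d - 1), function(l) log(eR - (l / d) * eD), numeric(1)))
  }
  ll
}

# brute-force 1-D maximizer of the Efron partial likelihood
oracle_cox_1d <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_efron_loglik(b, time, event, x),
                  interval, maximum = TRUE, tol = 1e-9)$maximum
}

# product-limit estimator by hand: S(t) at each event time
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    died <- sum(time == tt[i] & event == 1)
    s <- s * (1 - died / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square by manual O/E/V tabulation
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Harrell's C by exhaustive pair enumeration
oracle_cindex <- function(score, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # comparable: the earlier time is an event
    if (time[i] == time[j] && event[i] == event[j]) next
    first <- if (time[i] < time[j]) i else j
    other <- if (first == i) j else i
    if (time[i] == time[j]) { first <- which(c(event[i], event[j]) == 1)[1]
                              first <- c(i, j)[first]; other <- setdiff(c(i, j), first) }
    if (event[first] != 1) next
    den <- den + 1
    if (score[first] > score[other]) num <- num + 1
    else if (score[first] == score[other]) num <- num + 0.5
  }
  num / den
}

# DerSimonian-Laird by closed form, written out independently
oracle_dl_tau2 <- function(effects, ses) {
  w <- ses^-2
  m <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - m)^2)
  max(0, (q - (length(effects) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

make_clinical <- function(time, event, ...) {
  data.frame(sample_id = sprintf("s%03d", seq_along(time)),
             time = time, event = event, ..., stringsAsFactors = FALSE)
}

# small standardized matrix straight from values (genes x samples)
zmat <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, "standardized")
}
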
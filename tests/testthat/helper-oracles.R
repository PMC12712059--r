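# Independent oracles: literal, step-by-step implementations written
# against the method definitions, kept deliberately separate from the
# package code paths they check.

# brute-force single-sample enrichment: explicit per-gene CDF loops,
# explicit ranking, explicit walk
oracle_gsva <- function(expr, sets, tau = 1, kernel = c("gaussian_cdf", "empirical_cdf")) {
  kernel <- match.arg(kernel)
  ng <- nrow(expr); ns <- ncol(expr)
  z <- matrix(0, ng, ns)
  for (i in seq_len(ng)) {
    xi <- expr[i, ]
    if (kernel == "gaussian_cdf") {
      h <- stats::sd(xi) / 4
      for (j in seq_len(ns)) {
        if (h == 0) z[i, j] <- ns / 2
        else {
          acc <- 0
          for (k in seq_len(ns)) acc <- acc + stats::pnorm((xi[j] - xi[k]) / h)
          z[i, j] <- acc
        }
      }
    } else {
      for (j in seq_len(ns)) z[i, j] <- sum(xi <= xi[j])
    }
  }
  genes <- toupper(rownames(expr))
  out <- matrix(NA_real_, length(sets), ns,
                dimnames = list(names(sets), colnames(expr)))
  for (si in seq_along(sets)) {
    inset <- genes %in% toupper(sets[[si]])
    for (j in seq_len(ns)) {
      ord <- order(z[, j], decreasing = TRUE)  # ties by gene index
      cum <- 0; maxpos <- 0; minneg <- 0
      w <- abs(ng / 2 - seq_len(ng))^tau
      denom_in <- sum(w[inset[ord]])
      n_out <- ng - sum(inset)
      for (p in seq_len(ng)) {
        g <- ord[p]
        if (inset[g]) cum <- cum + w[p] / denom_in
        else cum <- cum - 1 / n_out
        if (cum > maxpos) maxpos <- cum
        if (cum < minneg) minneg <- cum
      }
      out[si, j] <- maxpos + minneg
    }
  }
  out
}

# hand product-limit estimator
oracle_km <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(dt))
  for (i in seq_along(dt)) {
    n_risk <- sum(time >= dt[i])
    d <- sum(time == dt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = dt, survival = surv)
}

# two-group log-rank from the hypergeometric mean/variance at each
# distinct event time
oracle_logrank_2g <- function(time, event, in_g1) {
  dt <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in dt) {
    risk <- time >= t
    n <- sum(risk); n1 <- sum(risk & in_g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(z = (o - e) / sqrt(v), chisq = (o - e)^2 / v)
}

# exhaustive cutpoint scan; statistic per candidate from
# survival::survdiff (an independent route from the package's own
# tabulation)
oracle_cutpoint <- function(time, event, x, minprop = 0.1) {
  q <- stats::quantile(x, c(minprop, 1 - minprop), names = FALSE)
  v <- sort(unique(x))
  mids <- (v[-1] + v[-length(v)]) / 2
  mids <- mids[mids > q[1] & mids < q[2]]
  stat <- vapply(mids, function(m) {
    g <- factor(x <= m)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sqrt(sd$chisq)
  }, numeric(1))
  list(cutpoint = mids[which.max(stat)], statistic = max(stat),
       candidates = mids, stats = stat)
}

# Benjamini-Hochberg step-up with explicit monotonicity enforcement
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# textbook one-way ANOVA sums of squares
oracle_anova <- function(values, group) {
  group <- as.factor(group)
  gm <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(group) - 1
  df2 <- length(values) - nlevels(group)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# exact rank-sum p by enumeration over all C(m+n, m) group splits
oracle_wilcox_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); m <- length(a)
  w_obs <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  ws <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]) - m * (m + 1) / 2)
  mean(abs(ws - m * (n - m) / 2) >= abs(w_obs - m * (n - m) / 2))
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# best label accuracy over all bijections of predicted onto true labels
best_label_accuracy <- function(pred, truth) {
  lv_p <- unique(pred); lv_t <- unique(truth)
  perms <- list()
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in permute(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- 0
  for (p in permute(lv_t)) {
    map <- stats::setNames(p, lv_p[seq_along(p)])
    if (length(lv_p) > length(p)) next
    best <- max(best, mean(map[pred] == truth))
  }
  best
}

# exhaustive max-total-score bijection over the 3! cluster->label maps
oracle_best_bijection <- function(score) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- -Inf; bp <- NULL
  for (r in seq_len(nrow(perms))) {
    tot <- sum(score[cbind(1:3, perms[r, ])])
    if (tot > best) { best <- tot; bp <- perms[r, ] }
  }
  colnames(score)[bp]
}

# small deterministic survival fixture generator for oracle comparisons
random_survival_fixture <- function(n, seed) {
  set.seed(seed)
  list(time = round(stats::rexp(n, 0.2), 3),
       event = stats::rbinom(n, 1, 0.7),
       x = round(stats::rnorm(n), 3))
}
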